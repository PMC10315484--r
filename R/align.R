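#' @importFrom Biostrings pairwiseAlignment AAString AAStringSet
#' @importFrom Biostrings nmatch score pattern subject
NULL

default_scoring <- function() {
  mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  list(matrix = mat, gap_open = 11, gap_ext = 1)
}

# Batched local alignment of many queries against one subject.
# Returns one AlignmentHit row per query. Identity is percent identical
# columns among all aligned columns (gap columns count in the denominator);
# coverage of X is the percent of X's residues inside the aligned span.
align_batch <- function(query_seqs, query_ids, subject_seq, subject_id,
                        scoring = default_scoring()) {
  if (!nzchar(subject_seq)) stop("empty subject sequence", call. = FALSE)
  if (any(!nzchar(query_seqs))) stop("empty query sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query_seqs),
    Biostrings::AAString(subject_seq),
    type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_ext
  )
  ncols <- Biostrings::nchar(aln)
  idn <- ifelse(ncols > 0, 100 * Biostrings::nmatch(aln) / ncols, 0)
  qs <- BiocGenerics::start(Biostrings::pattern(aln))
  qe <- BiocGenerics::end(Biostrings::pattern(aln))
  ss <- BiocGenerics::start(Biostrings::subject(aln))
  se <- BiocGenerics::end(Biostrings::subject(aln))
  qlen <- nchar(query_seqs)
  slen <- nchar(subject_seq)
  empty <- ncols == 0
  qcov <- ifelse(empty, 0, 100 * (qe - qs + 1) / qlen)
  scov <- ifelse(empty, 0, 100 * (se - ss + 1) / slen)
  data.frame(
    query_id = query_ids,
    subject_id = subject_id,
    identity = idn,
    query_coverage = qcov,
    subject_coverage = scov,
    score = pmax(Biostrings::score(aln), 0),
    query_start = ifelse(empty, NA_integer_, qs),
    query_end = ifelse(empty, NA_integer_, qe),
    subject_start = ifelse(empty, NA_integer_, ss),
    subject_end = ifelse(empty, NA_integer_, se),
    stringsAsFactors = FALSE
  )
}

#' Optimal local alignment of two protein sequences
#'
#' Smith–Waterman local alignment under a BLOSUM62 substitution matrix with
#' affine gap penalties (a gap of length k costs `gap_open + k * gap_ext`).
#' Identity is computed over aligned columns, with gap columns included in
#' the denominator but never in the identical count; coverage of each side
#' is the percent of that sequence's length spanned by the aligned region.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param scoring list with elements `matrix` (substitution matrix),
#'   `gap_open`, `gap_ext`; defaults to BLOSUM62 with 11/1.
#' @param ids length-2 character vector of ids for the report.
#' @return one-row data.frame: `query_id`, `subject_id`, `identity`,
#'   `query_coverage`, `subject_coverage`, `score`, and 1-based inclusive
#'   `query_start`/`query_end`/`subject_start`/`subject_end`.
#' @export
local_align <- function(a, b, scoring = default_scoring(),
                        ids = c("query", "subject")) {
  stop_if_not_scalar_string(a, "a")
  stop_if_not_scalar_string(b, "b")
  align_batch(a, ids[1], b, ids[2], scoring)
}

#' All-vs-all homology search with identity and coverage filters
#'
#' Aligns every query against every subject and keeps the best hit per
#' (query, subject) pair with identity strictly above `min_identity` and
#' query coverage strictly above `min_coverage` — the BLASTp-rescue filter
#' (identity > 25%, coverage > 50%). Coverage is taken on the query side:
#' the known transporter used as bait must be mostly contained in the
#' alignment, guarding against domain-only matches.
#'
#' @param queries,subjects protein record data.frames
#'   (see [read_fasta()]).
#' @param min_identity,min_coverage percent thresholds, strict.
#' @param scoring see [local_align()].
#' @param drop_self drop hits of a sequence against itself (same id).
#' @return AlignmentHit data.frame of retained hits.
#' @export
search_homologs <- function(queries, subjects, min_identity = 25,
                            min_coverage = 50, scoring = default_scoring(),
                            drop_self = TRUE) {
  stopifnot(is.data.frame(queries), nrow(queries) > 0,
            is.data.frame(subjects), nrow(subjects) > 0)
  hits <- lapply(seq_len(nrow(subjects)), function(j) {
    align_batch(queries$sequence, queries$id,
                subjects$sequence[j], subjects$id[j], scoring)
  })
  hits <- do.call(rbind, hits)
  if (drop_self) hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  keep <- hits$identity > min_identity & hits$query_coverage > min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
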