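#' Read a protein FASTA file into a protein record table
#'
#' Reads amino-acid FASTA and returns one row per entry. The header token
#' before the first whitespace becomes the record id, the remainder the
#' description. Sequences are uppercased on ingest; ids must be unique
#' within the file.
#'
#' @param path path to a FASTA file.
#' @param species species tag attached to every record (e.g. `"Si"`,
#'   `"Sc"`, `"Cn"`); recycled scalar.
#' @return a data.frame with columns `id`, `species`, `description`,
#'   `sequence`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("empty FASTA file (no records): ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids))) {
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty id",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("FASTA record '", ids[!nzchar(seqs)][1], "' has an empty sequence",
         call. = FALSE)
  }
  data.frame(
    id = ids,
    species = rep_len(as.character(species), length(ids)),
    description = desc,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Write a protein record table to FASTA
#'
#' @param records data.frame with `id`, `sequence` and optionally
#'   `description` columns (as produced by [read_fasta()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- records$description %||% character(0)
  names(set) <- if (length(desc) && any(nzchar(desc))) {
    trimws(paste(records$id, records$description))
  } else {
    records$id
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Translate an open reading frame to protein
#'
#' Standard-code translation of a nucleotide ORF. A trailing stop codon is
#' removed and not counted in the protein length. Internal stops are
#' translated as `*`, raise a warning, and are flagged in the
#' `internal_stop` attribute of the result.
#'
#' @param nt_sequence nucleotide string, length divisible by 3.
#' @return single amino-acid string; attribute `internal_stop` is `TRUE`
#'   if a stop codon occurs before the final codon.
#' @export
translate_orf <- function(nt_sequence) {
  stop_if_not_scalar_string(nt_sequence, "nt_sequence")
  nt <- toupper(nt_sequence)
  if (nchar(nt) %% 3L != 0L) {
    stop("ORF length (", nchar(nt), ") is not divisible by 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    if.fuzzy.codon = "solve"
  ))
  # trailing stop is the natural terminator, not part of the protein
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  internal <- grepl("*", aa, fixed = TRUE)
  if (internal) {
    warning("internal stop codon in ORF translation", call. = FALSE)
  }
  structure(aa, internal_stop = internal)
}
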