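#' Read a fold-change table
#'
#' Reads a TSV of genes x comparisons log2 fold changes in the
#' printed-table convention where 0 (or `NA` on input) encodes
#' not-significant; any other entry must satisfy `|value| >= lfc_min`.
#' The first column is taken as the gene id.
#'
#' @param path TSV path.
#' @param lfc_min invariant threshold for nonzero entries.
#' @return numeric matrix, gene ids as rownames.
#' @export
read_fc_table <- function(path, lfc_min = 1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  mat[is.na(mat)] <- 0
  rownames(mat) <- ids
  validate_fc_table(mat, lfc_min)
  mat
}

validate_fc_table <- function(fc_table, lfc_min = 1) {
  bad <- fc_table != 0 & abs(fc_table) < lfc_min
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("fold-change table invariant violated: nonzero entry |",
         fc_table[w[1], w[2]], "| < ", lfc_min, " at gene '",
         rownames(fc_table)[w[1]], "', column '",
         colnames(fc_table)[w[2]], "'", call. = FALSE)
  }
  invisible(fc_table)
}

#' Up/down counts per comparison from a fold-change table
#'
#' For each comparison column, the number of genes with log2 fold change
#' at or above `lfc_min` (up) and at or below `-lfc_min` (down), plus the
#' number of distinct genes significant in at least one column — the
#' cross-tabulation behind a "DEGs per comparison" summary row.
#'
#' @param fc_table matrix in the 0-means-ns convention
#'   (see [read_fc_table()]).
#' @param lfc_min threshold, default 1.
#' @return list: `per_comparison` (data.frame `comparison`, `n_up`,
#'   `n_down`), `distinct_total`.
#' @export
deg_counts_from_fc_table <- function(fc_table, lfc_min = 1) {
  validate_fc_table(fc_table, lfc_min)
  n_up <- colSums(fc_table >= lfc_min)
  n_down <- colSums(fc_table <= -lfc_min)
  list(
    per_comparison = data.frame(
      comparison = colnames(fc_table),
      n_up = as.integer(n_up),
      n_down = as.integer(n_down),
      stringsAsFactors = FALSE
    ),
    distinct_total = sum(rowSums(fc_table != 0) > 0)
  )
}

#' Genes consistently regulated across every comparison
#'
#' Returns the gene ids whose entry is nonzero with the requested sign in
#' ALL columns of the fold-change table — e.g. the single transporter
#' gene consistently salt-induced at every timepoint.
#'
#' @param fc_table matrix (see [read_fc_table()]).
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids (possibly empty).
#' @export
consistent_genes <- function(fc_table, direction = c("up", "down")) {
  direction <- match.arg(direction)
  hit <- if (direction == "up") fc_table > 0 else fc_table < 0
  rownames(fc_table)[rowSums(hit) == ncol(fc_table)]
}

#' Venn region counts for two or three DEG sets
#'
#' @param named_deg_sets named list of 2 or 3 character vectors.
#' @return named integer vector over all non-empty regions; region names
#'   join set names with `&` (e.g. `"A"`, `"A&B"`, `"A&B&C"`), each
#'   region exclusive of the larger intersections.
#' @export
venn_regions <- function(named_deg_sets) {
  k <- length(named_deg_sets)
  if (k < 2 || k > 3) {
    stop("venn_regions supports 2 or 3 sets, got ", k, call. = FALSE)
  }
  if (is.null(names(named_deg_sets)) || any(!nzchar(names(named_deg_sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  sets <- lapply(named_deg_sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  out <- integer(nrow(combos))
  names(out) <- apply(combos, 1, function(inc) {
    paste(names(sets)[unlist(inc)], collapse = "&")
  })
  for (r in seq_len(nrow(combos))) {
    inc <- unlist(combos[r, ])
    out[r] <- sum(apply(member, 1, function(m) all(m == inc)))
  }
  stopifnot(sum(out) == length(universe))
  out
}

#' Break down transporter DEGs by annotation category
#'
#' Cross-tabulates significant DEG records against the transportome's
#' subcellular location or substrate group, split by direction and
#' timepoint — the data behind "transporters induced at 1.5 h per
#' compartment" style panels. DEG genes absent from the transportome are
#' excluded and their number attached as attribute `"n_excluded"`.
#'
#' @param deg_records data.frame from [call_degs()] (only `up`/`down`
#'   rows are counted).
#' @param transportome annotated `transportome` data.frame.
#' @param by `"location"` or `"substrate_group"`.
#' @return data.frame `category`, `direction`, `timepoint`, `count`.
#' @export
breakdown_degs <- function(deg_records, transportome,
                           by = c("location", "substrate_group")) {
  by <- match.arg(by)
  sig <- deg_records[deg_records$status %in% c("up", "down"), ,
                     drop = FALSE]
  known <- sig$gene_id %in% transportome$protein_id
  n_excluded <- sum(!known)
  sig <- sig[known, , drop = FALSE]
  cat <- transportome[[by]][match(sig$gene_id, transportome$protein_id)]
  cat[is.na(cat) | !nzchar(cat)] <- "?"
  tp <- vapply(strsplit(sig$comparison_id, ":", fixed = TRUE),
               `[`, "", 2L)
  tab <- as.data.frame(table(category = cat, direction = sig$status,
                             timepoint = factor(tp, levels = TIMEPOINTS)),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tab$count <- as.integer(tab$count)
  attr(tab, "n_excluded") <- n_excluded
  tab
}

#' Hierarchical clustering of fold-change profiles
#'
#' Deterministic agglomerative clustering of genes by their fold-change
#' profiles across comparisons. Rows are ordered by gene id before
#' clustering so ties break reproducibly; a constant matrix collapses to
#' a single cluster without error.
#'
#' @param fc_matrix genes x comparisons numeric matrix with rownames.
#' @param k number of flat clusters to cut (default `NULL`: no cut).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list: `hclust` (the tree), `leaf_order` (gene ids in dendrogram
#'   order), `clusters` (named integer vector when `k` given, else
#'   `NULL`).
#' @export
cluster_fc_profiles <- function(fc_matrix, k = NULL, metric = "euclidean",
                                linkage = "complete") {
  stopifnot(is.matrix(fc_matrix), nrow(fc_matrix) >= 2,
            !is.null(rownames(fc_matrix)))
  fc_matrix <- fc_matrix[order(rownames(fc_matrix)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(fc_matrix, method = metric),
                      method = linkage)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, leaf_order = rownames(fc_matrix)[hc$order],
       clusters = clusters)
}

#' Sample-similarity diagnostics: Pearson correlation and PCA
#'
#' Computes the symmetric Pearson correlation matrix between samples over
#' all gene expression values, and a principal component analysis of the
#' samples on log2(x + 1), centred, components ordered by descending
#' variance. Zero-variance samples yield `NA` correlations for their
#' pairs.
#'
#' @param expr_matrix genes x samples expression matrix (e.g. FPKM).
#' @param log_transform apply log2(x + 1) before PCA (and correlation
#'   when `TRUE`, matching heat-map practice).
#' @return list: `correlation` (samples x samples), `pca_scores`
#'   (samples x PCs), `variance_explained` (proportion per PC).
#' @export
sample_similarity <- function(expr_matrix, log_transform = TRUE) {
  expr_matrix <- as.matrix(expr_matrix)
  if (ncol(expr_matrix) < 2) stop(">= 2 samples required", call. = FALSE)
  x <- if (log_transform) log2(expr_matrix + 1) else expr_matrix
  cm <- suppressWarnings(stats::cor(x, method = "pearson"))
  diag(cm) <- ifelse(apply(x, 2, stats::sd) == 0, NA, 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(correlation = cm, pca_scores = pc$x,
       variance_explained = ve)
}
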