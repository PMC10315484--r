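# Kyte-Doolittle hydropathy scale; non-standard residues (X etc.) score 0.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Predict transmembrane segments from windowed hydropathy
#'
#' A classical hydropathy-plot stand-in for a dedicated TM-topology
#' predictor: the Kyte–Doolittle score is averaged over a sliding window,
#' maximal runs of window centres whose mean exceeds `threshold` are
#' expanded to the full window extent, overlapping expansions are merged,
#' and segments shorter than `min_len` residues are discarded. Sequences
#' shorter than the window yield zero segments. Pipelines working from a
#' real predictor's output can bypass this via [read_tm_table()].
#'
#' @param seq amino-acid sequence.
#' @param protein_id id carried into the profile.
#' @param window odd window width in residues.
#' @param threshold mean-hydropathy cutoff for a window centre.
#' @param min_len minimum retained segment length, residues.
#' @return list of class `tm_profile`: `protein_id`, `segments` (two-column
#'   matrix of 1-based inclusive start/end), `tm_count`.
#' @export
predict_tm_segments <- function(seq, protein_id = "protein", window = 19,
                                threshold = 1.6, min_len = 15) {
  stop_if_not_scalar_string(seq, "seq")
  stopifnot(window %% 2 == 1, window >= 3, min_len >= 1)
  res <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(res)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (n < window) {
    return(structure(list(protein_id = protein_id, segments = empty,
                          tm_count = 0L), class = "tm_profile"))
  }
  h <- unname(KD_SCALE[res])
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  above <- means[centers] > threshold
  if (!any(above)) {
    return(structure(list(protein_id = protein_id, segments = empty,
                          tm_count = 0L), class = "tm_profile"))
  }
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- which(r$values)
  # expand each run of centres to the window extent, then merge overlaps
  seg_start <- centers[starts_idx[runs]] - half
  seg_end <- centers[ends_idx[runs]] + half
  merged_s <- seg_start[1]; merged_e <- seg_end[1]
  if (length(seg_start) > 1) {
    for (k in 2:length(seg_start)) {
      if (seg_start[k] <= merged_e[length(merged_e)] + 1L) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], seg_end[k])
      } else {
        merged_s <- c(merged_s, seg_start[k])
        merged_e <- c(merged_e, seg_end[k])
      }
    }
  }
  keep <- (merged_e - merged_s + 1L) >= min_len
  segs <- cbind(start = merged_s[keep], end = merged_e[keep])
  structure(list(protein_id = protein_id, segments = segs,
                 tm_count = nrow(segs)), class = "tm_profile")
}

#' Predict TM segments for every record in a protein table
#'
#' @param records protein record data.frame (see [read_fasta()]).
#' @inheritParams predict_tm_segments
#' @return data.frame `protein_id`, `tm_count`, `segments` (segment string
#'   `"s1-e1;s2-e2"`, empty when none).
#' @export
predict_tm_table <- function(records, window = 19, threshold = 1.6,
                             min_len = 15) {
  profs <- lapply(seq_len(nrow(records)), function(i) {
    predict_tm_segments(records$sequence[i], records$id[i],
                        window = window, threshold = threshold,
                        min_len = min_len)
  })
  data.frame(
    protein_id = vapply(profs, `[[`, "", "protein_id"),
    tm_count = vapply(profs, `[[`, 0L, "tm_count"),
    segments = vapply(profs, function(p) {
      if (p$tm_count == 0L) "" else
        paste(p$segments[, "start"], p$segments[, "end"],
              sep = "-", collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Read an externally computed TM table
#'
#' Accepts the tab-separated output of a real TM predictor (columns
#' `protein_id`, `tm_count`, optional `segments`) so the hydropathy
#' stand-in can be bypassed.
#'
#' @param path TSV path.
#' @return data.frame `protein_id`, `tm_count`, `segments`.
#' @export
read_tm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "tm_count") %in% names(tab))) {
    stop("TM table must have columns protein_id and tm_count", call. = FALSE)
  }
  if (is.null(tab$segments)) tab$segments <- ""
  tab$tm_count <- as.integer(tab$tm_count)
  if (any(is.na(tab$tm_count) | tab$tm_count < 0)) {
    stop("tm_count must be a non-negative integer", call. = FALSE)
  }
  tab[, c("protein_id", "tm_count", "segments")]
}
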