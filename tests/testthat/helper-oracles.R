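# Independent oracles, deliberately naive implementations.

# Exhaustive affine-gap Smith-Waterman (Gotoh) over all DP cells.
# Gap of length k costs open + k * ext, matching the aligner's convention.
sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[ra[i], rb[j]]
      M[i + 1, j + 1] <- max(0, s + max(M[i, j], Ix[i, j], Iy[i, j]))
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1], Ix[i + 1, j + 1],
                  Iy[i + 1, j + 1])
    }
  }
  best
}

# From-scratch Benjamini-Hochberg via the sorted-rank definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force connected components by transitive closure over an edge list.
components_oracle <- function(ids, edges) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        a <- edges[r, 1]; b <- edges[r, 2]
        if (comp[a] != comp[b]) {
          comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# Direct-summation windowed hydropathy mean at a single centre position.
kd_window_mean_oracle <- function(seq, center, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  half <- (window - 1) / 2
  res <- strsplit(seq, "")[[1]][(center - half):(center + half)]
  v <- kd[res]; v[is.na(v)] <- 0
  mean(v)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein <- function(n, pool = c("A", "R", "N", "D", "C", "Q", "E",
                                       "G", "H", "I", "L", "K", "M", "F",
                                       "P", "S", "T", "W", "Y", "V")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Mutate a protein at exactly `rate` of its sites (no indels).
mutate_exact <- function(seq, rate) {
  res <- strsplit(seq, "")[[1]]
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  k <- round(length(res) * rate)
  idx <- sample(length(res), k)
  res[idx] <- vapply(res[idx], function(r) sample(setdiff(aa, r), 1), "")
  paste(res, collapse = "")
}
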