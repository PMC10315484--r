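COMPARISON_CONTRASTS <- list(
  NaFLvsFL     = list(treat = c(lifestyle = "FL",   salt = "NaCl50"),
                      ref   = c(lifestyle = "FL",   salt = "control")),
  NaSymbvsSymb = list(treat = c(lifestyle = "Symb", salt = "NaCl50"),
                      ref   = c(lifestyle = "Symb", salt = "control")),
  SymbvsFL     = list(treat = c(lifestyle = "Symb", salt = "control"),
                      ref   = c(lifestyle = "FL",   salt = "control")),
  NaSymbvsNaFL = list(treat = c(lifestyle = "Symb", salt = "NaCl50"),
                      ref   = c(lifestyle = "FL",   salt = "NaCl50"))
)

TIMEPOINTS <- c("1.5h", "7d", "14d")

#' The twelve condition comparisons of the study design
#'
#' Four contrasts (salt within free-living, salt within symbiosis,
#' symbiosis vs free-living without salt, and with salt) at each of three
#' timepoints (1.5 h, 7 d, 14 d).
#'
#' @return character vector of comparison ids, e.g. `"NaFLvsFL:7d"`.
#' @export
all_comparisons <- function() {
  as.vector(outer(names(COMPARISON_CONTRASTS), TIMEPOINTS, paste,
                  sep = ":"))
}

parse_comparison <- function(comparison_id) {
  parts <- strsplit(comparison_id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% names(COMPARISON_CONTRASTS) ||
      !parts[2] %in% TIMEPOINTS) {
    stop("unknown comparison id '", comparison_id, "' (expected e.g. '",
         all_comparisons()[1], "')", call. = FALSE)
  }
  c(COMPARISON_CONTRASTS[[parts[1]]],
    list(contrast = parts[1], timepoint = parts[2]))
}

match_samples <- function(meta, side, timepoint) {
  meta$sample_id[meta$lifestyle == side[["lifestyle"]] &
                   meta$salt == side[["salt"]] &
                   meta$timepoint == timepoint]
}

#' Quality-control filter for RNA samples
#'
#' Keeps samples with RNA integrity number strictly above 7.5 and a
#' 28S/18S rRNA ratio strictly above 1.5; samples with a missing metric
#' are rejected with reason `missing_qc`.
#'
#' @param meta sample metadata data.frame with `sample_id`, `rin`,
#'   `rrna_ratio`.
#' @return list `kept` (sample ids) and `rejected` (data.frame
#'   `sample_id`, `reason`).
#' @export
qc_samples <- function(meta, min_rin = 7.5, min_rrna_ratio = 1.5) {
  stopifnot(all(c("sample_id", "rin", "rrna_ratio") %in% names(meta)))
  missing <- is.na(meta$rin) | is.na(meta$rrna_ratio)
  pass <- !missing & meta$rin > min_rin & meta$rrna_ratio > min_rrna_ratio
  reason <- rep(NA_character_, nrow(meta))
  reason[missing] <- "missing_qc"
  reason[!missing & meta$rin <= min_rin] <- "rin"
  reason[!missing & meta$rin > min_rin &
           meta$rrna_ratio <= min_rrna_ratio] <- "rrna_ratio"
  list(kept = meta$sample_id[pass],
       rejected = data.frame(sample_id = meta$sample_id[!pass],
                             reason = reason[!pass],
                             stringsAsFactors = FALSE))
}

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total_counts[s])` —
#' length- and depth-normalised abundance. Doubling every count in a
#' sample leaves that sample's FPKM unchanged.
#'
#' @param counts genes x samples non-negative count matrix with rownames.
#' @param gene_lengths_bp named vector of transcript lengths in bp
#'   (all > 0), covering every gene in `counts`.
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, gene_lengths_bp) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  len <- gene_lengths_bp[rownames(counts)]
  if (any(is.na(len))) {
    stop("missing gene length for: ",
         paste(utils::head(rownames(counts)[is.na(len)], 3),
               collapse = ", "), call. = FALSE)
  }
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  sweep(sweep(counts, 1, len, "/"), 2, lib, "/") * 1e9
}

#' Flag genes unexpressed in at least one condition
#'
#' A gene is flagged when its FPKM is at or below `eps` in every replicate
#' of at least one (lifestyle, salt, timepoint) condition cell.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param meta sample metadata with `sample_id`, `lifestyle`, `salt`,
#'   `timepoint`.
#' @param gene_ids restrict the scan to these genes (e.g. the transportome
#'   members); default all rows.
#' @param eps expression threshold, default 0.
#' @return character vector of flagged gene ids.
#' @export
flag_unexpressed <- function(fpkm, meta, gene_ids = rownames(fpkm),
                             eps = 0) {
  gene_ids <- intersect(gene_ids, rownames(fpkm))
  cells <- split(meta$sample_id,
                 interaction(meta$lifestyle, meta$salt, meta$timepoint,
                             drop = TRUE))
  flagged <- rep(FALSE, length(gene_ids))
  for (samples in cells) {
    samples <- intersect(samples, colnames(fpkm))
    if (!length(samples)) next
    sub <- fpkm[gene_ids, samples, drop = FALSE]
    flagged <- flagged | apply(sub <= eps, 1, all)
  }
  gene_ids[flagged]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed from the median ratio of each
#' sample's counts to the gene-wise geometric mean, over genes expressed
#' in every sample; falls back to library-size ratios when no such gene
#' exists.
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    lib <- colSums(counts)
    return(lib / exp(mean(log(lib))))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts) {
    exp(stats::median(log(cnts) - log_gm[use]))
  })
  unname(sf)
}

nb_dispersion_mom <- function(q_a, q_b) {
  # pooled method-of-moments dispersion on normalised counts
  est <- function(q) {
    mu <- mean(q)
    if (mu <= 0) return(NA_real_)
    (stats::var(q) - mu) / mu^2
  }
  ests <- c(est(q_a), est(q_b))
  ests <- ests[!is.na(ests)]
  if (!length(ests)) return(1e-8)
  max(mean(ests), 1e-8)
}

#' Negative-binomial two-group differential expression test
#'
#' A documented stand-in for a full shrinkage-based DE engine: counts are
#' normalised by median-of-ratios size factors, gene-wise dispersion is
#' estimated by pooled method of moments (floored at 1e-8), and a Wald
#' statistic on the log2 ratio of group means (pseudocount 0.5) is
#' referred to the standard normal. P values are Benjamini–Hochberg adjusted across all
#' tested genes. A gene is `up` iff `padj < alpha` and `log2fc >= lfc_min`,
#' `down` iff `padj < alpha` and `log2fc <= -lfc_min`, otherwise `ns`.
#'
#' @param counts genes x samples count matrix with dimnames.
#' @param meta sample metadata (`sample_id`, `lifestyle`, `salt`,
#'   `timepoint`).
#' @param comparison_id one of [all_comparisons()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param exclude_samples sample ids dropped before testing (e.g.
#'   replicates flagged as biased in sample-level diagnostics).
#' @return data.frame `gene_id`, `comparison_id`, `log2fc`, `pvalue`,
#'   `padj`, `status`.
#' @export
call_degs <- function(counts, meta, comparison_id, alpha = 0.05,
                      lfc_min = 1, exclude_samples = character()) {
  counts <- as.matrix(counts)
  cmp <- parse_comparison(comparison_id)
  meta <- meta[!(meta$sample_id %in% exclude_samples), , drop = FALSE]
  treat <- intersect(match_samples(meta, cmp$treat, cmp$timepoint),
                     colnames(counts))
  ref <- intersect(match_samples(meta, cmp$ref, cmp$timepoint),
                   colnames(counts))
  if (length(treat) < 2 || length(ref) < 2) {
    stop("comparison '", comparison_id,
         "' needs >= 2 replicates per group (treat ", length(treat),
         ", ref ", length(ref), ")", call. = FALSE)
  }
  sub <- counts[, c(ref, treat), drop = FALSE]
  sf <- size_factors(sub)
  q <- sweep(sub, 2, sf, "/")
  i_ref <- seq_along(ref)
  i_trt <- length(ref) + seq_along(treat)
  n1 <- length(ref); n2 <- length(treat)
  res <- t(vapply(seq_len(nrow(q)), function(g) {
    qa <- q[g, i_ref]; qb <- q[g, i_trt]
    mu_a <- mean(qa); mu_b <- mean(qb)
    lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
    if (mu_a == 0 && mu_b == 0) return(c(lfc = 0, p = NA_real_))
    disp <- nb_dispersion_mom(qa, qb)
    var_mean <- function(mu, idx, n) {
      sum(mu / sf[idx] + disp * mu^2) / n^2
    }
    se_log2 <- function(mu, idx, n) {
      sqrt(var_mean(mu, idx, n)) / ((mu + 0.5) * log(2))
    }
    se <- sqrt(se_log2(mu_a, i_ref, n1)^2 + se_log2(mu_b, i_trt, n2)^2)
    z <- lfc / se
    c(lfc = lfc, p = 2 * stats::pnorm(-abs(z)))
  }, c(lfc = 0, p = 0)))
  padj <- rep(NA_real_, nrow(res))
  tested <- !is.na(res[, "p"])
  padj[tested] <- stats::p.adjust(res[tested, "p"], method = "BH")
  status <- deg_status(padj, res[, "lfc"], alpha = alpha,
                       lfc_min = lfc_min)
  data.frame(gene_id = rownames(counts),
             comparison_id = comparison_id,
             log2fc = unname(res[, "lfc"]),
             pvalue = unname(res[, "p"]),
             padj = padj,
             status = status,
             stringsAsFactors = FALSE)
}

#' Differential-expression status from adjusted p and fold change
#'
#' @param padj adjusted p values (NA = untested, always `ns`).
#' @param log2fc log2 fold changes.
#' @param alpha,lfc_min thresholds (padj < 0.05, |log2fc| >= 1).
#' @return character vector `up` / `down` / `ns`.
#' @export
deg_status <- function(padj, log2fc, alpha = 0.05, lfc_min = 1) {
  status <- rep("ns", length(padj))
  sig <- !is.na(padj) & padj < alpha
  status[sig & log2fc >= lfc_min] <- "up"
  status[sig & log2fc <= -lfc_min] <- "down"
  status
}

#' Call DEGs for several comparisons
#'
#' @inheritParams call_degs
#' @param comparison_ids comparisons to run, default all twelve.
#' @param skip_incomplete silently skip comparisons whose groups lack
#'   replicates instead of erroring.
#' @return row-bound data.frame of [call_degs()] results.
#' @export
call_all_degs <- function(counts, meta,
                          comparison_ids = all_comparisons(),
                          alpha = 0.05, lfc_min = 1,
                          exclude_samples = character(),
                          skip_incomplete = FALSE) {
  out <- lapply(comparison_ids, function(cid) {
    if (skip_incomplete) {
      tryCatch(call_degs(counts, meta, cid, alpha, lfc_min,
                         exclude_samples),
               error = function(e) NULL)
    } else {
      call_degs(counts, meta, cid, alpha, lfc_min, exclude_samples)
    }
  })
  do.call(rbind, out)
}
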