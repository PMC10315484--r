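HYDROPHOBIC_RES <- c("L", "I", "V", "F", "A", "M")
HYDROPHILIC_RES <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G", "P", "H")

#' Simulation configuration for the synthetic study
#'
#' Default values state the simulated world: a desk-scale fungal proteome
#' in which a quarter of the proteins are polytopic membrane transporters
#' (4–10 transmembrane blocks of 19–23 hydrophobic residues joined by
#' 20–60 residue hydrophilic loops), two reference transportomes derived
#' by a seeded mutation model (20% substitutions, 1% single-residue
#' indels — comfortably inside the identity > 25% / coverage > 50% rescue
#' regime), a fifth of the focal transporters withheld from the annotated
#' baseline as rescue/screen targets, annotation keywords at 90% recall
#' and 2% false-positive rate, and negative-binomial counts over the
#' 2 lifestyle x 2 salt x 3 timepoint x 3 replicate design with
#' library sizes varied uniformly by ±30% and dispersion 0.05. Planted
#' expression effects include one always-salt-induced gene (up in the
#' salt-vs-control free-living contrast at all three timepoints, log2FC 2)
#' and one strongly symbiosis-induced gene (log2FC 8 at 7 d and 14 d),
#' mirroring the marker genes of the study design, plus generic +/-2
#' effects spread over the contrasts.
#'
#' @param seed integer seed (mandatory); per-output streams are derived
#'   as small offsets of it.
#' @param ... overrides for any default listed above.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_proteins = 160,
    transporter_fraction = 0.25,
    tm_segments_range = c(4L, 10L),
    tm_block_len = c(19L, 23L),
    loop_len = c(20L, 60L),
    decoy_len = c(150L, 600L),
    ortholog_divergence = list(substitution = 0.2, indel = 0.01),
    ortholog_presence = 0.7,
    ref_extra = 4L,
    unannotated_fraction = 0.2,
    annotation_keyword_recall = 0.9,
    keyword_fp_rate = 0.02,
    cog_transport_prob = 0.8,
    design = list(lifestyles = c("FL", "Symb"),
                  salt = c("control", "NaCl50"),
                  timepoints = c("1.5h", "7d", "14d"),
                  replicates = 3L),
    n_genes = 2000L,
    nb_mean_range = c(50, 500),
    nb_dispersion = 0.05,
    library_size_variation = 0.3,
    n_generic_effects = 48L,
    generic_lfc = 2,
    ena5_lfc = 2,
    ena1_lfc = 8,
    n_silent = 5L,
    qc_fail_rate = 0,
    gene_length_range = c(500L, 5000L)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, over)
  if (cfg$transporter_fraction <= 0 || cfg$transporter_fraction >= 1) {
    stop("transporter_fraction must be in (0, 1)", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) {
    stop("nb_dispersion must be positive", call. = FALSE)
  }
  rates <- c(cfg$ortholog_divergence$substitution,
             cfg$ortholog_divergence$indel,
             cfg$annotation_keyword_recall, cfg$keyword_fp_rate,
             cfg$qc_fail_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

sample_residues <- function(n, pool) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

make_transporter_seq <- function(cfg) {
  k <- sample(seq(cfg$tm_segments_range[1], cfg$tm_segments_range[2]), 1)
  loops <- vapply(seq_len(k + 1), function(i) {
    sample_residues(sample(seq(cfg$loop_len[1], cfg$loop_len[2]), 1),
                    HYDROPHILIC_RES)
  }, "")
  blocks <- vapply(seq_len(k), function(i) {
    sample_residues(sample(seq(cfg$tm_block_len[1], cfg$tm_block_len[2]), 1),
                    HYDROPHOBIC_RES)
  }, "")
  list(seq = paste0(paste0(loops[seq_len(k)], blocks, collapse = ""),
                    loops[k + 1]),
       tm_planted = k)
}

mutate_sequence <- function(seq, substitution, indel) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  aa <- names(KD_SCALE)
  sub_here <- stats::runif(length(res)) < substitution
  res[sub_here] <- vapply(res[sub_here], function(r) {
    sample(setdiff(aa, r), 1)
  }, "", USE.NAMES = FALSE)
  out <- character(0)
  for (r in res) {
    u <- stats::runif(1)
    if (u < indel / 2) {
      next                               # deletion
    } else if (u < indel) {
      out <- c(out, r, sample(aa, 1))    # insertion after the site
    } else {
      out <- c(out, r)
    }
  }
  paste(out, collapse = "")
}

TC_FAMILY_POOL <- data.frame(
  tc_class = c("2", "2", "2", "3", "3", "1", "1", "8", "9", "4", "5"),
  family_name = c("Major Facilitator Superfamily",
                  "Monovalent Cation:Proton Antiporter",
                  "K+ Uptake Permease",
                  "P-type ATPase", "ATP-binding Cassette",
                  "Voltage-gated Ion Channel", "Major Intrinsic Protein",
                  "Auxiliary transport protein",
                  "Putative transport protein",
                  "Acyl-CoA Thioesterase", "NADPH Oxidase"),
  substrate_group = c("nutrients", "osmoregulators", "nutrients",
                      "osmoregulators", "metabolic products",
                      "osmoregulators", "osmoregulators", "none/unknown",
                      "none/unknown", "metabolic substrates",
                      "metabolic substrates"),
  substrate_detail = c("Sugars", "Na+, H+", "K+", "Na+, K+",
                       "Drugs", "K+", "Water", "Unknown", "Unknown",
                       "Acyl-CoA", "Electrons"),
  location = c("PM", "Vacuole", "PM", "PM", "Vacuole", "PM", "PM", "?",
               "?", "Peroxisome", "Mitochondria"),
  stringsAsFactors = FALSE
)

random_tc_number <- function(tc_class) {
  paste(tc_class, sample(LETTERS[1:4], 1), sample(1:40, 1),
        sample(1:9, 1), sample(1:9, 1), sep = ".")
}

#' Generate the synthetic proteome suite
#'
#' Emits the focal proteome (planted TM-rich transporters among
#' hydrophilic decoys), reference transportomes for two species derived
#' from focal transporters by the seeded mutation model (plus a few
#' reference-only transporters with no focal parent), a TC-annotated
#' reference table, the annotated baseline (a random subset of the
#' planted transporters, the rest withheld as rescue/screen targets), and
#' the ground-truth ledger. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list: `si_proteome`, `ref_records`, `tc_reference`,
#'   `annotated_ids`, `truth` (list with `transporter_ids`,
#'   `annotated_ids`, `withheld_ids`, `decoy_ids`, `ortholog_pairs`,
#'   `ref_only_ids`, `tm_planted`).
#' @export
generate_proteome_suite <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_proteins
  n_tr <- round(n * config$transporter_fraction)
  ids <- sprintf("si%04d", seq_len(n))
  tr_ids <- ids[seq_len(n_tr)]
  decoy_ids <- setdiff(ids, tr_ids)
  seqs <- character(n)
  tm_planted <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    tr <- make_transporter_seq(config)
    seqs[i] <- tr$seq
    tm_planted[i] <- tr$tm_planted
  }
  for (i in seq(n_tr + 1, n)) {
    seqs[i] <- sample_residues(
      sample(seq(config$decoy_len[1], config$decoy_len[2]), 1),
      HYDROPHILIC_RES
    )
  }
  si <- data.frame(id = ids, species = "Si",
                   description = "", sequence = seqs,
                   stringsAsFactors = FALSE)

  # reference orthologs + species-only transporters, with TC annotations
  div <- config$ortholog_divergence
  fam_rows <- sample(nrow(TC_FAMILY_POOL), n_tr, replace = TRUE)
  pairs <- list(); ref_rows <- list(); tc_rows <- list()
  for (sp in c("Sc", "Cn")) {
    for (i in seq_len(n_tr)) {
      if (stats::runif(1) < config$ortholog_presence) {
        rid <- sprintf("%s_%04d", tolower(sp), i)
        ref_rows[[length(ref_rows) + 1L]] <- data.frame(
          id = rid, species = sp, description = "",
          sequence = mutate_sequence(seqs[i], div$substitution, div$indel),
          stringsAsFactors = FALSE)
        fam <- TC_FAMILY_POOL[fam_rows[i], ]
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          ref_id = rid,
          tc_number = paste(fam$tc_class, "A", i, 1, 1, sep = "."),
          family_name = fam$family_name,
          substrate_group = fam$substrate_group,
          substrate_detail = fam$substrate_detail,
          location = fam$location, stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1L]] <- data.frame(
          si_id = tr_ids[i], ref_id = rid, species = sp,
          stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(config$ref_extra)) {
      rid <- sprintf("%s_only%02d", tolower(sp), j)
      tr <- make_transporter_seq(config)
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        id = rid, species = sp, description = "", sequence = tr$seq,
        stringsAsFactors = FALSE)
      fam <- TC_FAMILY_POOL[sample(nrow(TC_FAMILY_POOL), 1), ]
      tc_rows[[length(tc_rows) + 1L]] <- data.frame(
        ref_id = rid, tc_number = random_tc_number(fam$tc_class),
        family_name = fam$family_name,
        substrate_group = fam$substrate_group,
        substrate_detail = fam$substrate_detail,
        location = fam$location, stringsAsFactors = FALSE)
    }
  }
  ref_records <- do.call(rbind, ref_rows)
  tc_reference <- do.call(rbind, tc_rows)
  ortholog_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(si_id = character(), ref_id = character(),
               species = character(), stringsAsFactors = FALSE)

  n_withheld <- round(n_tr * config$unannotated_fraction)
  withheld <- sort(sample(tr_ids, n_withheld))
  annotated <- setdiff(tr_ids, withheld)
  truth <- list(
    transporter_ids = tr_ids,
    annotated_ids = annotated,
    withheld_ids = withheld,
    decoy_ids = decoy_ids,
    ortholog_pairs = ortholog_pairs,
    ref_only_ids = grep("_only", ref_records$id, value = TRUE),
    tm_planted = stats::setNames(tm_planted, tr_ids)
  )
  list(si_proteome = si, ref_records = ref_records,
       tc_reference = tc_reference, annotated_ids = annotated,
       truth = truth)
}

#' Generate the synthetic functional-annotation table
#'
#' Transporter descriptions carry a sampled transporter keyword stem with
#' probability `annotation_keyword_recall`; decoy descriptions carry one
#' with probability `keyword_fp_rate`. COG letters for transporters are
#' drawn from the transport-associated set with probability
#' `cog_transport_prob`; decoys receive transport-associated letters at
#' the false-positive rate. Lengths and TM counts are derived from the
#' sequences themselves ([predict_tm_table()]), so the table is always
#' consistent with the emitted FASTA.
#'
#' @param proteome the focal proteome data.frame.
#' @param truth truth list from [generate_proteome_suite()].
#' @param config the [sim_config()].
#' @return list: `annotations` (data.frame `protein_id`, `og_id`,
#'   `cog_letters`, `description`, `kog_description`, `length`,
#'   `tm_count`), `truth` with `$keyword_bearers` and `$cog_bearers`
#'   added.
#' @export
generate_annotation_table <- function(proteome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ids <- proteome$id
  is_tr <- ids %in% truth$transporter_ids
  stems <- transporter_keywords()
  nouns <- c("sugar", "amino acid", "metal ion", "phosphate", "potassium",
             "sodium", "oligopeptide", "drug", "sulfate", "ammonium")
  decoy_desc <- c("hypothetical protein", "DNA-binding protein",
                  "ribosomal protein", "protein kinase",
                  "cell wall glycoprotein", "ubiquitin ligase")
  has_kw <- ifelse(is_tr,
                   stats::runif(length(ids)) < config$annotation_keyword_recall,
                   stats::runif(length(ids)) < config$keyword_fp_rate)
  desc <- ifelse(
    has_kw,
    paste("putative", sample(nouns, length(ids), TRUE),
          sample(stems, length(ids), TRUE)),
    sample(decoy_desc, length(ids), TRUE)
  )
  transport_letters <- c("P", "G", "E", "U")
  other_letters <- c("J", "K", "L", "O", "T", "S")
  has_cog <- ifelse(is_tr,
                    stats::runif(length(ids)) < config$cog_transport_prob,
                    stats::runif(length(ids)) < config$keyword_fp_rate)
  cog <- ifelse(has_cog, sample(transport_letters, length(ids), TRUE),
                sample(other_letters, length(ids), TRUE))
  kog <- ifelse(has_cog,
                "inorganic ion transport and metabolism",
                "general function prediction only")
  tm_tab <- predict_tm_table(proteome)
  annotations <- data.frame(
    protein_id = ids,
    og_id = sprintf("OG%05d", sample(99999, length(ids))),
    cog_letters = cog,
    description = desc,
    kog_description = kog,
    length = nchar(proteome$sequence),
    tm_count = tm_tab$tm_count[match(ids, tm_tab$protein_id)],
    stringsAsFactors = FALSE
  )
  truth$keyword_bearers <- ids[has_kw]
  truth$cog_bearers <- ids[has_cog]
  list(annotations = annotations, truth = truth)
}

design_cells <- function(design) {
  cells <- expand.grid(lifestyle = design$lifestyles, salt = design$salt,
                       timepoint = design$timepoints,
                       stringsAsFactors = FALSE)
  cells$cell <- paste(cells$lifestyle, cells$salt, cells$timepoint,
                      sep = ".")
  cells
}

#' Generate the synthetic count matrix, metadata and gene lengths
#'
#' Negative-binomial counts (`variance = mu + dispersion * mu^2`) over the
#' full factorial design, with planted differential expression encoded as
#' multiplicative shifts of the affected condition-cell means: one gene
#' plays the always-salt-induced role (up in the salt-vs-control
#' free-living contrast at every timepoint), one the symbiosis-induced
#' role (strongly up at 7 d and 14 d of symbiosis), and generic +/- 2
#' log2FC effects are scattered over the other contrasts. A few genes are
#' silenced (mean 0) in one condition cell. The truth ledger gains the
#' exact per-comparison expected log2 ratios derived from the constructed
#' cell means, so recall and false-discovery scoring never depends on the
#' realised noise.
#'
#' @param config the [sim_config()].
#' @param truth truth list (from the proteome/annotation steps; may be a
#'   bare `list()` for a counts-only simulation).
#' @return list: `counts` (genes x 36 samples), `meta` (sample metadata
#'   incl. `rin`, `rrna_ratio`), `gene_lengths` (named bp vector),
#'   `truth` with `$de` (data.frame `gene_id`, `comparison_id`,
#'   `true_lfc`, `is_de`), `$silent`, `$ena5_gene`, `$ena1_gene`,
#'   `$qc_fail_samples` added.
#' @export
generate_counts <- function(config, truth = list()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  des <- config$design
  cells <- design_cells(des)
  n_genes <- config$n_genes
  n_prot <- length(truth$transporter_ids %||% character()) +
    length(truth$decoy_ids %||% character())
  gene_ids <- c(truth$transporter_ids, truth$decoy_ids,
                if (n_genes > n_prot)
                  sprintf("bg%04d", seq_len(n_genes - n_prot)))
  gene_ids <- gene_ids[seq_len(min(length(gene_ids), n_genes))]
  n_genes <- length(gene_ids)

  lmr <- log(config$nb_mean_range)
  base_mean <- exp(stats::runif(n_genes, lmr[1], lmr[2]))
  names(base_mean) <- gene_ids

  # choose role genes among planted transporters when available
  pool <- truth$transporter_ids %||% character(0)
  if (length(pool) < 2) pool <- gene_ids
  roles <- sample(pool, 2)
  ena5 <- roles[1]; ena1 <- roles[2]
  base_mean[c(ena5, ena1)] <- pmax(base_mean[c(ena5, ena1)], 150)

  effects <- data.frame(
    gene_id = c(rep(ena5, 3), rep(ena1, 2)),
    contrast = c(rep("NaFLvsFL", 3), rep("SymbvsFL", 2)),
    timepoint = c("1.5h", "7d", "14d", "7d", "14d"),
    lfc = c(rep(config$ena5_lfc, 3), rep(config$ena1_lfc, 2)),
    stringsAsFactors = FALSE
  )
  generic_pool <- setdiff(gene_ids, roles)
  n_gen <- min(config$n_generic_effects, length(generic_pool))
  if (n_gen > 0) {
    g <- sample(generic_pool, n_gen)
    effects <- rbind(effects, data.frame(
      gene_id = g,
      contrast = sample(names(COMPARISON_CONTRASTS), n_gen, TRUE),
      timepoint = sample(TIMEPOINTS, n_gen, TRUE),
      lfc = sample(c(-1, 1), n_gen, TRUE) * config$generic_lfc,
      stringsAsFactors = FALSE
    ))
  }

  # cell means: baseline, shifted multiplicatively in each effect's
  # treatment cell at its timepoint
  mu <- matrix(base_mean, nrow = n_genes, ncol = nrow(cells),
               dimnames = list(gene_ids, cells$cell))
  for (r in seq_len(nrow(effects))) {
    ct <- COMPARISON_CONTRASTS[[effects$contrast[r]]]
    cell <- paste(ct$treat[["lifestyle"]], ct$treat[["salt"]],
                  effects$timepoint[r], sep = ".")
    mu[effects$gene_id[r], cell] <-
      mu[effects$gene_id[r], cell] * 2^effects$lfc[r]
  }
  silent <- data.frame(gene_id = character(), cell = character(),
                       stringsAsFactors = FALSE)
  if (config$n_silent > 0) {
    sg <- sample(setdiff(gene_ids, effects$gene_id), config$n_silent)
    sc <- sample(cells$cell, config$n_silent, replace = TRUE)
    silent <- data.frame(gene_id = sg, cell = sc, stringsAsFactors = FALSE)
    mu[cbind(sg, sc)] <- 0
  }

  meta <- merge(cells, data.frame(replicate = seq_len(des$replicates)))
  meta$sample_id <- paste(meta$cell, meta$replicate, sep = ".r")
  meta <- meta[order(meta$sample_id), ]
  rownames(meta) <- NULL
  v <- config$library_size_variation
  lib_factor <- stats::runif(nrow(meta), 1 - v, 1 + v)
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, n_genes, nrow(meta),
                   dimnames = list(gene_ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    m <- mu[, meta$cell[j]] * lib_factor[j]
    counts[, j] <- stats::rnbinom(n_genes, mu = m, size = size)
  }
  meta$rin <- stats::runif(nrow(meta), 8, 10)
  meta$rrna_ratio <- stats::runif(nrow(meta), 1.6, 2.2)
  qc_fail <- character(0)
  if (config$qc_fail_rate > 0) {
    fail <- stats::runif(nrow(meta)) < config$qc_fail_rate
    meta$rin[fail] <- stats::runif(sum(fail), 5, 7.5)
    qc_fail <- meta$sample_id[fail]
  }
  gene_lengths <- stats::setNames(
    sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
           n_genes, replace = TRUE),
    gene_ids
  )

  # exact expected log2 ratios per comparison from the constructed means
  de <- do.call(rbind, lapply(all_comparisons(), function(cid) {
    cmp <- parse_comparison(cid)
    tcell <- paste(cmp$treat[["lifestyle"]], cmp$treat[["salt"]],
                   cmp$timepoint, sep = ".")
    rcell <- paste(cmp$ref[["lifestyle"]], cmp$ref[["salt"]],
                   cmp$timepoint, sep = ".")
    lfc <- log2((mu[, tcell] + 0.5) / (mu[, rcell] + 0.5))
    data.frame(gene_id = gene_ids, comparison_id = cid,
               true_lfc = unname(lfc), is_de = unname(abs(lfc) >= 1),
               stringsAsFactors = FALSE)
  }))
  truth$de <- de
  truth$planted_effects <- effects
  truth$silent <- silent
  truth$ena5_gene <- ena5
  truth$ena1_gene <- ena1
  truth$qc_fail_samples <- qc_fail
  meta_cols <- c("sample_id", "lifestyle", "salt", "timepoint",
                 "replicate", "rin", "rrna_ratio")
  list(counts = counts, meta = meta[, meta_cols],
       gene_lengths = gene_lengths, truth = truth)
}

#' Generate the full synthetic suite
#'
#' Convenience wrapper chaining [generate_proteome_suite()],
#' [generate_annotation_table()] and [generate_counts()] under one config.
#'
#' @param config a [sim_config()].
#' @return list: `si_proteome`, `ref_records`, `tc_reference`,
#'   `annotated_ids`, `annotations`, `counts`, `meta`, `gene_lengths`,
#'   `truth`.
#' @export
generate_suite <- function(config) {
  prot <- generate_proteome_suite(config)
  ann <- generate_annotation_table(prot$si_proteome, prot$truth, config)
  cnt <- generate_counts(config, ann$truth)
  list(si_proteome = prot$si_proteome, ref_records = prot$ref_records,
       tc_reference = prot$tc_reference, annotated_ids = prot$annotated_ids,
       annotations = ann$annotations, counts = cnt$counts,
       meta = cnt$meta, gene_lengths = cnt$gene_lengths,
       truth = cnt$truth)
}

#' Verify a synthetic suite against its own truth ledger
#'
#' Internal-consistency checks: every truth id exists in the emitted
#' files, planted transporters and decoys partition the proteome,
#' ortholog pairs reference real sequences, the design has the full
#' sample complement, and counts are non-negative integers.
#'
#' @param suite output of [generate_suite()].
#' @return `TRUE` invisibly; errors describe the first inconsistency.
#' @export
verify_truth <- function(suite) {
  tr <- suite$truth
  ids <- suite$si_proteome$id
  stopifnot(
    all(tr$transporter_ids %in% ids),
    all(tr$decoy_ids %in% ids),
    length(intersect(tr$transporter_ids, tr$decoy_ids)) == 0,
    setequal(c(tr$transporter_ids, tr$decoy_ids), ids),
    setequal(c(tr$annotated_ids, tr$withheld_ids), tr$transporter_ids),
    all(tr$ortholog_pairs$si_id %in% tr$transporter_ids),
    all(tr$ortholog_pairs$ref_id %in% suite$ref_records$id),
    all(suite$tc_reference$ref_id %in% suite$ref_records$id),
    nrow(suite$meta) == length(unique(suite$meta$lifestyle)) *
      length(unique(suite$meta$salt)) *
      length(unique(suite$meta$timepoint)) * max(suite$meta$replicate),
    !anyDuplicated(suite$meta[, c("lifestyle", "salt", "timepoint",
                                  "replicate")]),
    all(suite$counts >= 0),
    all(suite$counts == round(suite$counts)),
    setequal(rownames(suite$counts), names(suite$gene_lengths)),
    all(c(tr$ena5_gene, tr$ena1_gene) %in% rownames(suite$counts))
  )
  invisible(TRUE)
}
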