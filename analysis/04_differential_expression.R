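#!/usr/bin/env Rscript

# Step 4 — expression analysis over the 12 condition comparisons.
#
# Sample QC, FPKM, sample-similarity diagnostics (Pearson correlation,
# PCA), DEG calling at padj < 0.05 and |log2FC| >= 1 for every
# comparison, scoring against the planted truth, the transportome
# overlay (unexpressed genes, per-location breakdowns, Venn regions) and
# hierarchical clustering of significant fold-change profiles.

suppressPackageStartupMessages(library(transportomeR))

sim <- "results/sim"
out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cnt_tab <- read.delim(file.path(sim, "counts.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
counts <- as.matrix(cnt_tab[, -1]); rownames(counts) <- cnt_tab[[1]]
meta <- read.delim(file.path(sim, "sample_meta.tsv"),
                   stringsAsFactors = FALSE)
lens_tab <- read.delim(file.path(sim, "gene_lengths.tsv"),
                       stringsAsFactors = FALSE)
gene_lengths <- setNames(lens_tab$length_bp, lens_tab$gene_id)
truth <- jsonlite::read_json(file.path(sim, "truth.json"),
                             simplifyVector = TRUE)
tome <- read.delim("results/transportome/transportome.tsv",
                   stringsAsFactors = FALSE)
tome$protein_id <- as.character(tome$protein_id)

qc <- qc_samples(meta)
message(length(qc$kept), "/", nrow(meta), " samples pass QC",
        if (nrow(qc$rejected)) paste0(" (rejected: ",
          paste(qc$rejected$sample_id, collapse = ", "), ")") else "")
counts <- counts[, qc$kept, drop = FALSE]
meta <- meta[meta$sample_id %in% qc$kept, ]

fpkm <- compute_fpkm(counts, gene_lengths)
write.table(data.frame(gene_id = rownames(fpkm), round(fpkm, 3),
                       check.names = FALSE),
            file.path(out, "fpkm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sim_diag <- sample_similarity(fpkm)
write.table(round(sim_diag$correlation, 4),
            file.path(out, "sample_correlation.tsv"),
            sep = "\t", quote = FALSE)
pcs <- data.frame(sample_id = rownames(sim_diag$pca_scores),
                  round(sim_diag$pca_scores[, 1:2], 3))
write.table(pcs, file.path(out, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of sample variance",
                100 * sim_diag$variance_explained[1],
                100 * sim_diag$variance_explained[2]))

unexpr <- flag_unexpressed(fpkm, meta, gene_ids = tome$protein_id)
message(length(unexpr), " of ", nrow(tome),
        " transportome genes unexpressed in >= 1 condition (planted: ",
        nrow(truth$silent), " silent genes overall)")
writeLines(unexpr, file.path(out, "unexpressed_transporters.txt"))

degs <- call_all_degs(counts, meta)
write.table(degs, file.path(out, "deg_records.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

silent <- truth$silent$gene_id
d <- degs[!(degs$gene_id %in% silent), ]
td <- truth$de[!(truth$de$gene_id %in% silent), ]
m <- match(paste(d$gene_id, d$comparison_id),
           paste(td$gene_id, td$comparison_id))
is_de <- td$is_de[m]; called <- d$status != "ns"
message(sprintf("Planted-DEG recall %.3f, observed FDR %.3f (%d calls)",
                sum(called & is_de) / sum(is_de),
                sum(called & !is_de) / max(sum(called), 1), sum(called)))

# per-comparison up/down cross-tabulation, transporters only
tr_degs <- degs[degs$gene_id %in% tome$protein_id, ]
xtab <- do.call(rbind, lapply(split(tr_degs, tr_degs$comparison_id),
  function(dd) data.frame(comparison = dd$comparison_id[1],
                          n_up = sum(dd$status == "up"),
                          n_down = sum(dd$status == "down"))))
xtab <- xtab[match(all_comparisons(), xtab$comparison), ]
message("Transporter DEGs per comparison:")
print(xtab, row.names = FALSE)
write.table(xtab, file.path(out, "transporter_deg_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Venn over the three 7d comparisons of the salt/symbiosis design
sets <- lapply(c("NaFLvsFL:7d", "SymbvsFL:7d", "NaSymbvsNaFL:7d"),
               function(cid) {
                 dd <- tr_degs[tr_degs$comparison_id == cid, ]
                 dd$gene_id[dd$status != "ns"]
               })
names(sets) <- c("NaFLvsFL", "SymbvsFL", "NaSymbvsNaFL")
venn <- venn_regions(sets)
jsonlite::write_json(as.list(venn), file.path(out, "venn_7d.json"),
                     auto_unbox = TRUE)
message("7d Venn regions: ",
        paste(names(venn), venn, sep = "=", collapse = ", "))

bd <- breakdown_degs(tr_degs, tome, by = "location")
write.table(bd[bd$count > 0, ], file.path(out, "location_breakdown.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# fold-change profile clustering of significant transporter genes
sig_genes <- unique(tr_degs$gene_id[tr_degs$status != "ns"])
if (length(sig_genes) >= 2) {
  fc <- matrix(0, length(sig_genes), length(all_comparisons()),
               dimnames = list(sig_genes, all_comparisons()))
  for (cid in all_comparisons()) {
    dd <- tr_degs[tr_degs$comparison_id == cid, ]
    sig <- dd[dd$status != "ns" & dd$gene_id %in% sig_genes, ]
    fc[sig$gene_id, cid] <- sig$log2fc
  }
  cl <- cluster_fc_profiles(fc, k = min(3, length(sig_genes)))
  writeLines(cl$leaf_order, file.path(out, "profile_leaf_order.txt"))
  message("Clustered ", length(sig_genes),
          " significant transporter profiles into ",
          length(unique(cl$clusters)), " groups")
}
message("Expression outputs written under ", out)
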