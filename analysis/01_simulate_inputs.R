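#!/usr/bin/env Rscript

# Step 1 — simulate the study inputs.
#
# Emits the synthetic focal proteome with planted TM-rich transporters,
# the two reference transportomes (divergent orthologs plus a few
# reference-only transporters), the functional-annotation table, the
# TC-annotated reference, and the 36-sample count matrix with planted
# salt- and symbiosis-responsive genes. Ground truth is serialised
# alongside so later steps can score themselves.

suppressPackageStartupMessages(library(transportomeR))

seed <- as.integer(Sys.getenv("SIM_SEED", "1"))
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

suite <- generate_suite(sim_config(seed))
verify_truth(suite)

write_fasta(suite$si_proteome, file.path(out, "si_proteome.fasta"))
write_fasta(suite$ref_records, file.path(out, "reference_transportomes.fasta"))
writeLines(suite$annotated_ids, file.path(out, "annotated_ids.txt"))
write.table(suite$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(suite$tc_reference, file.path(out, "tc_reference.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = rownames(suite$counts), suite$counts,
                       check.names = FALSE),
            file.path(out, "counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(suite$meta, file.path(out, "sample_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(suite$gene_lengths),
                       length_bp = unname(suite$gene_lengths)),
            file.path(out, "gene_lengths.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(suite$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

message("Simulated (seed ", seed, "): ",
        nrow(suite$si_proteome), " proteins (",
        length(suite$truth$transporter_ids), " planted transporters, ",
        length(suite$truth$withheld_ids), " withheld from annotation), ",
        nrow(suite$ref_records), " reference sequences, ",
        nrow(suite$counts), " genes x ", ncol(suite$counts), " samples.")
message("Inputs written under ", out)
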