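#' Curated fold-change tables shipped with the package
#'
#' Two small curated tables for the *Serendipita indica* transporter
#' study system, in the printed-table convention (log2 fold change, 0 =
#' not significant):
#'
#' * `salt_response_table()` — the 20 transporter genes regulated by
#'   50 mM NaCl under free-living growth, across the salt-vs-control
#'   contrast at 1.5 h, 7 d and 14 d. Includes the Na+ efflux ATPase gene
#'   *SiENA5* (72634), the only gene induced at all three timepoints.
#' * `ion_homeostasis_table()` — transporters relevant to Na+/K+/H+/Ca2+
#'   homeostasis across the six symbiosis-vs-free-living comparisons,
#'   headed by the strongly symbiosis-induced ENA-type ATPase gene
#'   *SiENA1* (72635). Note: 75414 is labelled SiKHA1 in the salt table
#'   but SiKHA2 here (with 75409 as SiKHA1); both tables are preserved
#'   verbatim and the discrepancy is deliberate.
#'
#' @return list with `table` (the full annotated data.frame) and `fc`
#'   (numeric genes x comparisons matrix suitable for
#'   [deg_counts_from_fc_table()] and friends).
#' @export
salt_response_table <- function() {
  read_fixture_fc("salt_freeliving_fc.tsv",
                  meta_cols = c("protein_id", "piin_id", "gene_name",
                                "family", "substrate", "location"))
}

#' @rdname salt_response_table
#' @export
ion_homeostasis_table <- function() {
  read_fixture_fc("ion_homeostasis_fc.tsv",
                  meta_cols = c("protein_id", "gene_name", "family",
                                "substrate", "location"))
}

read_fixture_fc <- function(file, meta_cols) {
  path <- system.file("extdata", file, package = "transportomeR",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character"))
  fc <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  storage.mode(fc) <- "double"
  rownames(fc) <- tab$protein_id
  validate_fc_table(fc)
  list(table = tab, fc = fc)
}
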