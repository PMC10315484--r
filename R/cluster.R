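CLUSTER_CATEGORIES <- c("THREE_WAY", "SI_SC", "SI_CN", "SC_CN",
                        "SC_ONLY", "CN_ONLY", "SI_ONLY", "OTHER")

categorize_species_set <- function(species, roles) {
  s <- unique(species)
  focal <- roles[["focal"]]; ref1 <- roles[["ref1"]]; ref2 <- roles[["ref2"]]
  if (!all(s %in% c(focal, ref1, ref2))) return("OTHER")
  has <- c(focal, ref1, ref2) %in% s
  key <- paste(as.integer(has), collapse = "")
  switch(key,
         "111" = "THREE_WAY",
         "110" = "SI_SC",
         "101" = "SI_CN",
         "011" = "SC_CN",
         "010" = "SC_ONLY",
         "001" = "CN_ONLY",
         "100" = "SI_ONLY",
         "OTHER")
}

#' Cluster proteins by reciprocal (bidirectional) alignment coverage
#'
#' Emulates "bidirectional coverage" sequence clustering: two proteins are
#' linked when their optimal local alignment covers at least `min_coverage`
#' percent of BOTH sequences and reaches at least `min_identity` percent
#' identity; clusters are the connected components of that graph. Each
#' cluster is categorised by the species present among its members — the
#' focal species plus two reference transportomes give eight possible
#' compositions (`THREE_WAY`, `SI_SC`, `SI_CN`, `SC_CN`, `SC_ONLY`,
#' `CN_ONLY`, `SI_ONLY`, `OTHER`).
#'
#' Pairs whose length ratio is below `length_ratio_prefilter` are skipped
#' before alignment, a speed heuristic: reciprocal 80% coverage between
#' sequences of very different lengths would require an implausible number
#' of gap columns under affine penalties.
#'
#' @param records protein record data.frame with `id`, `species`,
#'   `sequence`.
#' @param min_coverage reciprocal coverage threshold, percent, inclusive.
#' @param min_identity identity floor, percent, inclusive; guards against
#'   star-shaped spurious components at small scale.
#' @param species_roles named character vector mapping `focal`, `ref1`,
#'   `ref2` to species tags.
#' @param scoring see [local_align()].
#' @param length_ratio_prefilter skip alignment when
#'   `min(len)/max(len)` falls below this.
#' @return list of clusters, each a list with `members` (data.frame
#'   `protein_id`, `species`) and `category`; a flat membership data.frame
#'   (`cluster_id`, `protein_id`, `species`, `category`) is attached as
#'   attribute `"membership"`.
#' @export
bidirectional_clusters <- function(records, min_coverage = 80,
                                   min_identity = 30,
                                   species_roles = c(focal = "Si",
                                                     ref1 = "Sc",
                                                     ref2 = "Cn"),
                                   scoring = default_scoring(),
                                   length_ratio_prefilter = 0.6) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("id", "species", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate protein ids in clustering input", call. = FALSE)
  }
  n <- nrow(records)
  lens <- nchar(records$sequence)
  edges <- list()
  for (j in seq_len(n)[-1]) {
    i <- seq_len(j - 1L)
    ratio <- pmin(lens[i], lens[j]) / pmax(lens[i], lens[j])
    i <- i[ratio >= length_ratio_prefilter]
    if (!length(i)) next
    hits <- align_batch(records$sequence[i], records$id[i],
                        records$sequence[j], records$id[j], scoring)
    ok <- hits$identity >= min_identity &
      hits$query_coverage >= min_coverage &
      hits$subject_coverage >= min_coverage
    if (any(ok)) {
      edges[[length(edges) + 1L]] <-
        cbind(hits$query_id[ok], hits$subject_id[ok])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = records$id)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(matrix(match(em, records$id), ncol = 2)))
  }
  comp <- igraph::components(g)$membership
  species_of <- stats::setNames(records$species, records$id)
  clusters <- lapply(sort(unique(comp)), function(cid) {
    ids <- sort(names(comp)[comp == cid])
    members <- data.frame(protein_id = ids,
                          species = unname(species_of[ids]),
                          stringsAsFactors = FALSE)
    list(members = members,
         category = categorize_species_set(members$species, species_roles))
  })
  membership <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    data.frame(cluster_id = k,
               protein_id = clusters[[k]]$members$protein_id,
               species = clusters[[k]]$members$species,
               category = clusters[[k]]$category,
               stringsAsFactors = FALSE)
  }))
  attr(clusters, "membership") <- membership
  clusters
}
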