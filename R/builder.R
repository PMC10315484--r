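#' The transporter/channel keyword stems
#'
#' The fourteen keyword stems screened against functional-annotation free
#' text to flag candidate transporters: transport(er), efflux, uptake,
#' exporter, importer, pump, permease, exchange(r), channel, carrier,
#' influx, symporter, antiporter, translocator. Matching is
#' case-insensitive substring matching, so the stem `transport` also
#' matches `transporter` and `exchange` also matches `exchanger`.
#'
#' @return character vector of stems.
#' @export
transporter_keywords <- function() {
  c("transport", "efflux", "uptake", "exporter", "importer", "pump",
    "permease", "exchange", "channel", "carrier", "influx", "symporter",
    "antiporter", "translocator")
}

EVIDENCE_SOURCES <- c("annotated", "cluster_accept", "rescue_blast",
                      "eggnog_keyword", "eggnog_cog")

evidence_frame <- function(protein_id = character(), source = character(),
                           detail = character()) {
  stopifnot(all(source %in% EVIDENCE_SOURCES))
  data.frame(protein_id = protein_id, source = source, detail = detail,
             stringsAsFactors = FALSE)
}

#' Accept cluster members into the transportome and collect rescue baits
#'
#' Members of the focal species in clusters that also contain at least one
#' reference species (`THREE_WAY`, `SI_SC`, `SI_CN`) are accepted into the
#' transportome directly. Clusters with no focal-species member (`SC_CN`,
#' `SC_ONLY`, `CN_ONLY`) contribute their reference members as baits for a
#' homology rescue against the full focal proteome. `SI_ONLY` clusters add
#' nothing here: their members are already part of the annotated baseline
#' that the final union step carries.
#'
#' @param clusters output of [bidirectional_clusters()].
#' @param annotated_si_ids ids of the annotated focal-species transporters.
#' @param species_roles as in [bidirectional_clusters()].
#' @return list with `accepted` (evidence data.frame, source
#'   `cluster_accept`) and `rescue_query_ids` (character).
#' @export
accept_from_clusters <- function(clusters, annotated_si_ids,
                                 species_roles = c(focal = "Si",
                                                   ref1 = "Sc",
                                                   ref2 = "Cn")) {
  focal <- species_roles[["focal"]]
  known <- unname(species_roles)
  accepted <- list(); rescue <- character()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    bad <- setdiff(unique(cl$members$species), known)
    if (length(bad)) {
      stop("unknown species tag in cluster ", k, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (cl$category %in% c("THREE_WAY", "SI_SC", "SI_CN")) {
      si <- cl$members$protein_id[cl$members$species == focal]
      accepted[[length(accepted) + 1L]] <- evidence_frame(
        protein_id = si,
        source = rep("cluster_accept", length(si)),
        detail = rep(paste0("cluster_", k, ":", cl$category), length(si))
      )
    } else if (cl$category %in% c("SC_CN", "SC_ONLY", "CN_ONLY")) {
      rescue <- c(rescue, cl$members$protein_id[cl$members$species != focal])
    }
  }
  acc <- if (length(accepted)) do.call(rbind, accepted) else evidence_frame()
  list(accepted = acc, rescue_query_ids = sort(unique(rescue)))
}

#' Rescue non-annotated transporters by homology to reference baits
#'
#' Reference transporters with no counterpart in the annotated focal set
#' are aligned against the complete focal proteome; hits passing the
#' identity/coverage filter whose subject is not already annotated become
#' rescue candidates.
#'
#' @param rescue_queries protein record data.frame of bait sequences.
#' @param si_proteome protein record data.frame, the full focal proteome.
#' @param already_annotated_ids ids excluded from candidacy.
#' @param min_identity,min_coverage strict percent thresholds
#'   (identity > 25, query coverage > 50 by default).
#' @param scoring see [local_align()].
#' @return evidence data.frame with source `rescue_blast`; `detail` is the
#'   bait id.
#' @export
rescue_candidates <- function(rescue_queries, si_proteome,
                              already_annotated_ids, min_identity = 25,
                              min_coverage = 50,
                              scoring = default_scoring()) {
  if (is.null(rescue_queries) || nrow(rescue_queries) == 0) {
    return(evidence_frame())
  }
  overlap <- intersect(rescue_queries$id, si_proteome$id)
  if (length(overlap)) {
    stop("rescue query ids overlap the focal proteome: ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  hits <- search_homologs(rescue_queries, si_proteome,
                          min_identity = min_identity,
                          min_coverage = min_coverage, scoring = scoring)
  hits <- hits[!(hits$subject_id %in% already_annotated_ids), , drop = FALSE]
  if (!nrow(hits)) return(evidence_frame())
  hits <- hits[order(hits$subject_id, -hits$score, hits$query_id), ]
  evidence_frame(protein_id = hits$subject_id,
                 source = rep("rescue_blast", nrow(hits)),
                 detail = hits$query_id)
}

match_stems <- function(text, stems) {
  # returns list (per text) of matched stems; case-insensitive substring
  low <- tolower(text)
  lapply(low, function(t) stems[vapply(stems, grepl, TRUE, x = t,
                                       fixed = TRUE)])
}

#' Screen annotation descriptions for transporter keywords
#'
#' Case-insensitive substring match of each keyword stem against the
#' free-text `description` column; one evidence row per (protein, matched
#' stem). Proteins in `exclude_ids` (the already-annotated set) are
#' skipped.
#'
#' @param annotations annotation data.frame with `protein_id` and
#'   `description`.
#' @param keywords stems, default [transporter_keywords()].
#' @param exclude_ids ids to skip.
#' @return evidence data.frame with source `eggnog_keyword`; `detail` is
#'   the matched stem.
#' @export
screen_keywords <- function(annotations, keywords = transporter_keywords(),
                            exclude_ids = character()) {
  ann <- annotations[!(annotations$protein_id %in% exclude_ids), ,
                     drop = FALSE]
  if (!nrow(ann)) return(evidence_frame())
  ms <- match_stems(ann$description, keywords)
  n <- lengths(ms)
  evidence_frame(protein_id = rep(ann$protein_id, n),
                 source = rep("eggnog_keyword", sum(n)),
                 detail = unlist(ms, use.names = FALSE))
}

#' Screen COG annotations for transport-associated candidates
#'
#' Flags proteins whose orthologous-group (KOG/COG) description matches a
#' transporter keyword stem, or whose COG category letter is in the
#' configured transport-associated set. Proteins already annotated or
#' already emitted by the keyword screen are excluded via `exclude_ids`.
#'
#' @param annotations annotation data.frame with `protein_id`,
#'   `cog_letters` and `kog_description`.
#' @param transport_cog_letters COG category letters treated as
#'   transport-associated; the default covers inorganic ion (P),
#'   carbohydrate (G) and amino-acid (E) transport and metabolism plus
#'   intracellular trafficking and secretion (U).
#' @param keywords stems for the description-text route.
#' @param exclude_ids ids to skip.
#' @return evidence data.frame with source `eggnog_cog`; `detail` is the
#'   matched stem or `cog:<letter>`.
#' @export
screen_cog <- function(annotations,
                       transport_cog_letters = c("P", "G", "E", "U"),
                       keywords = transporter_keywords(),
                       exclude_ids = character()) {
  ann <- annotations[!(annotations$protein_id %in% exclude_ids), ,
                     drop = FALSE]
  if (!nrow(ann)) return(evidence_frame())
  ms <- match_stems(ann$kog_description %||% "", keywords)
  letters_hit <- lapply(strsplit(ann$cog_letters %||% "", ""), function(l) {
    paste0("cog:", intersect(l, transport_cog_letters))
  })
  details <- mapply(function(a, b) unique(c(a, b)), ms, letters_hit,
                    SIMPLIFY = FALSE)
  details <- lapply(details, function(d) d[nzchar(d) & d != "cog:"])
  n <- lengths(details)
  evidence_frame(protein_id = rep(ann$protein_id, n),
                 source = rep("eggnog_cog", sum(n)),
                 detail = unlist(details, use.names = FALSE))
}

#' Revise candidate transporters by length, TM count and annotation text
#'
#' Reconstruction of the manual revision that winnows screened candidates:
#' a candidate is kept iff its length lies within `rules$len_range` AND it
#' either has at least `rules$min_tm` predicted transmembrane segments or
#' its KOG/description text matches an accessory-factor allowlist (soluble
#' subunits and regulators of transport complexes carry no TM but belong
#' in the inventory). Every decision is returned with the failing rule.
#'
#' @param candidate_ids character vector of candidate protein ids.
#' @param annotations annotation data.frame (`protein_id`, `length`,
#'   `description`, `kog_description`).
#' @param tm_table TM table (`protein_id`, `tm_count`); missing ids count
#'   as unknown (0 TM).
#' @param rules list: `min_tm` (default 1), `len_range` (default
#'   c(50, 5000)), `accessory_terms` (character allowlist).
#' @return data.frame `protein_id`, `kept`, `reason` (`"ok"`, `"tm"`,
#'   `"length"`, `"unknown_length"`).
#' @export
revise_candidates <- function(candidate_ids, annotations, tm_table,
                              rules = list()) {
  rules <- utils::modifyList(list(
    min_tm = 1,
    len_range = c(50, 5000),
    accessory_terms = c("accessory", "auxiliary", "regulatory subunit",
                        "transport complex subunit", "chaperone")
  ), rules)
  ids <- unique(candidate_ids)
  len <- annotations$length[match(ids, annotations$protein_id)]
  tm <- tm_table$tm_count[match(ids, tm_table$protein_id)]
  txt <- paste(annotations$description[match(ids, annotations$protein_id)],
               annotations$kog_description[match(ids, annotations$protein_id)])
  accessory <- vapply(tolower(txt), function(t) {
    any(vapply(tolower(rules$accessory_terms), grepl, TRUE, x = t,
               fixed = TRUE))
  }, TRUE, USE.NAMES = FALSE)
  reason <- rep("ok", length(ids))
  reason[is.na(len)] <- "unknown_length"
  in_len <- !is.na(len) & len >= rules$len_range[1] & len <= rules$len_range[2]
  reason[!is.na(len) & !in_len] <- "length"
  tm_ok <- !is.na(tm) & tm >= rules$min_tm
  fail_tm <- in_len & !tm_ok & !accessory
  reason[fail_tm] <- "tm"
  data.frame(protein_id = ids, kept = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Assign a TC number from reference hits
#'
#' Picks, among alignment hits of one protein against a TC-annotated
#' reference set, the best-scoring hit passing the identity/coverage
#' filter, breaking ties by higher identity and then lexicographic subject
#' id. The hit's TC number and family transfer to the protein. With no
#' passing hit the sentinel `9.B.0.0.0` is assigned (TC class 9:
#' incompletely characterized).
#'
#' @param entry_id the protein id.
#' @param tc_hits AlignmentHit data.frame of this protein's hits
#'   (query side = the protein).
#' @param tc_reference data.frame `ref_id`, `tc_number`, `family_name`.
#' @param min_identity,min_coverage strict percent thresholds.
#' @return one-row data.frame `protein_id`, `tc_number`, `family_name`,
#'   `tc_ref_id`, `note`.
#' @export
assign_tc <- function(entry_id, tc_hits, tc_reference, min_identity = 25,
                      min_coverage = 50) {
  bad <- !vapply(tc_reference$tc_number, function(x) {
    tryCatch({ parse_tc(x); TRUE }, error = function(e) FALSE)
  }, TRUE, USE.NAMES = FALSE)
  if (any(bad)) {
    stop("malformed TC number in reference record '",
         tc_reference$ref_id[bad][1], "': ",
         tc_reference$tc_number[bad][1], call. = FALSE)
  }
  hits <- tc_hits[tc_hits$query_id == entry_id &
                    tc_hits$identity > min_identity &
                    tc_hits$query_coverage > min_coverage, , drop = FALSE]
  hits <- hits[hits$subject_id %in% tc_reference$ref_id, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(protein_id = entry_id, tc_number = "9.B.0.0.0",
                      family_name = "Unassigned", tc_ref_id = NA_character_,
                      note = "no passing TC reference hit",
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(-hits$score, -hits$identity, hits$subject_id), ]
  best <- hits[1, ]
  ref <- tc_reference[match(best$subject_id, tc_reference$ref_id), ]
  data.frame(protein_id = entry_id, tc_number = ref$tc_number,
             family_name = ref$family_name, tc_ref_id = ref$ref_id,
             note = "", stringsAsFactors = FALSE)
}

#' Assemble the transportome
#'
#' Unions the annotated baseline with the accepted new candidates,
#' deduplicates by protein id, and attaches per-entry provenance
#' (annotated / cluster acceptance / homology rescue / keyword screen /
#' COG screen, in that display precedence), TC number, family, TM count
#' and length. Output is sorted by protein id.
#'
#' @param annotated_ids character, the annotated baseline.
#' @param accepted_new_ids character, candidates surviving revision.
#' @param evidence evidence data.frame pooled from all sources.
#' @param tc_assignments data.frame from [assign_tc()] rows.
#' @param tm_table TM table (`protein_id`, `tm_count`).
#' @param lengths data.frame `protein_id`, `length` (conflicting lengths
#'   for one id are an error).
#' @param alt_ids optional data.frame `protein_id`, `alt_id`.
#' @return data.frame of class `transportome`: `protein_id`, `alt_id`,
#'   `tc_number`, `tc_class`, `family_name`, `tm_count`, `length`,
#'   `substrate_group`, `substrate_detail`, `location`, and list-column
#'   `provenance` (data.frame `source`, `detail` per entry).
#' @export
build_transportome <- function(annotated_ids, accepted_new_ids, evidence,
                               tc_assignments, tm_table, lengths,
                               alt_ids = NULL) {
  if (anyDuplicated(lengths$protein_id)) {
    dup <- lengths$protein_id[duplicated(lengths$protein_id)]
    conf <- unique(dup[vapply(dup, function(d) {
      length(unique(lengths$length[lengths$protein_id == d])) > 1
    }, TRUE)])
    if (length(conf)) {
      stop("conflicting lengths for protein id(s): ",
           paste(utils::head(conf, 3), collapse = ", "), call. = FALSE)
    }
    lengths <- lengths[!duplicated(lengths$protein_id), ]
  }
  ids <- sort(unique(c(annotated_ids, accepted_new_ids)))
  ev <- rbind(
    evidence_frame(protein_id = annotated_ids,
                   source = rep("annotated", length(annotated_ids)),
                   detail = rep("annotated baseline", length(annotated_ids))),
    evidence
  )
  ev <- ev[ev$protein_id %in% ids, , drop = FALSE]
  ev$source <- factor(ev$source, levels = EVIDENCE_SOURCES)
  ev <- ev[order(ev$protein_id, ev$source, ev$detail), ]
  ev <- ev[!duplicated(ev[, c("protein_id", "source", "detail")]), ]
  ev$source <- as.character(ev$source)
  prov <- split(ev[, c("source", "detail")], ev$protein_id)
  missing_prov <- setdiff(ids, names(prov))
  if (length(missing_prov)) {
    stop("entries without provenance: ",
         paste(utils::head(missing_prov, 3), collapse = ", "), call. = FALSE)
  }
  tc <- tc_assignments[match(ids, tc_assignments$protein_id), ]
  tc_number <- ifelse(is.na(tc$tc_number), "9.B.0.0.0", tc$tc_number)
  out <- data.frame(
    protein_id = ids,
    alt_id = if (is.null(alt_ids)) NA_character_ else
      alt_ids$alt_id[match(ids, alt_ids$protein_id)],
    tc_number = tc_number,
    tc_class = vapply(tc_number, function(x) parse_tc(x)$tc_class, ""),
    family_name = ifelse(is.na(tc$family_name), "Unassigned",
                         tc$family_name),
    tm_count = {
      tmc <- tm_table$tm_count[match(ids, tm_table$protein_id)]
      as.integer(ifelse(is.na(tmc), 0L, tmc))
    },
    length = lengths$length[match(ids, lengths$protein_id)],
    substrate_group = NA_character_,
    substrate_detail = NA_character_,
    location = NA_character_,
    stringsAsFactors = FALSE
  )
  out$provenance <- unname(prov[out$protein_id])
  rownames(out) <- NULL
  class(out) <- c("transportome", "data.frame")
  out
}

#' Run the full transportome construction pipeline
#'
#' End-to-end driver: cluster the annotated focal transporters with the
#' reference transportomes, accept focal members of mixed clusters,
#' rescue non-annotated homologs of reference-only clusters against the
#' complete proteome, screen the functional-annotation table by keyword
#' and COG, revise the pooled candidates by length/TM/annotation, assign
#' TC numbers by alignment to the TC-annotated reference set, and
#' assemble the final inventory.
#'
#' @param si_proteome full focal proteome (protein record data.frame,
#'   species tag equal to `species_roles[["focal"]]`).
#' @param annotated_ids annotated transporter ids within `si_proteome`.
#' @param ref_records reference transportome records (both reference
#'   species in one data.frame).
#' @param annotations functional-annotation table.
#' @param tc_reference data.frame `ref_id`, `tc_number`, `family_name`
#'   (+ optional `substrate_group`, `substrate_detail`, `location`);
#'   `ref_id` must index sequences in `ref_records`.
#' @param tm_table optional precomputed TM table; computed with
#'   [predict_tm_table()] when `NULL`.
#' @param species_roles as in [bidirectional_clusters()].
#' @param revision_rules see [revise_candidates()].
#' @param scoring see [local_align()].
#' @return list: `transportome`, plus intermediates `clusters`,
#'   `accepted`, `rescued`, `keyword_hits`, `cog_hits`, `revision`,
#'   `tc_assignments`, `tm_table`.
#' @export
build_transportome_pipeline <- function(si_proteome, annotated_ids,
                                        ref_records, annotations,
                                        tc_reference, tm_table = NULL,
                                        species_roles = c(focal = "Si",
                                                          ref1 = "Sc",
                                                          ref2 = "Cn"),
                                        revision_rules = list(),
                                        scoring = default_scoring()) {
  annotated_recs <- si_proteome[si_proteome$id %in% annotated_ids, ,
                                drop = FALSE]
  clusters <- bidirectional_clusters(
    rbind(annotated_recs, ref_records),
    species_roles = species_roles, scoring = scoring
  )
  acc <- accept_from_clusters(clusters, annotated_ids, species_roles)
  rescue_queries <- ref_records[ref_records$id %in% acc$rescue_query_ids, ,
                                drop = FALSE]
  rescued <- rescue_candidates(rescue_queries, si_proteome, annotated_ids,
                               scoring = scoring)
  kw <- screen_keywords(annotations, exclude_ids = annotated_ids)
  cog <- screen_cog(annotations,
                    exclude_ids = c(annotated_ids,
                                    unique(kw$protein_id),
                                    unique(rescued$protein_id)))
  if (is.null(tm_table)) tm_table <- predict_tm_table(si_proteome)
  candidate_ids <- unique(c(rescued$protein_id, kw$protein_id,
                            cog$protein_id))
  revision <- revise_candidates(candidate_ids, annotations, tm_table,
                                revision_rules)
  accepted_new <- revision$protein_id[revision$kept]
  member_ids <- sort(unique(c(annotated_ids, accepted_new)))
  members <- si_proteome[match(member_ids, si_proteome$id), , drop = FALSE]
  ref_seqs <- ref_records[ref_records$id %in% tc_reference$ref_id, ,
                          drop = FALSE]
  tc_hits <- if (nrow(ref_seqs)) {
    search_homologs(members, ref_seqs, min_identity = 0, min_coverage = 0,
                    scoring = scoring, drop_self = FALSE)
  } else {
    data.frame(query_id = character(), subject_id = character(),
               identity = numeric(), query_coverage = numeric(),
               subject_coverage = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  }
  tc_assignments <- do.call(rbind, lapply(member_ids, function(id) {
    assign_tc(id, tc_hits, tc_reference)
  }))
  lengths <- data.frame(protein_id = si_proteome$id,
                        length = nchar(si_proteome$sequence),
                        stringsAsFactors = FALSE)
  transportome <- build_transportome(
    annotated_ids = annotated_ids,
    accepted_new_ids = accepted_new,
    evidence = rbind(acc$accepted, rescued, kw, cog),
    tc_assignments = tc_assignments,
    tm_table = tm_table,
    lengths = lengths
  )
  list(transportome = transportome, clusters = clusters,
       accepted = acc$accepted, rescued = rescued, keyword_hits = kw,
       cog_hits = cog, revision = revision,
       tc_assignments = tc_assignments, tm_table = tm_table)
}
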