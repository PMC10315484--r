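make_cluster <- function(ids, species, category) {
  list(members = data.frame(protein_id = ids, species = species,
                            stringsAsFactors = FALSE),
       category = category)
}

test_that("cluster acceptance follows the category rules exactly", {
  # single mixed cluster: focal member accepted, nothing to rescue
  one <- list(make_cluster(c("si_a", "sc_b"), c("Si", "Sc"), "SI_SC"))
  got <- accept_from_clusters(one, "si_a")
  expect_equal(got$accepted$protein_id, "si_a")
  expect_equal(got$rescue_query_ids, character(0))

  # reference-only cluster: no acceptance, member becomes a rescue bait
  sc_only <- list(make_cluster("sc_x", "Sc", "SC_ONLY"))
  got <- accept_from_clusters(sc_only, character(0))
  expect_equal(nrow(got$accepted), 0)
  expect_equal(got$rescue_query_ids, "sc_x")

  # mixed fixture over all categories vs a hand-enumerated oracle
  fixture <- list(
    make_cluster(c("si1", "sc1", "cn1"), c("Si", "Sc", "Cn"), "THREE_WAY"),
    make_cluster(c("si2", "sc2"), c("Si", "Sc"), "SI_SC"),
    make_cluster(c("si3", "cn3"), c("Si", "Cn"), "SI_CN"),
    make_cluster(c("sc4", "cn4"), c("Sc", "Cn"), "SC_CN"),
    make_cluster("sc5", "Sc", "SC_ONLY"),
    make_cluster("cn6", "Cn", "CN_ONLY"),
    make_cluster("si7", "Si", "SI_ONLY")
  )
  got <- accept_from_clusters(fixture, c("si1", "si2", "si3", "si7"))
  expect_setequal(got$accepted$protein_id, c("si1", "si2", "si3"))
  expect_setequal(got$rescue_query_ids, c("sc4", "cn4", "sc5", "cn6"))

  bad <- list(make_cluster("x1", "Xx", "OTHER"))
  expect_error(accept_from_clusters(bad, character(0)), "unknown species")
})

test_that("homology rescue retrieves planted unannotated orthologs only", {
  set.seed(91)
  hidden <- random_protein(150)        # unannotated focal transporter
  bait <- mutate_exact(hidden, 0.35)   # reference ortholog, 35% divergence
  proteome <- data.frame(
    id = c("si_hidden", "si_known", "si_noise"),
    species = "Si", description = "",
    sequence = c(hidden, random_protein(140), random_protein(130)),
    stringsAsFactors = FALSE
  )
  baits <- data.frame(id = "sc_bait", species = "Sc", description = "",
                      sequence = bait, stringsAsFactors = FALSE)

  got <- rescue_candidates(baits, proteome, already_annotated_ids = "si_known")
  expect_equal(got$protein_id, "si_hidden")
  expect_equal(got$source, "rescue_blast")
  expect_equal(got$detail, "sc_bait")

  # the same protein already annotated is not emitted
  got2 <- rescue_candidates(baits, proteome,
                            already_annotated_ids = c("si_known", "si_hidden"))
  expect_equal(nrow(got2), 0)

  # bait unrelated to everything -> empty
  lone <- data.frame(id = "sc_lone", species = "Sc", description = "",
                     sequence = random_protein(150), stringsAsFactors = FALSE)
  expect_equal(nrow(rescue_candidates(lone, proteome, character(0))), 0)

  # id-space collision is a hard error
  clash <- baits; clash$id <- "si_known"
  expect_error(rescue_candidates(clash, proteome, character(0)), "overlap")
})

test_that("keyword screen matches stems case-insensitively and logs them", {
  ann <- data.frame(
    protein_id = c("a", "b", "c", "d", "e"),
    og_id = "OG1", cog_letters = "S",
    description = c("putative sugar Transporter", "channel-forming toxin",
                    "hypothetical protein", "drug efflux pump",
                    "annotated permease"),
    kog_description = "", length = 300L,
    stringsAsFactors = FALSE
  )
  got <- screen_keywords(ann, exclude_ids = "e")
  expect_setequal(unique(got$protein_id), c("a", "b", "d"))
  expect_true("transport" %in% got$detail[got$protein_id == "a"])
  expect_true("channel" %in% got$detail[got$protein_id == "b"])
  # "d" matches two stems -> two evidence rows
  expect_setequal(got$detail[got$protein_id == "d"], c("efflux", "pump"))
  # post-hoc grep invariant: every matched stem occurs in its description
  for (r in seq_len(nrow(got))) {
    desc <- ann$description[ann$protein_id == got$protein_id[r]]
    expect_true(grepl(got$detail[r], desc, ignore.case = TRUE))
  }
})

test_that("COG screen uses letters and KOG text, deduplicated downstream", {
  ann <- data.frame(
    protein_id = c("p", "q", "r", "s"),
    og_id = "OG1",
    cog_letters = c("P", "S", "KT", "G"),
    description = "hypothetical protein",
    kog_description = c("", "inorganic ion transport and metabolism",
                        "transcription", ""),
    length = 300L, stringsAsFactors = FALSE
  )
  got <- screen_cog(ann)
  expect_setequal(unique(got$protein_id), c("p", "q", "s"))
  expect_equal(got$detail[got$protein_id == "p"], "cog:P")
  expect_true("transport" %in% got$detail[got$protein_id == "q"])
  # exclusion (already annotated or already keyword-screened)
  expect_false("s" %in% screen_cog(ann, exclude_ids = "s")$protein_id)
})

test_that("revision keeps TM-bearing or accessory candidates within length bounds", {
  ann <- data.frame(
    protein_id = c("tm6", "tm0", "acc", "short", "long"),
    og_id = "OG1", cog_letters = "P",
    description = c("transporter", "transporter", "accessory subunit",
                    "transporter", "transporter"),
    kog_description = "", length = c(500L, 400L, 350L, 30L, 6000L),
    stringsAsFactors = FALSE
  )
  tm <- data.frame(protein_id = c("tm6", "tm0", "acc", "short", "long"),
                   tm_count = c(6L, 0L, 0L, 4L, 8L),
                   stringsAsFactors = FALSE)
  got <- revise_candidates(ann$protein_id, ann, tm)
  expect_equal(got$kept, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(got$reason[got$protein_id == "tm0"], "tm")
  expect_equal(got$reason[got$protein_id == "short"], "length")
  expect_equal(got$reason[got$protein_id == "long"], "length")

  # planted mixture: all TM-positive truths kept, all TM-zero decoys dropped
  set.seed(13)
  n <- 40
  ids <- sprintf("c%02d", 1:n)
  truth_tm <- rep(c(TRUE, FALSE), n / 2)
  ann2 <- data.frame(protein_id = ids, og_id = "OG", cog_letters = "P",
                     description = "candidate", kog_description = "",
                     length = sample(100:900, n), stringsAsFactors = FALSE)
  tm2 <- data.frame(protein_id = ids,
                    tm_count = ifelse(truth_tm, sample(1:12, n, TRUE), 0L),
                    stringsAsFactors = FALSE)
  got2 <- revise_candidates(ids, ann2, tm2)
  expect_equal(got2$kept, truth_tm)   # precision and recall 1 on truth
})

test_that("TC assignment transfers the best passing hit deterministically", {
  ref <- data.frame(ref_id = c("tc_a", "tc_b"),
                    tc_number = c("2.A.1.1.5", "3.A.3.1.1"),
                    family_name = c("MFS", "P-ATPase"),
                    stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id = "x", subject_id = c("tc_a", "tc_b"),
    identity = c(60, 40), query_coverage = c(90, 90),
    subject_coverage = c(90, 90), score = c(200, 150),
    stringsAsFactors = FALSE
  )
  got <- assign_tc("x", hits, ref)
  expect_equal(got$tc_number, "2.A.1.1.5")
  expect_equal(got$family_name, "MFS")

  # no passing hit -> sentinel, flagged
  weak <- transform(hits, identity = c(20, 10))
  got <- assign_tc("x", weak, ref)
  expect_equal(got$tc_number, "9.B.0.0.0")
  expect_match(got$note, "no passing")

  # equal scores: higher identity wins; equal identity: lexicographic id —
  # and the choice is stable across repeated calls
  tie <- transform(hits, score = 200, identity = 50)
  first <- assign_tc("x", tie, ref)
  expect_equal(first$tc_ref_id, "tc_a")
  for (i in 1:5) expect_identical(assign_tc("x", tie, ref), first)

  bad_ref <- data.frame(ref_id = "oops", tc_number = "2.A",
                        family_name = "?", stringsAsFactors = FALSE)
  expect_error(assign_tc("x", hits, bad_ref), "oops")
})

test_that("transportome assembly unions, deduplicates, and keeps provenance", {
  n_ann <- 684; n_new <- 80
  ann_ids <- sprintf("a%04d", seq_len(n_ann))
  new_ids <- sprintf("n%04d", seq_len(n_new))
  all_ids <- c(ann_ids, new_ids)
  ev <- data.frame(protein_id = new_ids, source = "rescue_blast",
                   detail = "bait", stringsAsFactors = FALSE)
  tc <- data.frame(protein_id = all_ids, tc_number = "2.A.1.1.5",
                   family_name = "MFS", tc_ref_id = "r", note = "",
                   stringsAsFactors = FALSE)
  tm <- data.frame(protein_id = all_ids, tm_count = 6L,
                   stringsAsFactors = FALSE)
  len <- data.frame(protein_id = all_ids, length = 500L,
                    stringsAsFactors = FALSE)
  tome <- build_transportome(ann_ids, new_ids, ev, tc, tm, len)
  expect_equal(nrow(tome), 764)   # 684 annotated + 80 new, disjoint
  expect_equal(tome$protein_id, sort(all_ids))
  expect_true(all(lengths(tome$provenance) > 0))
  srcs <- unique(unlist(lapply(tome$provenance, `[[`, "source")))
  expect_true(all(srcs %in% c("annotated", "cluster_accept", "rescue_blast",
                              "eggnog_keyword", "eggnog_cog")))

  # overlap between screened and rescued: counted once, both rows kept
  ev2 <- rbind(ev, data.frame(protein_id = new_ids[1],
                              source = "eggnog_keyword", detail = "pump",
                              stringsAsFactors = FALSE))
  tome2 <- build_transportome(ann_ids, new_ids, ev2, tc, tm, len)
  expect_equal(nrow(tome2), 764)
  prov1 <- tome2$provenance[[match(new_ids[1], tome2$protein_id)]]
  expect_setequal(prov1$source, c("rescue_blast", "eggnog_keyword"))
  # display precedence: rescue before keyword evidence
  expect_equal(prov1$source[1], "rescue_blast")

  # conflicting lengths are a hard error
  len_bad <- rbind(len, data.frame(protein_id = ann_ids[1], length = 99L))
  expect_error(build_transportome(ann_ids, new_ids, ev, tc, tm, len_bad),
               "conflicting lengths")
})

test_that("transportome build is idempotent", {
  ann_ids <- sprintf("a%02d", 1:10)
  new_ids <- sprintf("n%02d", 1:3)
  ev <- data.frame(protein_id = new_ids, source = "eggnog_keyword",
                   detail = "carrier", stringsAsFactors = FALSE)
  ids <- c(ann_ids, new_ids)
  tc <- data.frame(protein_id = ids, tc_number = "1.A.1.1.1",
                   family_name = "VIC", tc_ref_id = "r", note = "",
                   stringsAsFactors = FALSE)
  tm <- data.frame(protein_id = ids, tm_count = 2L, stringsAsFactors = FALSE)
  len <- data.frame(protein_id = ids, length = 420L, stringsAsFactors = FALSE)
  tome <- build_transportome(ann_ids, new_ids, ev, tc, tm, len)

  # rebuild from the built object's own components
  ev_back <- do.call(rbind, lapply(seq_len(nrow(tome)), function(i) {
    cbind(protein_id = tome$protein_id[i], tome$provenance[[i]])
  }))
  ev_back <- ev_back[ev_back$source != "annotated", ]
  rebuilt <- build_transportome(
    annotated_ids = ann_ids,
    accepted_new_ids = setdiff(tome$protein_id, ann_ids),
    evidence = ev_back,
    tc_assignments = tome[, c("protein_id", "tc_number", "family_name")],
    tm_table = tome[, c("protein_id", "tm_count")],
    lengths = tome[, c("protein_id", "length")]
  )
  expect_equal(rebuilt, tome)
})
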