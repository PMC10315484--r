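test_that("FASTA reading parses headers, enforces unique ids, round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 putative transporter", "MKT", ">p2", "mktay"), f)
  recs <- read_fasta(f, species = "Si")
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$description, c("putative transporter", ""))
  expect_equal(recs$sequence, c("MKT", "MKTAY"))  # uppercased on ingest

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKT", ">p1", "AAA"), dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")

  out <- withr::local_tempfile(fileext = ".fasta")
  set.seed(11)
  tab <- data.frame(
    id = paste0("q", 1:5),
    description = c("alpha beta", "", "x", "", "z"),
    sequence = replicate(5, random_protein(sample(10:80, 1))),
    stringsAsFactors = FALSE
  )
  write_fasta(tab, out)
  back <- read_fasta(out)
  expect_equal(back$id, tab$id)
  expect_equal(back$sequence, tab$sequence)
})

test_that("ORF translation counts residues and flags internal stops", {
  expect_equal(as.character(translate_orf("ATGAAA")), "MK")
  expect_error(translate_orf("ATGAA"), "divisible")

  set.seed(4)
  sense <- c("TTT", "CTT", "ATG", "GTT", "TCT", "CCT", "ACT", "GCT",
             "TAT", "CAT", "AAA", "GAT", "TGT", "TGG", "CGT", "GGT")
  orf_of <- function(n_nt) paste(sample(sense, n_nt / 3, TRUE), collapse = "")
  expect_equal(nchar(translate_orf(orf_of(2025))), 675)
  expect_equal(nchar(translate_orf(orf_of(1953))), 651)

  # trailing stop removed and not counted; internal stop flagged
  expect_equal(nchar(suppressWarnings(translate_orf(paste0(orf_of(2025), "TAA")))), 675)
  expect_false(attr(translate_orf(orf_of(300)), "internal_stop"))
  expect_warning(got <- translate_orf("ATGTAAATG"), "internal stop")
  expect_true(attr(got, "internal_stop"))
})

test_that("local alignment: self-hit, containment, and empty input", {
  set.seed(21)
  s <- random_protein(60)
  self <- local_align(s, s)
  expect_equal(self$identity, 100)
  expect_equal(self$query_coverage, 100)
  expect_equal(self$subject_coverage, 100)

  b <- random_protein(100)
  a <- substr(b, 1, 50)
  hit <- local_align(a, b)
  expect_equal(hit$query_coverage, 100)
  expect_equal(hit$subject_coverage, 50, tolerance = 0.05)

  expect_error(local_align("", "MKT"), "non-empty")
})

test_that("Smith-Waterman scores match the exhaustive DP oracle", {
  mat <- blosum62()
  set.seed(42)
  for (i in 1:60) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    expect_equal(local_align(a, b)$score, sw_oracle(a, b, mat),
                 info = paste(a, b))
  }
  # dissimilar pair from the oracle side
  expect_equal(local_align("MKTA", "GGGG")$score,
               sw_oracle("MKTA", "GGGG", mat))
})

test_that("homolog search applies strict identity/coverage thresholds", {
  set.seed(31)
  base <- random_protein(100)
  near <- mutate_exact(base, 0.40)
  far <- mutate_exact(base, 0.90)
  queries <- data.frame(id = c("near", "far"), species = "Sc",
                        description = "", sequence = c(near, far),
                        stringsAsFactors = FALSE)
  subjects <- data.frame(id = "base", species = "Si", description = "",
                         sequence = base, stringsAsFactors = FALSE)
  hits <- search_homologs(queries, subjects)
  expect_true("near" %in% hits$query_id)
  expect_false("far" %in% hits$query_id)

  # strictness: a hit exactly at the threshold is dropped
  h <- search_homologs(queries[queries$id == "near", , drop = FALSE],
                       subjects)
  expect_equal(nrow(search_homologs(queries[1, , drop = FALSE], subjects,
                                    min_identity = h$identity)), 0)
  expect_equal(nrow(search_homologs(queries[1, , drop = FALSE], subjects,
                                    min_coverage = h$query_coverage)), 0)

  ident <- data.frame(id = c("x", "y"), species = c("a", "b"),
                      description = "", sequence = base,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(search_homologs(ident[1, , drop = FALSE],
                                    ident[2, , drop = FALSE])), 1)
})

test_that("hydropathy TM prediction finds planted segments and none in loops", {
  expect_equal(predict_tm_segments(strrep("S", 100))$tm_count, 0)

  block <- paste0(strrep("E", 50), strrep("L", 21), strrep("E", 50))
  p <- predict_tm_segments(block)
  expect_equal(p$tm_count, 1)
  expect_true(p$segments[1, "start"] <= 51 && p$segments[1, "end"] >= 71)

  # windowed-mean oracle: every centre inside the called segment core is
  # above threshold by direct summation
  core <- 60:62
  for (c0 in core) {
    expect_gt(kd_window_mean_oracle(block, c0, 19), 1.6)
  }
  expect_lt(kd_window_mean_oracle(block, 30, 19), 1.6)

  three <- paste0(strrep("E", 40), strrep("L", 21), strrep("E", 40),
                  strrep("V", 21), strrep("E", 40), strrep("I", 21),
                  strrep("E", 40))
  expect_equal(predict_tm_segments(three)$tm_count, 3)

  # shorter than the window
  expect_equal(predict_tm_segments("LLLLL")$tm_count, 0)
  # non-standard residues score zero hydropathy
  expect_equal(predict_tm_segments(strrep("X", 100))$tm_count, 0)
})

test_that("TM prediction is reversal-invariant up to coordinate mirroring", {
  set.seed(55)
  for (i in 1:25) {
    n_block <- sample(1:3, 1)
    parts <- "E"
    for (b in seq_len(n_block)) {
      parts <- paste0(parts, strrep("E", sample(30:50, 1)),
                      strrep(sample(c("L", "I", "V"), 1), sample(19:25, 1)))
    }
    s <- paste0(parts, strrep("E", sample(30:50, 1)))
    fwd <- predict_tm_segments(s)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    bwd <- predict_tm_segments(rev_s)
    expect_equal(fwd$tm_count, bwd$tm_count)
    if (fwd$tm_count > 0) {
      n <- nchar(s)
      mirrored <- cbind(start = n + 1 - rev(fwd$segments[, "end"]),
                        end = n + 1 - rev(fwd$segments[, "start"]))
      expect_equal(unname(bwd$segments), unname(mirrored))
    }
  }
})

test_that("bidirectional clustering partitions inputs and matches a closure oracle", {
  set.seed(77)
  base1 <- random_protein(120)
  base2 <- random_protein(150)
  recs <- data.frame(
    id = c("si_a", "sc_a", "cn_a", "si_b", "sc_b", "lone"),
    species = c("Si", "Sc", "Cn", "Si", "Sc", "Cn"),
    description = "",
    sequence = c(base1, mutate_exact(base1, 0.1), mutate_exact(base1, 0.15),
                 base2, mutate_exact(base2, 0.1), random_protein(130)),
    stringsAsFactors = FALSE
  )
  cl <- bidirectional_clusters(recs)
  mem <- attr(cl, "membership")
  # partition: every input id exactly once
  expect_setequal(mem$protein_id, recs$id)
  expect_equal(anyDuplicated(mem$protein_id), 0L)

  cats <- vapply(cl, `[[`, "", "category")
  expect_true("THREE_WAY" %in% cats)
  expect_true("SI_SC" %in% cats)
  expect_true("CN_ONLY" %in% cats)

  # component oracle: rebuild the qualifying edge list independently and
  # take its transitive closure
  edges <- matrix(character(0), ncol = 2)
  for (i in 1:(nrow(recs) - 1)) {
    for (j in (i + 1):nrow(recs)) {
      h <- local_align(recs$sequence[i], recs$sequence[j],
                       ids = c(recs$id[i], recs$id[j]))
      if (h$identity >= 30 && h$query_coverage >= 80 &&
          h$subject_coverage >= 80) {
        edges <- rbind(edges, c(recs$id[i], recs$id[j]))
      }
    }
  }
  oracle <- components_oracle(recs$id, edges)
  oracle_sets <- lapply(oracle, sort)
  got_sets <- lapply(split(mem$protein_id, mem$cluster_id), sort)
  expect_setequal(unname(lapply(got_sets, paste, collapse = "+")),
                  unname(lapply(oracle_sets, paste, collapse = "+")))

  # two unrelated proteins -> two singletons
  two <- bidirectional_clusters(data.frame(
    id = c("u", "v"), species = c("Si", "Sc"), description = "",
    sequence = c(random_protein(100), random_protein(100)),
    stringsAsFactors = FALSE))
  expect_equal(length(two), 2)
})
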