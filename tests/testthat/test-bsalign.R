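test_that("converted reference spaces apply the base substitutions", {
  g <- toy_ref(c(chrA = strrep("ACGT", 20)))
  idx <- build_converted_indexes(g, aligner_params(seed_length = 12L,
                                                   seed_max_mismatches = 2L))
  expect_identical(substr(idx$converted_seq$CT[["chrA"]], 1, 4), "ATGT")
  expect_identical(substr(idx$converted_seq$GA[["chrA"]], 1, 4), "ACAT")

  g2 <- toy_ref(c(chrA = strrep("AT", 40)))
  idx2 <- build_converted_indexes(g2, aligner_params(seed_length = 12L))
  expect_identical(idx2$converted_seq$CT[["chrA"]], g2$sequences[["chrA"]])
  expect_identical(idx2$converted_seq$GA[["chrA"]], g2$sequences[["chrA"]])
})

test_that("every CT-space 30-mer is recovered at its true position", {
  g <- fixture("align_5kb", function() generate_genome(1, 5000, 0.45,
                                                       seed = 21))
  idx <- build_converted_indexes(g)
  ct_text <- chartr("C", "T", g$sequences[[1]])
  at <- seq(1, 5000 - 30 + 1, by = 37)  # systematic subsample
  reads <- substring(ct_text, at, at + 29)
  hits <- bscapture:::find_hits(reads, idx, aligner_params())
  hits <- hits[hits$space == "CT" & hits$strand == "+"]
  found <- merge(data.table::data.table(read = seq_along(at),
                                        start = at - 1L),
                 hits, by = c("read", "start"))
  expect_equal(nrow(found), length(at))
  expect_true(all(found$mm == 0))
})

test_that("bisulfite-consistent mismatches are free, others budgeted", {
  g <- fixture("align_5kb", function() generate_genome(1, 5000, 0.45,
                                                       seed = 21))
  idx <- build_converted_indexes(g)
  p <- aligner_params()

  raw <- substr(g$sequences[[1]], 1001, 1090)
  cpos <- which(strsplit(raw, "")[[1]] == "C")
  read <- raw
  substr(read, cpos[1], cpos[1]) <- "T"  # one unmethylated C read as T
  h <- align_pair(read, index = idx, params = p)$hits1
  h <- h[h$strand == "+" & h$space == "CT"]
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1000)
  expect_equal(h$mm, 0)

  # six non-bisulfite substitutions (placed after the seed, mismatching
  # in both conversion spaces) exceed the total budget
  sub_both <- c(A = "C", C = "G", G = "C", T = "G")
  at <- c(35L, 44L, 53L, 62L, 71L, 80L)
  bad <- raw
  for (i in at) substr(bad, i, i) <- sub_both[[substr(raw, i, i)]]
  hb <- align_pair(bad, index = idx, params = p)$hits1
  expect_equal(nrow(hb[hb$start == 1000 & hb$strand == "+"]), 0)

  # five pass
  ok <- raw
  for (i in at[1:5]) substr(ok, i, i) <- sub_both[[substr(raw, i, i)]]
  ho <- align_pair(ok, index = idx, params = p)$hits1
  ho <- ho[ho$start == 1000 & ho$strand == "+" & ho$space == "CT"]
  expect_equal(nrow(ho), 1)
  expect_equal(ho$mm, 5)
})

test_that("seed mismatch budget is enforced separately", {
  g <- fixture("align_5kb", function() generate_genome(1, 5000, 0.45,
                                                       seed = 21))
  idx <- build_converted_indexes(g)
  raw <- substr(g$sequences[[1]], 2001, 2090)
  # substitutions that are mismatches in both conversion spaces
  sub_both <- c(A = "C", C = "G", G = "C", T = "G")
  bad <- raw
  for (i in c(5L, 15L, 25L))
    substr(bad, i, i) <- sub_both[[substr(raw, i, i)]]
  h <- align_pair(bad, index = idx, params = aligner_params())$hits1
  expect_equal(nrow(h[h$start == 2000 & h$strand == "+"]), 0)

  # the same three substitutions outside the seed are tolerated
  ok <- raw
  for (i in c(45L, 60L, 75L))
    substr(ok, i, i) <- sub_both[[substr(raw, i, i)]]
  h2 <- align_pair(ok, index = idx, params = aligner_params())$hits1
  expect_gte(nrow(h2[h2$start == 2000 & h2$strand == "+" & h2$mm == 3]), 1)
})

test_that("pair resolution prefers proper pairs and flags ties as multi", {
  p <- aligner_params()
  paired_hit <- data.table::data.table(
    chrom = "chr1", start = c(100L, 300L), len = 90L,
    strand = c("+", "-"), space = "CT", mm = c(1L, 0L), seed_mm = 0L)
  lone <- data.table::data.table(
    chrom = "chr1", start = 5000L, len = 90L, strand = "+", space = "CT",
    mm = 0L, seed_mm = 0L)

  # mate 1 has a 0-mismatch lone hit elsewhere, but the paired placement
  # (1 mismatch) must win
  rec <- select_unique_best(rbind(paired_hit[1], lone), paired_hit[2],
                            params = p)
  expect_true(all(rec$status == "unique"))
  expect_true(all(rec$paired))
  expect_equal(sort(rec$start), c(100L, 300L))

  # two equally ranked placements -> multi
  two <- data.table::data.table(
    chrom = "chr1", start = c(100L, 2000L), len = 90L, strand = "+",
    space = "CT", mm = 0L, seed_mm = 0L)
  rec2 <- select_unique_best(two, two[0], params = p)
  expect_true(all(rec2$status == "multi"))

  # no candidates at all -> unmapped (no records)
  rec3 <- select_unique_best(two[0], two[0], params = p)
  expect_equal(nrow(rec3), 0)

  # inconsistent conversion spaces cannot form a proper pair
  h1 <- data.table::data.table(chrom = "chr1", start = 100L, len = 90L,
                               strand = "+", space = "CT", mm = 0L,
                               seed_mm = 0L)
  h2 <- data.table::data.table(chrom = "chr1", start = 300L, len = 90L,
                               strand = "-", space = "GA", mm = 0L,
                               seed_mm = 0L)
  rec4 <- select_unique_best(h1, h2, params = p)
  expect_true(all(rec4$paired == FALSE))
})

test_that("seeded alignment equals the exhaustive oracle on a toy library", {
  g <- fixture("oracle_mini_genome", function()
    generate_genome(1, 6000, 0.45, seed = 23))
  m <- generate_methylome(g, seed = 23)
  t <- define_targets(g, 3, 300, 400, seed = 23)
  p <- sim_params(n_fragments = 60, on_target_capture_prob = 1,
                  off_target_capture_prob = 1, pcr_duplicate_mean = 1,
                  seed = 23)
  lib <- simulate_reads(g, m, t, NULL, p)
  idx <- build_converted_indexes(g)
  ap <- aligner_params()
  aln <- align_library(lib$read1, lib$read2, lib$qname, idx, ap)

  chars <- genome_char_list(g)
  for (i in seq_along(lib$qname)) {
    h1 <- oracle_align_read(lib$read1[i], chars)
    h2 <- oracle_align_read(lib$read2[i], chars)
    res <- oracle_resolve_pair(h1, h2, nchar(lib$read1[i]),
                               nchar(lib$read2[i]), ap$max_insert)
    got <- aln$records[aln$records$pid == i]
    if (res$status == "unique_pair") {
      expect_equal(nrow(got), 2)
      expect_equal(sort(got$start),
                   sort(c(res$placement$start1, res$placement$start2)))
      expect_equal(sum(got$mm),
                   res$placement$mm1 + res$placement$mm2)
    } else if (res$status == "multi") {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("deduplication keeps one member per placement group", {
  base <- data.table::data.table(
    qname = sprintf("m%d", 1:4), pid = 1:4, mate = 1L, chrom = "chr1",
    start = 100L, end = 190L, len = 90L, strand = "+", space = "CT",
    mm = c(2L, 0L, 1L, 1L), gaps = 0L, paired = FALSE,
    outer_start = 100L, outer_end = 190L, status = "unique",
    seq = strrep("A", 90))
  aln <- structure(list(records = base,
                        stats = list(unique_reads = 4L, n_pairs = 4L)),
                   class = "bs_alignment")
  out <- deduplicate(aln)
  expect_equal(sum(!out$records$is_duplicate), 1)
  # fewest mismatches wins
  expect_equal(out$records[is_duplicate == FALSE]$qname, "m2")
  expect_equal(out$dedup_report$duplication_rate, 75)

  # differing conversion space -> separate groups
  base2 <- data.table::copy(base)[1:2]
  base2[2, space := "GA"]
  out2 <- deduplicate(structure(list(records = base2,
                                     stats = list(unique_reads = 2L)),
                                class = "bs_alignment"))
  expect_equal(sum(!out2$records$is_duplicate), 2)
})

test_that("estimated duplication matches the simulator truth", {
  g <- fixture("dup_genome", function() generate_genome(1, 20000, 0.45,
                                                        seed = 24))
  m <- generate_methylome(g, seed = 24)
  t <- define_targets(g, 4, 300, 400, seed = 24)
  p <- sim_params(n_fragments = 5000, on_target_capture_prob = 1,
                  off_target_capture_prob = 1, pcr_duplicate_mean = 2,
                  sequencing_error_rate = 0, seed = 24)
  lib <- simulate_reads(g, m, t, NULL, p)
  idx <- build_converted_indexes(g)
  aln <- deduplicate(align_library(lib$read1, lib$read2, lib$qname, idx))

  # truth at placement level: indistinguishable placements are duplicates
  fr <- lib$truth_fragments
  mol <- merge(lib$truth_molecules, fr, by = "frag_id")
  truth_rate <- 100 * (nrow(mol) -
                         nrow(unique(mol[, c("chrom", "start", "end",
                                             "strand")]))) / nrow(mol)
  expect_lt(abs(aln$dedup_report$duplication_rate - truth_rate), 1.5)
})

test_that("error-free Watson reads align in CT space at truth coordinates", {
  g <- generate_genome(1, 15000, 0.45, seed = 25)
  m <- generate_methylome(g, seed = 25)
  t <- define_targets(g, 3, 300, 400, seed = 25)
  p <- sim_params(n_fragments = 400, on_target_capture_prob = 1,
                  off_target_capture_prob = 1, pcr_duplicate_mean = 1,
                  sequencing_error_rate = 0,
                  strand_mode = "watson-informative-only", seed = 25)
  lib <- simulate_reads(g, m, t, NULL, p)
  idx <- build_converted_indexes(g)
  aln <- align_library(lib$read1, lib$read2, lib$qname, idx)
  rec <- aln$records
  expect_gt(nrow(rec), 700)
  expect_true(all(rec$space == "CT"))
  expect_true(all(rec$mm <= 5))
  truth <- parse_qname(rec$qname)
  r1 <- rec$mate == 1L
  expect_true(all(rec$start[r1] == truth$start[r1]))
  expect_true(all(rec$strand[r1] == "+"))
  expect_true(all(rec$end[!r1] == truth$end[!r1]))
  expect_true(all(rec$strand[!r1] == "-"))
})
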