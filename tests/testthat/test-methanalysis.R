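mk_calls <- function(chrom, pos, m, u, context = "CpG", strand = "+") {
  x <- data.table::data.table(
    chrom = chrom, pos = pos, strand = strand, context = context,
    count_methylated = m, count_unmethylated = u)
  x[, depth := count_methylated + count_unmethylated]
  x[, raw_level := ifelse(depth > 0, 100 * count_methylated / depth,
                          NA_real_)]
  x
}

mk_targets <- function(chrom, start, end, id) {
  t <- data.table::data.table(chrom = chrom, start = start, end = end,
                              id = id)
  data.table::setattr(t, "class", c("target_set", class(t)))
  t
}

test_that("region aggregation pools CpG counts and flags empty regions", {
  targets <- mk_targets("chr1", c(0L, 100L), c(50L, 200L), c("r1", "r2"))
  calls <- mk_calls("chr1", c(10L, 20L), m = c(5L, 0L), u = c(5L, 10L))
  agg <- aggregate_regions(calls, targets)
  expect_equal(agg[agg$id == "r1"]$level, 25)   # (5+0)/(5+5+0+10)
  expect_false(agg[agg$id == "r2"]$covered)
  expect_true(is.na(agg[agg$id == "r2"]$level))

  # non-CpG calls never contribute
  calls2 <- rbind(calls, mk_calls("chr1", 30L, 50L, 0L, context = "CHH"))
  expect_equal(aggregate_regions(calls2, targets)[id == "r1"]$level, 25)
})

test_that("sub-region counts sum to the parent region", {
  set.seed(41)
  pos <- sort(sample(0:999, 80))
  calls <- mk_calls("chr1", pos, m = rbinom(80, 30, 0.4),
                    u = rbinom(80, 30, 0.6))
  whole <- aggregate_regions(calls, mk_targets("chr1", 0L, 1000L, "w"))
  cut <- sample(1:999, 1)
  parts <- aggregate_regions(calls, mk_targets("chr1", c(0L, cut),
                                               c(cut, 1000L),
                                               c("p1", "p2")))
  expect_equal(whole$sum_methylated, sum(parts$sum_methylated))
  expect_equal(whole$sum_unmethylated, sum(parts$sum_unmethylated))
})

test_that("Fisher p-values are exact against full enumeration", {
  expect_equal(fisher_exact_two_sided(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_exact_two_sided(-1, 0, 0, 3), "non-negative")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4)))
    p_pkg <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    p_orc <- oracle_fisher(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(p_pkg - p_orc), 1e-12)
  }
})

test_that("package Fisher test agrees with stats::fisher.test", {
  set.seed(43)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(5:50, 1), runif(4)))
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    p_pkg <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_pkg, p_ref, tolerance = 1e-6)
  }
})

test_that("DMR calling applies the three gates conjunctively", {
  mk_reg <- function(m, u) data.table::data.table(
    id = sprintf("r%d", seq_along(m)), sum_methylated = m,
    sum_unmethylated = u,
    level = 100 * m / (m + u), covered = m + u > 0)

  # a hypomethylated region gaining methylation: levels 0 vs 22.222,
  # all three gates pass
  a <- mk_reg(0L, 36L)
  b <- mk_reg(8L, 28L)
  expect_equal(b$level, 22.222, tolerance = 1e-3)
  res <- call_dmrs(a, b)
  expect_true(res$passes_p)
  expect_true(res$passes_fold)
  expect_equal(res$fold_change, Inf)
  expect_true(res$passes_diff)
  expect_true(res$is_dmr)

  # identical counts: p = 1, diff = 0, not a DMR
  same <- mk_reg(c(10L, 0L), c(10L, 20L))
  res2 <- call_dmrs(same, same)
  expect_equal(res2$p_value, c(1, 1))
  expect_false(any(res2$is_dmr))

  # significance alone is not enough: 40% vs 75% at high depth is
  # significant and >20 points apart but under two-fold
  a3 <- mk_reg(200L, 300L)   # 40%
  b3 <- mk_reg(375L, 125L)   # 75%
  res3 <- call_dmrs(a3, b3)
  expect_true(res3$passes_p)
  expect_true(res3$passes_diff)
  expect_false(res3$passes_fold)
  expect_false(res3$is_dmr)

  expect_error(call_dmrs(mk_reg(1L, 1L),
                         mk_reg(c(1L, 2L), c(1L, 2L))), "universes")

  # degenerate gates flag every tested region
  sim <- simulate_dmr_counts(20, 5, depth = 50, seed = 5)
  res4 <- call_dmrs(sim$regions_a, sim$regions_b, alpha = 1, fold = 1,
                    diff = 0)
  noties <- res4[res4$p_value < 1 & res4$abs_diff > 0 &
                   res4$fold_change > 1]
  expect_true(all(noties$is_dmr))
})

test_that("planted DMRs are recovered and nulls controlled at depth 200", {
  sim <- simulate_dmr_counts(n_null = 150L, n_dmr = 25L, depth = 200L,
                             seed = 7)
  res <- call_dmrs(sim$regions_a, sim$regions_b)
  x <- merge(res, sim$truth, by = "id", suffixes = c("", "_truth"))
  recall <- mean(x[x$is_dmr_truth == TRUE]$is_dmr)
  expect_gte(recall, 0.9)
  fp <- x[x$is_dmr_truth == FALSE & x$is_dmr == TRUE]
  expect_lte(nrow(fp), 3)
})

test_that("type-I error of the significance gate is controlled under null", {
  sim <- simulate_dmr_counts(n_null = 500L, n_dmr = 0L, depth = 100L,
                             seed = 8)
  res <- call_dmrs(sim$regions_a, sim$regions_b)
  expect_lte(mean(res$p_value < 0.01), 0.02)
})

test_that("metagene sections are assigned by equal-width binning", {
  # single plus-strand gene with 3 exons, hand-checked assignments
  models <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = c(4000L, 4600L, 5200L), end = c(4400L, 5000L, 5500L),
    exon_rank = 1:3)
  pos <- c(2000L,  # upstream, rel 0 -> section 1
           3999L,  # upstream, rel 1999 -> section 20
           4000L,  # first exon (400 bp), rel 0 -> section 1
           4399L,  # first exon, rel 399 -> section 10
           4600L,  # internal (400 bp total), rel 0 -> section 1
           4999L,  # internal, rel 399 -> section 10
           5200L,  # terminal (300 bp), rel 0 -> section 1
           5499L,  # terminal, rel 299 -> section 10
           5500L,  # downstream, rel 0 -> section 1
           7499L)  # downstream, rel 1999 -> section 20
  calls <- mk_calls("chr1", pos, m = rep(1L, 10), u = rep(0L, 10))
  prof <- metagene_profile(calls, models)
  expect_equal(nrow(prof), 70)
  hit <- prof[prof$n_cpg > 0]
  expect_equal(hit$feature,
               c("upstream", "upstream", "first_exon", "first_exon",
                 "internal_exons", "internal_exons", "terminal_exon",
                 "terminal_exon", "downstream", "downstream"))
  expect_equal(hit$section_within,
               c(1L, 20L, 1L, 10L, 1L, 10L, 1L, 10L, 1L, 20L))

  # a constant methylation field gives every populated section that mean
  pos3 <- seq(2000L, 7400L, by = 37L)
  calls3 <- mk_calls("chr1", pos3, m = rep(3L, length(pos3)),
                     u = rep(97L, length(pos3)))
  prof3 <- metagene_profile(calls3, models)
  expect_true(all(abs(prof3[prof3$n_cpg > 0]$mean_level - 3) < 1e-9))

  # minus-strand gene: the axis flips with transcription
  mm <- data.table::copy(models)[, `:=`(strand = "-", exon_rank = 3:1)]
  one <- mk_calls("chr1", 5501L, m = 1L, u = 0L)  # just past gene end
  pm <- metagene_profile(one, mm)
  expect_equal(pm[pm$n_cpg > 0]$feature, "upstream")
  expect_equal(pm[pm$n_cpg > 0]$section_within, 20L)  # adjacent to TSS

  # upstream sections are exactly 100 bp: positions 3999 and 3900 share
  # section 20, position 3899 falls in section 19
  p100 <- metagene_profile(mk_calls("chr1", c(3999L, 3900L, 3899L),
                                    m = c(1L, 1L, 1L), u = c(0L, 0L, 0L)),
                           models)
  up <- p100[p100$feature == "upstream" & p100$n_cpg > 0]
  expect_equal(up$section_within, c(19L, 20L))
  expect_equal(up$n_cpg, c(1L, 2L))
})

test_that("two-exon genes skip internal sections", {
  models <- data.table::data.table(
    gene_id = "g2", chrom = "chr1", strand = "+",
    start = c(4000L, 5000L), end = c(4400L, 5400L), exon_rank = 1:2)
  calls <- mk_calls("chr1", c(4100L, 5100L), m = c(1L, 1L), u = c(0L, 0L))
  prof <- metagene_profile(calls, models)
  expect_equal(sum(prof[prof$feature == "internal_exons"]$n_cpg), 0)
  expect_equal(sum(prof[prof$feature == "first_exon"]$n_cpg), 1)
  expect_equal(sum(prof[prof$feature == "terminal_exon"]$n_cpg), 1)
})

test_that("Pearson concordance handles identity, inversion and degeneracy", {
  calls <- mk_calls("chr1", seq(0L, 990L, by = 10L),
                    m = rbinom(100, 20, 0.5), u = 5L)
  calls[, depth := 20L]
  expect_equal(pearson_concordance(calls, calls)$r, 1)

  inv <- data.table::copy(calls)[, raw_level := 100 - raw_level]
  expect_equal(pearson_concordance(calls, inv)$r, -1)

  const <- data.table::copy(calls)[, raw_level := 50]
  expect_error(pearson_concordance(calls, const), "constant")

  shallow <- data.table::copy(calls)[, depth := 5L]
  expect_error(pearson_concordance(calls, shallow), "depth filter|fewer")

  # the interval is data-driven and covers the point estimate
  set.seed(44)
  noisy <- data.table::copy(calls)[, raw_level :=
    pmin(100, pmax(0, raw_level + rnorm(.N, 0, 10)))]
  cc <- pearson_concordance(calls, noisy)
  expect_true(cc$conf_int[1] < cc$r && cc$r < cc$conf_int[2])
  expect_equal(cc$n_sites, 100L)
})

test_that("site validation switches between chi-square and exact tests", {
  lhc <- data.table::data.table(site = c("s1", "s2", "s3"),
                                methylated = c(10L, 50L, 0L),
                                unmethylated = c(90L, 50L, 10L))
  clones <- data.table::data.table(site = c("s1", "s2", "s3"),
                                   methylated = c(1L, 25L, 0L),
                                   unmethylated = c(9L, 25L, 5L))
  res <- site_validation_test(lhc, clones)
  expect_gt(res[res$site == "s1"]$p_value, 0.01)  # concordant
  expect_false(any(res$significant))
  expect_equal(res[res$site == "s2"]$test, "chisq")
  expect_equal(res[res$site == "s3"]$test, "fisher")

  # identical proportions are never significant at any depth
  same <- site_validation_test(
    data.table::data.table(site = "x", methylated = 400L,
                           unmethylated = 600L),
    data.table::data.table(site = "x", methylated = 40L,
                           unmethylated = 60L))
  expect_false(same$significant)

  # matched 27-site panel: significant count consistent with alpha
  set.seed(45)
  p <- runif(27, 0.05, 0.95)
  lhc27 <- data.table::data.table(site = sprintf("c%02d", 1:27),
                                  methylated = rbinom(27, 100, p))
  lhc27[, unmethylated := 100L - methylated]
  cl27 <- data.table::data.table(site = sprintf("c%02d", 1:27),
                                 methylated = rbinom(27, 12, p))
  cl27[, unmethylated := 12L - methylated]
  res27 <- site_validation_test(lhc27, cl27)
  expect_lte(sum(res27$significant), 2)

  # zero-depth sites are skipped with a log message
  z <- data.table::data.table(site = "z", methylated = 0L,
                              unmethylated = 0L)
  expect_message(site_validation_test(z, data.table::data.table(
    site = "z", methylated = 5L, unmethylated = 5L)), "skipped")
})
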