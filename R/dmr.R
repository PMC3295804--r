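#' Aggregate CpG counts over target regions
#'
#' Sums methylated and unmethylated CpG observations (both strands) over
#' every region; the region level is the pooled ratio
#' `100 * sum(mC) / (sum(mC) + sum(C))`. Regions with no covered CpG are
#' kept with `covered = FALSE` and an undefined level.
#'
#' @param calls a `cytosine_calls` table.
#' @param targets a `target_set`.
#' @return a `data.table` with `id`, `sum_methylated`, `sum_unmethylated`,
#'   `level` (%), `covered`.
#' @export
aggregate_regions <- function(calls, targets) {
  cpg <- calls[context == "CpG"]
  tgt <- as.data.table(targets)[, .(chrom, start, end, id)]
  if (nrow(cpg)) {
    cpg_gr <- GenomicRanges::GRanges(cpg$chrom,
                                     IRanges::IRanges(cpg$pos + 1L,
                                                      cpg$pos + 1L))
    ov <- GenomicRanges::findOverlaps(cpg_gr, targets_granges(tgt))
    hit <- data.table(id = tgt$id[S4Vectors::subjectHits(ov)],
                      m = cpg$count_methylated[S4Vectors::queryHits(ov)],
                      u = cpg$count_unmethylated[S4Vectors::queryHits(ov)])
    agg <- hit[, .(sum_methylated = sum(m), sum_unmethylated = sum(u)),
               by = id]
  } else {
    agg <- data.table(id = character(), sum_methylated = integer(),
                      sum_unmethylated = integer())
  }
  out <- merge(tgt[, .(id)], agg, by = "id", all.x = TRUE)
  out[is.na(sum_methylated), `:=`(sum_methylated = 0L,
                                  sum_unmethylated = 0L)]
  out[, total := sum_methylated + sum_unmethylated]
  out[, covered := total > 0L]
  out[, level := ifelse(covered, 100 * sum_methylated / total, NA_real_)]
  setorder(out, id)
  out[, .(id, sum_methylated, sum_unmethylated, level, covered)]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration; the two-sided p-value sums the
#' probabilities of all tables (at fixed margins) whose probability does
#' not exceed that of the observed table (with a relative tolerance of
#' 1e-7 for ties under floating point). An all-zero table has p = 1 by
#' convention.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = samples:
#'   `[[a, b], [c, d]]`.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0) return(1)
  m <- a + b          # margin of row 1
  n <- c + d          # margin of row 2
  k <- a + c          # margin of column 1
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Call differentially methylated regions between two samples
#'
#' Applies the three-criterion rule conjunctively on regions aggregated in
#' both samples: (1) two-sided Fisher's exact test on the pooled methylated
#' and unmethylated counts with `p < alpha`; (2) fold change — the larger
#' level over the smaller — `> fold`; (3) absolute level difference
#' `> diff` percentage points. No multiple-testing correction is applied by
#' default, matching the raw-p procedure the workflow follows; setting
#' `p_adjust` applies [stats::p.adjust()] to the significance gate instead.
#' Regions without coverage in either sample are excluded from testing.
#'
#' @param regions_a,regions_b outputs of [aggregate_regions()] over the
#'   same region universe.
#' @param alpha significance threshold (default 0.01).
#' @param fold fold-change threshold (default 2; a region with one zero
#'   level and one positive level has infinite fold change and passes).
#' @param diff absolute difference threshold in percentage points
#'   (default 20).
#' @param p_adjust optional method string for [stats::p.adjust()].
#' @return a `data.table` of class `dmr_result` with counts, levels,
#'   `p_value`, `fold_change`, `abs_diff`, the three gate booleans and
#'   `is_dmr`.
#' @export
call_dmrs <- function(regions_a, regions_b, alpha = 0.01, fold = 2,
                      diff = 20, p_adjust = NULL) {
  if (!setequal(regions_a$id, regions_b$id) ||
      nrow(regions_a) != nrow(regions_b))
    stop("region universes differ between the two samples", call. = FALSE)
  x <- merge(regions_a, regions_b, by = "id", suffixes = c("_a", "_b"))
  x <- x[covered_a & covered_b]
  if (nrow(x) == 0L)
    return(structure(data.table(), class = c("dmr_result", "data.table",
                                             "data.frame")))
  x[, p_value := mapply(fisher_exact_two_sided, sum_methylated_a,
                        sum_unmethylated_a, sum_methylated_b,
                        sum_unmethylated_b)]
  x[, abs_diff := abs(level_a - level_b)]
  lo <- pmin(x$level_a, x$level_b)
  hi <- pmax(x$level_a, x$level_b)
  x[, fold_change := ifelse(lo == 0 & hi == 0, 1,
                            ifelse(lo == 0, Inf, hi / lo))]
  p_gate <- if (is.null(p_adjust)) x$p_value
            else stats::p.adjust(x$p_value, method = p_adjust)
  x[, passes_p := p_gate < alpha]
  x[, passes_fold := fold_change > fold]
  x[, passes_diff := abs_diff > diff]
  x[, is_dmr := passes_p & passes_fold & passes_diff]
  setattr(x, "class", c("dmr_result", "data.table", "data.frame"))
  x[]
}

#' Simulate region-level CpG counts with planted DMRs
#'
#' Generates pooled CpG counts for two samples over `n_null + n_dmr`
#' regions at a fixed per-region depth. Null regions share one methylation
#' level per region; planted regions shift sample B upward by `shift`
#' percentage points. Base levels are drawn Uniform over `base_range`
#' (hypomethylated, promoter-like regions gaining methylation, so the true
#' fold change of every planted region exceeds the two-fold gate).
#'
#' @param n_null,n_dmr region counts.
#' @param depth pooled CpG depth per region per sample.
#' @param shift planted shift in percentage points.
#' @param base_range range of base levels, as fractions.
#' @param seed integer seed.
#' @return a list with `regions_a`, `regions_b` (aggregation-format tables)
#'   and `truth` (`id`, `is_dmr`).
#' @export
simulate_dmr_counts <- function(n_null = 450L, n_dmr = 50L, depth = 200L,
                                shift = 40, base_range = c(0.05, 0.25),
                                seed = 1L) {
  set.seed(substream_seed(seed, "dmr-counts"))
  n <- n_null + n_dmr
  id <- sprintf("region_%04d", seq_len(n))
  planted <- c(rep(FALSE, n_null), rep(TRUE, n_dmr))
  p_a <- runif(n, base_range[1], base_range[2])
  p_b <- ifelse(planted, pmin(1, p_a + shift / 100), p_a)
  m_a <- rbinom(n, depth, p_a)
  m_b <- rbinom(n, depth, p_b)
  mk <- function(m) data.table(
    id = id, sum_methylated = m, sum_unmethylated = depth - m,
    level = 100 * m / depth, covered = TRUE)
  list(regions_a = mk(m_a), regions_b = mk(m_b),
       truth = data.table(id = id, is_dmr = planted))
}
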