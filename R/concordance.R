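#' Pearson concordance between two call sets
#'
#' Correlates per-cytosine methylation levels of two samples at sites with
#' depth at least `min_depth` in both (the workflow's "at least nine
#' reads" restriction). The 95% confidence interval uses Fisher's
#' variance-stabilizing z-transform with normal quantiles.
#'
#' @param calls_a,calls_b `cytosine_calls` tables; `corrected_level` is
#'   used when present, `raw_level` otherwise.
#' @param min_depth minimum depth in both samples (default 9).
#' @param conf confidence level for the interval.
#' @return a list of class `concordance`: `r`, `conf_int`, `n_sites`,
#'   `min_depth`.
#' @export
pearson_concordance <- function(calls_a, calls_b, min_depth = 9L,
                                conf = 0.95) {
  lev <- function(x) if ("corrected_level" %in% names(x))
    x$corrected_level else x$raw_level
  a <- as.data.table(calls_a)[, .(chrom, pos, strand, depth,
                                  level = lev(calls_a))]
  b <- as.data.table(calls_b)[, .(chrom, pos, strand, depth,
                                  level = lev(calls_b))]
  x <- merge(a, b, by = c("chrom", "pos", "strand"),
             suffixes = c("_a", "_b"))
  x <- x[depth_a >= min_depth & depth_b >= min_depth]
  if (nrow(x) < 3L)
    stop("fewer than 3 shared sites pass the depth filter", call. = FALSE)
  if (stats::sd(x$level_a) == 0 || stats::sd(x$level_b) == 0)
    stop("constant methylation levels: correlation undefined",
         call. = FALSE)
  r <- cor(x$level_a, x$level_b)
  z <- atanh(r)
  se <- 1 / sqrt(nrow(x) - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  structure(list(r = r, conf_int = tanh(c(z - q * se, z + q * se)),
                 n_sites = nrow(x), min_depth = min_depth),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(
    "<concordance> r = %.3f (95%% CI %.3f-%.3f), %d sites at depth >= %d\n",
    x$r, x$conf_int[1], x$conf_int[2], x$n_sites, x$min_depth))
  invisible(x)
}

#' Per-CpG validation tests against clone sequencing
#'
#' Compares capture-sequencing counts with clone (bisulfite PCR)
#' counts site by site as 2x2 tables: a chi-square test with continuity
#' correction when all expected counts reach 5, otherwise the exact test.
#' Sites with zero depth on either side are skipped.
#'
#' @param lhc_counts `data.table` with `site`, `methylated`,
#'   `unmethylated` from the capture assay.
#' @param clone_calls same columns from clone sequencing.
#' @param alpha significance threshold (default 0.01).
#' @return a `data.table`: `site`, `p_value`, `test` (chisq/fisher),
#'   `significant`.
#' @export
site_validation_test <- function(lhc_counts, clone_calls, alpha = 0.01) {
  x <- merge(as.data.table(lhc_counts), as.data.table(clone_calls),
             by = "site", suffixes = c("_lhc", "_clone"))
  skipped <- x[methylated_lhc + unmethylated_lhc == 0L |
                 methylated_clone + unmethylated_clone == 0L]
  if (nrow(skipped))
    message(nrow(skipped), " zero-depth site(s) skipped")
  x <- x[!site %in% skipped$site]
  if (nrow(x) == 0L)
    return(data.table(site = character(), p_value = numeric(),
                      test = character(), significant = logical()))
  res <- x[, {
    tab <- matrix(c(methylated_lhc, unmethylated_lhc,
                    methylated_clone, unmethylated_clone),
                  nrow = 2, byrow = TRUE)
    expect <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expect >= 5)) {
      p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
      list(p_value = p, test = "chisq")
    } else {
      list(p_value = fisher_exact_two_sided(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]),
           test = "fisher")
    }
  }, by = site]
  res[, significant := p_value < alpha]
  res[]
}
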