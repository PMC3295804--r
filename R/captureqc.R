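#' Capture QC report
#'
#' Mapping, enrichment, duplication and coverage statistics for a captured
#' library, computed from the deduplicated unique alignments.
#'
#' A read is on target when its span overlaps any capture region by at
#' least 1 bp; a region counts as covered when at least one unique read
#' overlaps it, and as well-covered when at least `coverage_reads`
#' (default 10) unique reads do. Mean target depth is the summed per-base
#' unique-read depth over target bases divided by the target span.
#'
#' @param alignment a `bs_alignment`; enrichment, coverage and depth are
#'   computed over all unique reads (duplication is reported as its own
#'   rate when [deduplicate()] has run).
#' @param targets a `target_set`.
#' @param raw_read_pairs number of read pairs in the raw library (before
#'   alignment), used for the unique map rate denominator.
#' @param coverage_reads read count defining a well-covered region.
#' @return an object of class `capture_qc_report`.
#' @export
compute_capture_qc <- function(alignment, targets, raw_read_pairs,
                               coverage_reads = 10L) {
  stopifnot(inherits(alignment, "bs_alignment"))
  if (is.null(targets) || nrow(targets) == 0L)
    stop("empty target set", call. = FALSE)
  rec <- alignment$records
  raw_reads <- 2L * raw_read_pairs

  tgt_gr <- targets_granges(targets)
  read_gr <- GenomicRanges::GRanges(rec$chrom,
                                    IRanges::IRanges(rec$start + 1L, rec$end))

  on_target <- IRanges::overlapsAny(read_gr, tgt_gr)
  region_reads <- GenomicRanges::countOverlaps(tgt_gr, read_gr)

  cov <- GenomicRanges::coverage(read_gr)
  shared <- intersect(names(cov), unique(targets$chrom))
  target_base_depth <- 0
  per_chrom_span <- tapply(targets$end - targets$start, targets$chrom, sum)
  per_chrom_depth <- setNames(numeric(length(per_chrom_span)),
                              names(per_chrom_span))
  for (ch in shared) {
    rng <- IRanges::IRanges(targets$start[targets$chrom == ch] + 1L,
                            targets$end[targets$chrom == ch])
    v <- sum(sum(IRanges::Views(cov[[ch]], rng)))
    target_base_depth <- target_base_depth + v
    per_chrom_depth[ch] <- v
  }
  span <- target_span(targets)

  # per chromosome x conversion space (strand of origin) depth on targets
  strand_tab <- rec[, .(reads = .N, bases = sum(len)),
                    by = .(chrom, space)]
  setorder(strand_tab, chrom, space)

  structure(list(
    raw_read_pairs = raw_read_pairs,
    unique_map_rate = 100 * alignment$stats$unique_reads / raw_reads,
    duplication_rate = alignment$dedup_report$duplication_rate %||%
      NA_real_,
    mean_target_depth = target_base_depth / span,
    fraction_targets_covered = 100 * mean(region_reads >= 1L),
    fraction_targets_ge10 = 100 * mean(region_reads >= coverage_reads),
    on_target_rate = 100 * mean(on_target),
    n_reads_counted = nrow(rec),
    per_chromosome_strand_depth = strand_tab,
    per_chromosome_target_depth = data.table(
      chrom = names(per_chrom_span),
      span = as.integer(per_chrom_span),
      mean_depth = per_chrom_depth / as.numeric(per_chrom_span)),
    region_read_counts = data.table(id = targets$id, reads = region_reads,
                                    on_target_reads = region_reads)
  ), class = "capture_qc_report")
}

#' @export
print.capture_qc_report <- function(x, ...) {
  cat("<capture_qc_report>\n")
  cat(sprintf("  raw read pairs        %d\n", x$raw_read_pairs))
  cat(sprintf("  unique map rate       %.2f%%\n", x$unique_map_rate))
  cat(sprintf("  duplication rate      %.2f%%\n", x$duplication_rate))
  cat(sprintf("  mean target depth     %.1fx\n", x$mean_target_depth))
  cat(sprintf("  targets covered       %.2f%%\n",
              x$fraction_targets_covered))
  cat(sprintf("  targets >= 10 reads   %.2f%%\n", x$fraction_targets_ge10))
  cat(sprintf("  on-target rate        %.2f%%\n", x$on_target_rate))
  invisible(x)
}

#' Allele dropout report from known counts
#'
#' The dropout rate is `100 * (n_truth - n_recovered) / n_truth` over
#' depth-qualified, bisulfite-unambiguous heterozygous sites; excluded
#' ambiguous sites never enter the denominator.
#'
#' @param n_truth_het qualifying heterozygous sites in the truth set.
#' @param n_recovered_het sites at which both alleles were observed.
#' @param excluded_ambiguous count of sites excluded as C/T or A/G pairs.
#' @return an object of class `dropout_report`.
#' @export
dropout_report <- function(n_truth_het, n_recovered_het,
                           excluded_ambiguous = 0L) {
  n_truth_het <- check_count(n_truth_het, "n_truth_het", min = 1L)
  n_recovered_het <- check_count(n_recovered_het, "n_recovered_het")
  if (n_recovered_het > n_truth_het)
    stop("more recovered than truth sites", call. = FALSE)
  structure(list(
    n_truth_het = n_truth_het, n_recovered_het = n_recovered_het,
    dropout_rate = 100 * (n_truth_het - n_recovered_het) / n_truth_het,
    excluded_ambiguous = check_count(excluded_ambiguous,
                                     "excluded_ambiguous")
  ), class = "dropout_report")
}

#' @export
print.dropout_report <- function(x, ...) {
  cat(sprintf(
    "<dropout_report> %d/%d sites recovered, dropout %.1f%% (%d ambiguous excluded)\n",
    x$n_recovered_het, x$n_truth_het, x$dropout_rate,
    x$excluded_ambiguous))
  invisible(x)
}

#' Assess allele dropout at known heterozygous sites
#'
#' Truth sites are filtered to bisulfite-unambiguous allele pairs with
#' unique-read depth strictly greater than `min_depth` (the workflow's
#' "more than 10x" criterion). A site is recovered when both alleles are
#' observed with at least `min_allele_reads` conversion-safe observations
#' each. An observation is conversion-safe when the read base cannot be a
#' conversion artifact in its space: in C-to-T space a read T may be a
#' converted C, so T observations are discarded there; in G-to-A space
#' likewise read A.
#'
#' @param het_truth `data.table` from [plant_het_sites()] (or real calls
#'   with the same columns).
#' @param alignment a deduplicated `bs_alignment`.
#' @param genome the `ref_genome`.
#' @param min_depth depth must exceed this value (default 10).
#' @param min_allele_reads safe observations required per allele.
#' @return a `dropout_report` with an additional `site_table` attribute.
#' @export
assess_allele_dropout <- function(het_truth, alignment, genome,
                                  min_depth = 10L, min_allele_reads = 2L) {
  stopifnot(inherits(alignment, "bs_alignment"))
  min_depth <- check_count(min_depth, "min_depth", min = 1L)
  rec <- kept_records(alignment)
  if (nrow(het_truth) == 0L)
    stop("no heterozygous truth sites supplied", call. = FALSE)

  excluded <- sum(het_truth$bisulfite_ambiguous)
  informative <- het_truth[bisulfite_ambiguous == FALSE]

  ex <- explode_seqs(rec$seq)
  gpos <- rec$start[ex$seq_id] + ex$offset
  obs <- data.table(chrom = rec$chrom[ex$seq_id], pos = gpos,
                    base = ex$chars, space = rec$space[ex$seq_id])
  obs <- obs[informative, on = c("chrom", "pos"), nomatch = NULL]
  # conversion-safe identities only
  obs <- obs[!(space == "CT" & base == "T") & !(space == "GA" & base == "A")]

  depth_all <- obs[, .N, by = .(chrom, pos)]
  site <- merge(informative, depth_all, by = c("chrom", "pos"),
                all.x = TRUE)
  site[is.na(N), N := 0L]
  site <- site[N > min_depth]
  if (nrow(site) == 0L)
    stop("no heterozygous truth sites pass the depth filter",
         call. = FALSE)

  counts <- obs[, .(n = .N), by = .(chrom, pos, base)]
  site <- merge(site,
                counts[, .(chrom, pos, base, n)],
                by = c("chrom", "pos"), all.x = TRUE,
                allow.cartesian = TRUE)
  site_sum <- site[, .(
    ref_reads = sum(n[base == ref[1L]], na.rm = TRUE),
    alt_reads = sum(n[base == alt[1L]], na.rm = TRUE)
  ), by = .(chrom, pos)]
  site_sum[, recovered := ref_reads >= min_allele_reads &
             alt_reads >= min_allele_reads]

  rep <- dropout_report(nrow(site_sum), sum(site_sum$recovered), excluded)
  attr(rep, "site_table") <- site_sum[]
  rep
}
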