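#' Simulation parameters for a captured bisulfite library
#'
#' Defaults follow the assay the package models: ~250 bp fragments read as
#' 90 bp paired ends, liquid-capture enrichment giving roughly three
#' quarters of reads on target, and a PCR duplicate load of the order seen
#' in deeply sequenced captured libraries.
#'
#' @param fragment_mean,fragment_sd fragment length distribution (bp);
#'   lengths are drawn Normal and redrawn when < 1 bp.
#' @param read_length paired-end read length (bp); fragments shorter than
#'   this yield truncated reads.
#' @param n_fragments number of fragments attempted (before capture).
#' @param conversion_rate probability an unmethylated cytosine is read as T.
#' @param inappropriate_conversion_rate probability a methylated cytosine is
#'   read as T (over-conversion; 0 by default).
#' @param sequencing_error_rate per-base substitution error probability.
#' @param on_target_capture_prob,off_target_capture_prob retention
#'   probability for fragments that do / do not overlap a target by >= 1 bp.
#' @param pcr_duplicate_mean mean number of emitted copies per captured
#'   molecule; copies are `1 + Poisson(pcr_duplicate_mean - 1)`.
#' @param strand_mode `"both"` samples the source strand of each fragment
#'   uniformly; `"watson-informative-only"` restricts to the original top
#'   strand, mimicking single-strand probe capture.
#' @param quality_char constant FASTQ base quality character (phred+33).
#' @param seed integer seed; all randomness in [simulate_reads()] flows
#'   from it.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(fragment_mean = 250, fragment_sd = 30,
                       read_length = 90L, n_fragments = 20000L,
                       conversion_rate = 0.99,
                       inappropriate_conversion_rate = 0,
                       sequencing_error_rate = 0.001,
                       on_target_capture_prob = 0.8,
                       off_target_capture_prob = 0.01,
                       pcr_duplicate_mean = 1.7,
                       strand_mode = c("both", "watson-informative-only"),
                       quality_char = "I", seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  check_prob(conversion_rate, "conversion_rate")
  check_prob(inappropriate_conversion_rate, "inappropriate_conversion_rate")
  check_prob(sequencing_error_rate, "sequencing_error_rate")
  check_prob(on_target_capture_prob, "on_target_capture_prob")
  check_prob(off_target_capture_prob, "off_target_capture_prob")
  read_length <- check_count(read_length, "read_length", min = 1L)
  n_fragments <- check_count(n_fragments, "n_fragments", min = 1L)
  if (fragment_mean <= 0) stop("fragment_mean must be > 0", call. = FALSE)
  if (fragment_sd < 0) stop("fragment_sd must be >= 0", call. = FALSE)
  if (pcr_duplicate_mean < 1)
    stop("pcr_duplicate_mean must be >= 1", call. = FALSE)
  if (nchar(quality_char) != 1L)
    stop("quality_char must be a single character", call. = FALSE)
  structure(list(
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    read_length = read_length, n_fragments = n_fragments,
    conversion_rate = conversion_rate,
    inappropriate_conversion_rate = inappropriate_conversion_rate,
    sequencing_error_rate = sequencing_error_rate,
    on_target_capture_prob = on_target_capture_prob,
    off_target_capture_prob = off_target_capture_prob,
    pcr_duplicate_mean = pcr_duplicate_mean,
    strand_mode = strand_mode, quality_char = quality_char,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate a captured, bisulfite-converted paired-end library
#'
#' Per attempted fragment: (1) draw a Normal length and a uniform placement;
#' (2) retain with `on_target_capture_prob` if the fragment overlaps a
#' capture target by >= 1 bp, else with `off_target_capture_prob`;
#' (3) pick a source strand and homolog (heterozygous alleles are phased:
#' homolog 1 carries the reference allele, homolog 2 the alternate);
#' (4) convert: each cytosine of the source strand is methylated with its
#' per-molecule Bernoulli(true level) state, then reads as T with
#' `conversion_rate` if unmethylated or `inappropriate_conversion_rate` if
#' methylated — guanines on the read (opposite-strand cytosines) are never
#' touched; (5) amplify into `1 + Poisson(mean - 1)` PCR copies; (6) emit
#' 90 bp paired reads (read 2 is the reverse complement of the fragment
#' end) with independent per-base substitution errors per copy.
#'
#' Read names encode the truth origin `chrom:start:end:strand:dupgroup:copy`
#' so every downstream statistic can be joined against the truth tables.
#'
#' @param genome a `ref_genome`.
#' @param methylome a `methylome` over `genome`.
#' @param targets a `target_set` (capture design).
#' @param het_sites optional `data.table` from [plant_het_sites()].
#' @param params a `sim_params` object.
#' @return an object of class `bs_library`: reads (`qname`, `read1`,
#'   `read2`, `qual1`, `qual2`) plus truth tables `truth_fragments` (one row
#'   per captured molecule), `truth_molecules` (one row per emitted pair)
#'   and `truth_conversions` (one row per cytosine per captured molecule).
#' @export
simulate_reads <- function(genome, methylome, targets, het_sites = NULL,
                           params = sim_params()) {
  stopifnot(inherits(genome, "ref_genome"), inherits(methylome, "methylome"),
            inherits(params, "sim_params"))
  set.seed(substream_seed(params$seed, "reads"))
  rl <- params$read_length

  frags <- draw_fragments(genome, params)

  # capture: Bernoulli retention on >= 1 bp target overlap
  fr_gr <- GenomicRanges::GRanges(frags$chrom,
                                  IRanges::IRanges(frags$start + 1L, frags$end))
  frags[, on_target := IRanges::overlapsAny(fr_gr, targets_granges(targets))]
  keep_p <- ifelse(frags$on_target, params$on_target_capture_prob,
                   params$off_target_capture_prob)
  frags <- frags[runif(nrow(frags)) < keep_p]
  if (nrow(frags) == 0L) {
    warning("empty library: no fragments were retained by capture")
    return(empty_library(params))
  }
  frags[, frag_id := .I]
  frags[, homolog := sample(c(1L, 2L), .N, replace = TRUE)]
  frags[, strand := if (params$strand_mode == "both")
    sample(c("+", "-"), .N, replace = TRUE) else "+"]

  # fragment sequences (forward genome orientation)
  frags[, seq := substring(genome$sequences[chrom], start + 1L, end)]

  # phased heterozygous substitutions on homolog-2 molecules
  if (!is.null(het_sites) && nrow(het_sites) > 0L) {
    het_gr <- GenomicRanges::GRanges(het_sites$chrom,
                                     IRanges::IRanges(het_sites$pos + 1L,
                                                      het_sites$pos + 1L))
    kept_gr <- GenomicRanges::GRanges(frags$chrom,
                                      IRanges::IRanges(frags$start + 1L,
                                                       frags$end))
    ov <- GenomicRanges::findOverlaps(het_gr, kept_gr)
    for (k in seq_along(ov)) {
      i <- S4Vectors::queryHits(ov)[k]
      j <- S4Vectors::subjectHits(ov)[k]
      if (frags$homolog[j] == 2L) {
        at <- het_sites$pos[i] - frags$start[j] + 1L
        substr(frags$seq[j], at, at) <- het_sites$alt[i]
      }
    }
  }

  # orient to the source strand
  minus <- frags$strand == "-"
  if (any(minus)) frags$seq[minus] <- revcomp(frags$seq[minus])

  conv <- convert_fragments(frags, genome, methylome, params)
  frags$seq <- conv$seq
  truth_conversions <- conv$events

  # PCR amplification
  copies <- 1L + rpois(nrow(frags), params$pcr_duplicate_mean - 1)
  frags[, n_copies := copies]
  mol <- frags[rep(frag_id, copies)]
  mol[, copy_index := sequence(copies)]
  mol[, qname := sprintf("%s:%d:%d:%s:%d:%d", chrom, start, end, strand,
                         frag_id, copy_index)]

  len <- nchar(mol$seq)
  read1 <- substring(mol$seq, 1L, pmin(rl, len))
  read2 <- revcomp(substring(mol$seq, pmax(1L, len - rl + 1L), len))
  read1 <- add_sequencing_errors(read1, params$sequencing_error_rate)
  read2 <- add_sequencing_errors(read2, params$sequencing_error_rate)

  qual1 <- strrep(params$quality_char, nchar(read1))
  qual2 <- strrep(params$quality_char, nchar(read2))

  structure(list(
    qname = mol$qname, read1 = read1, read2 = read2,
    qual1 = qual1, qual2 = qual2,
    truth_fragments = frags[, .(frag_id, chrom, start, end, strand,
                                homolog, on_target, n_copies)],
    truth_molecules = mol[, .(qname, frag_id, copy_index)],
    truth_conversions = truth_conversions,
    params = params
  ), class = "bs_library")
}

empty_library <- function(params) {
  structure(list(
    qname = character(0), read1 = character(0), read2 = character(0),
    qual1 = character(0), qual2 = character(0),
    truth_fragments = data.table(frag_id = integer(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), homolog = integer(),
                                 on_target = logical(), n_copies = integer()),
    truth_molecules = data.table(qname = character(), frag_id = integer(),
                                 copy_index = integer()),
    truth_conversions = data.table(frag_id = integer(), chrom = character(),
                                   pos = integer(), strand = character(),
                                   context = character(),
                                   methylated = logical(),
                                   read_as_T = logical()),
    params = params
  ), class = "bs_library")
}

#' @export
print.bs_library <- function(x, ...) {
  cat(sprintf(
    "<bs_library> %d read pairs from %d fragments (%.1f%% on target)\n",
    length(x$qname), nrow(x$truth_fragments),
    if (nrow(x$truth_fragments))
      100 * mean(x$truth_fragments$on_target) else NA_real_))
  invisible(x)
}

draw_fragments <- function(genome, params) {
  lens <- genome$chrom_lengths
  need <- params$n_fragments
  out <- vector("list", 0L)
  guard <- 0L
  while (need > 0L && guard < 1000L) {
    guard <- guard + 1L
    n <- need
    chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
    w <- round(rnorm(n, params$fragment_mean, params$fragment_sd))
    L <- unname(lens[chrom])
    ok <- w >= 1 & w <= L
    if (!any(ok)) next
    chrom <- chrom[ok]; w <- as.integer(w[ok]); L <- L[ok]
    start <- as.integer(floor(runif(length(w)) * (L - w + 1)))
    out[[length(out) + 1L]] <- data.table(chrom = chrom, start = start,
                                          end = start + w)
    need <- need - length(w)
  }
  if (need > 0L)
    stop("could not draw valid fragments; check fragment length parameters",
         call. = FALSE)
  rbindlist(out)
}

# Bisulfite conversion of source-strand cytosines, one molecule at a time
# (methylation state is Bernoulli(true level) per molecule).
convert_fragments <- function(frags, genome, methylome, params) {
  lk <- methylome_lookup(methylome, genome)
  ctx <- methylome[, .(chrom, pos, strand, context)]
  setkey(ctx, chrom, pos, strand)

  ex <- explode_seqs(frags$seq)
  is_c <- ex$chars == "C"
  idx <- which(is_c)
  if (length(idx) == 0L) {
    return(list(seq = frags$seq,
                events = data.table(frag_id = integer(), chrom = character(),
                                    pos = integer(), strand = character(),
                                    context = character(),
                                    methylated = logical(),
                                    read_as_T = logical())))
  }
  fi <- ex$seq_id[idx]
  off <- ex$offset[idx]
  strand <- frags$strand[fi]
  chrom <- frags$chrom[fi]
  gpos <- ifelse(strand == "+", frags$start[fi] + off,
                 frags$end[fi] - 1L - off)

  key <- paste0(chrom, strand)
  level <- numeric(length(idx))
  for (k in unique(key)) {
    sel <- key == k
    level[sel] <- lk[[k]][gpos[sel] + 1L]
  }
  # cytosines created by an alternate allele have no truth entry: level 0
  level[is.na(level)] <- 0

  meth <- runif(length(idx)) < level
  read_as_T <- ifelse(meth,
                      runif(length(idx)) < params$inappropriate_conversion_rate,
                      runif(length(idx)) < params$conversion_rate)

  chars <- ex$chars
  chars[idx[read_as_T]] <- "T"
  seqs <- vapply(split(chars, ex$seq_id), paste, character(1), collapse = "")

  ev <- data.table(frag_id = frags$frag_id[fi], chrom = chrom, pos = gpos,
                   strand = strand, methylated = meth, read_as_T = read_as_T)
  ev <- ctx[ev, on = c("chrom", "pos", "strand")]
  ev[is.na(context), context := "non-CpG"]
  list(seq = unname(seqs),
       events = ev[, .(frag_id, chrom, pos, strand, context,
                       methylated, read_as_T)])
}

add_sequencing_errors <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  at <- sort(sample.int(total, n_err))
  cum <- cumsum(lens)
  ri <- findInterval(at - 1L, cum) + 1L
  pos <- at - c(0L, cum)[ri]
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ri[k]], pos[k], pos[k])
    substr(reads[ri[k]], pos[k], pos[k]) <-
      sample(setdiff(BASES, cur), 1L)
  }
  reads
}
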