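#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases at a requested GC fraction and optionally overwrites
#' intervals with CpG-dense sequence, emulating a genome with CpG islands
#' embedded in CpG-poor background. All coordinates in the package are
#' 0-based, half-open.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bp (>= 1000).
#' @param gc_fraction target G+C fraction in (0, 1).
#' @param cpg_island_spec optional `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `cpg_density`
#'   (probability of emitting a CG dinucleotide at each step inside the
#'   island; default 0.2). Island sequence replaces the background.
#' @param seed integer seed; the same seed always yields the same genome.
#' @return an object of class `ref_genome`: a list with `sequences` (named
#'   character vector), `chrom_lengths`, `total_length` and `cpg_positions`
#'   (0-based forward-strand positions of CpG dinucleotides, per chromosome).
#' @export
generate_genome <- function(n_chroms = 1L, chrom_length = 100000L,
                            gc_fraction = 0.4, cpg_island_spec = NULL,
                            seed = 1L) {
  n_chroms <- check_count(n_chroms, "n_chroms", min = 1L)
  chrom_length <- check_count(chrom_length, "chrom_length", min = 1L)
  if (chrom_length < 1000L)
    stop("'chrom_length' must be at least 1000 bp", call. = FALSE)
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop("'gc_fraction' must lie strictly between 0 and 1", call. = FALSE)
  set.seed(substream_seed(seed, "genome"))

  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    chars <- sample(BASES, chrom_length, replace = TRUE, prob = probs)
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))

  if (!is.null(cpg_island_spec) && nrow(cpg_island_spec) > 0L) {
    isl <- as.data.frame(cpg_island_spec)
    if (!all(c("chrom", "start", "end") %in% names(isl)))
      stop("cpg_island_spec needs columns chrom, start, end", call. = FALSE)
    if (is.null(isl$cpg_density)) isl$cpg_density <- 0.2
    for (i in seq_len(nrow(isl))) {
      chrom <- as.character(isl$chrom[i])
      if (!chrom %in% names(seqs))
        stop("cpg_island_spec references unknown chromosome ", chrom,
             call. = FALSE)
      s <- isl$start[i]; e <- isl$end[i]
      if (s < 0 || e > nchar(seqs[[chrom]]) || e <= s)
        stop("cpg_island_spec interval out of range", call. = FALSE)
      len <- e - s
      # emit CG with prob cpg_density (two bases), otherwise one random base
      out <- character(0)
      while (sum(nchar(out)) < len) {
        n_draw <- len  # generous; trimmed below
        cg <- runif(n_draw) < isl$cpg_density[i]
        piece <- ifelse(cg, "CG",
                        sample(BASES, n_draw, replace = TRUE, prob = probs))
        out <- c(out, piece)
      }
      island <- substr(paste(out, collapse = ""), 1L, len)
      substr(seqs[[chrom]], s + 1L, e) <- island
    }
  }

  new_ref_genome(seqs)
}

new_ref_genome <- function(seqs) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique names", call. = FALSE)
  chars <- strsplit(seqs, "", fixed = TRUE)
  cpg <- lapply(chars, function(ch) {
    n <- length(ch)
    if (n < 2L) return(integer(0))
    which(ch[-n] == "C" & ch[-1L] == "G") - 1L
  })
  structure(list(
    sequences = seqs,
    chrom_lengths = nchar(seqs),
    total_length = sum(nchar(seqs)),
    cpg_positions = cpg
  ), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d chromosome(s), %s bp, %s CpG sites (fwd)\n",
              length(x$sequences), format(x$total_length, big.mark = ","),
              format(sum(lengths(x$cpg_positions)), big.mark = ",")))
  invisible(x)
}

genome_chars <- function(genome, chrom) {
  strsplit(genome$sequences[[chrom]], "", fixed = TRUE)[[1]]
}

#' Coerce a reference genome to a Biostrings DNAStringSet
#' @param genome a `ref_genome`.
#' @return a [Biostrings::DNAStringSet].
#' @export
as_dnastringset <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  Biostrings::DNAStringSet(genome$sequences)
}

#' Define non-overlapping capture target regions
#'
#' Places `n_regions` disjoint intervals uniformly on the genome, a toy
#' stand-in for an exome capture design. Regions are BED-writable
#' (0-based, half-open) and sorted by chromosome and start.
#'
#' @param genome a `ref_genome`.
#' @param n_regions number of regions (>= 1).
#' @param min_len,max_len region length range in bp.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return an object of class `target_set`: a `data.table` with columns
#'   `chrom`, `start`, `end`, `id`, plus attribute `total_span`.
#' @export
define_targets <- function(genome, n_regions, min_len = 300L, max_len = 600L,
                           seed = 1L, max_tries = 100L * n_regions) {
  stopifnot(inherits(genome, "ref_genome"))
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  if (max_len < min_len) stop("max_len must be >= min_len", call. = FALSE)
  if (min_len < 1L) stop("region length must be >= 1", call. = FALSE)
  set.seed(substream_seed(seed, "targets"))

  lens <- genome$chrom_lengths
  placed <- vector("list", n_regions)
  n_placed <- 0L
  tries <- 0L
  while (n_placed < n_regions && tries < max_tries) {
    tries <- tries + 1L
    ch <- sample(names(lens), 1L, prob = lens)
    w <- sample_int_range(min_len, max_len, 1L)
    if (lens[[ch]] < w) next
    s <- sample.int(lens[[ch]] - w + 1L, 1L) - 1L
    ok <- TRUE
    if (n_placed > 0L) {
      prev <- rbindlist(placed[seq_len(n_placed)])
      hit <- prev[prev$chrom == ch & prev$start < s + w & prev$end > s]
      ok <- nrow(hit) == 0L
    }
    if (ok) {
      n_placed <- n_placed + 1L
      placed[[n_placed]] <- data.table(chrom = ch, start = s, end = s + w)
    }
  }
  if (n_placed < n_regions)
    stop(sprintf(
      "could only place %d of %d disjoint regions; genome too small",
      n_placed, n_regions), call. = FALSE)
  out <- rbindlist(placed)
  setorder(out, chrom, start)
  out[, id := sprintf("target_%04d", .I)]
  setattr(out, "total_span", sum(out$end - out$start))
  setattr(out, "class", c("target_set", class(out)))
  out[]
}

#' Total span of a target set in bp
#' @param targets a `target_set`.
#' @export
target_span <- function(targets) {
  attr(targets, "total_span") %||% sum(targets$end - targets$start)
}

targets_granges <- function(targets) {
  GenomicRanges::GRanges(targets$chrom,
                         IRanges::IRanges(targets$start + 1L, targets$end))
}

#' Plant heterozygous SNP sites on a reference genome
#'
#' Every reference position becomes heterozygous independently with
#' probability `density`; the alternate allele is drawn uniformly from the
#' other three bases. Allele pairs C/T and A/G (either order) are flagged
#' `bisulfite_ambiguous`: bisulfite conversion itself produces these
#' apparent genotypes, so downstream dropout analysis excludes them.
#'
#' @param genome a `ref_genome`.
#' @param density per-bp heterozygosity probability in (0, 1).
#' @param include_ambiguous if `FALSE`, alternate alleles are redrawn so no
#'   planted pair is bisulfite-ambiguous.
#' @param seed integer seed.
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `bisulfite_ambiguous`.
#' @export
plant_het_sites <- function(genome, density, include_ambiguous = TRUE,
                            seed = 1L) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!is.numeric(density) || density <= 0 || density >= 1)
    stop("'density' must lie strictly between 0 and 1", call. = FALSE)
  check_flag(include_ambiguous, "include_ambiguous")
  set.seed(substream_seed(seed, "hets"))

  out <- lapply(names(genome$sequences), function(chrom) {
    L <- genome$chrom_lengths[[chrom]]
    n <- rbinom(1L, L, density)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(L, n)) - 1L
    ref <- genome_chars(genome, chrom)[pos + 1L]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    data.table(chrom = chrom, pos = pos, ref = ref, alt = unname(alt))
  })
  sites <- rbindlist(out)
  if (nrow(sites) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      bisulfite_ambiguous = logical()))
  sites[, bisulfite_ambiguous := is_bs_ambiguous(ref, alt)]
  if (!include_ambiguous) {
    while (any(sites$bisulfite_ambiguous)) {
      idx <- which(sites$bisulfite_ambiguous)
      sites[idx, alt := vapply(ref, function(r)
        sample(setdiff(BASES, r), 1L), character(1))]
      sites[idx, bisulfite_ambiguous := is_bs_ambiguous(ref, alt)]
    }
  }
  sites[]
}

# C/T and A/G pairs (either order) are indistinguishable from conversion
is_bs_ambiguous <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "A" & alt == "G") | (ref == "G" & alt == "A")
}
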