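#' Generate a truth methylome over a reference genome
#'
#' Assigns a true methylation level to every cytosine on both strands.
#' CpG dinucleotides draw one shared level per Watson/Crick pair from a
#' two-component Beta mixture (symmetric CpG methylation is assumed, as in
#' mammalian somatic tissue), reproducing the bimodal landscape of mostly
#' fully methylated CpGs with a hypomethylated island fraction. Non-CpG
#' cytosines, essentially unmethylated in human somatic cells, all receive
#' the constant `noncpg_level`.
#'
#' @param genome a `ref_genome`.
#' @param cpg_beta_high,cpg_beta_low `c(shape1, shape2)` of the
#'   high-methylation and low-methylation Beta components.
#' @param p_high mixture weight of the high component, in `[0, 1]`.
#' @param noncpg_level constant true level for non-CpG cytosines (the
#'   ceiling the simulator guarantees for non-CpG methylation).
#' @param seed integer seed.
#' @return an object of class `methylome`: a `data.table` with one row per
#'   cytosine per strand — `chrom`, `pos` (0-based), `strand` (`+` Watson,
#'   `-` Crick), `context` (`"CpG"` or `"non-CpG"`), `true_level`.
#' @export
generate_methylome <- function(genome, cpg_beta_high = c(8, 1),
                               cpg_beta_low = c(1, 9), p_high = 0.7,
                               noncpg_level = 0.002, seed = 1L) {
  stopifnot(inherits(genome, "ref_genome"))
  check_prob(p_high, "p_high")
  check_prob(noncpg_level, "noncpg_level")
  stopifnot(length(cpg_beta_high) == 2L, length(cpg_beta_low) == 2L,
            all(cpg_beta_high > 0), all(cpg_beta_low > 0))
  set.seed(substream_seed(seed, "methylome"))

  per_chrom <- lapply(names(genome$sequences), function(chrom) {
    ch <- genome_chars(genome, chrom)
    watson <- which(ch == "C") - 1L          # C on forward strand
    crick <- which(ch == "G") - 1L           # C on reverse strand
    cpg <- genome$cpg_positions[[chrom]]     # Watson C of each CpG pair

    n_cpg <- length(cpg)
    high <- runif(n_cpg) < p_high
    lev <- numeric(n_cpg)
    lev[high] <- rbeta(sum(high), cpg_beta_high[1], cpg_beta_high[2])
    lev[!high] <- rbeta(sum(!high), cpg_beta_low[1], cpg_beta_low[2])

    cpg_level <- numeric(0)
    w <- data.table(chrom = chrom, pos = watson, strand = "+",
                    context = "non-CpG", true_level = noncpg_level)
    c_ <- data.table(chrom = chrom, pos = crick, strand = "-",
                     context = "non-CpG", true_level = noncpg_level)
    if (n_cpg) {
      # Watson member at p, Crick member at p+1; both share the pair level
      w[match(cpg, watson), `:=`(context = "CpG", true_level = lev)]
      c_[match(cpg + 1L, crick), `:=`(context = "CpG", true_level = lev)]
    }
    rbind(w, c_)
  })
  out <- rbindlist(per_chrom)
  setorder(out, chrom, pos, strand)
  setattr(out, "class", c("methylome", class(out)))
  out[]
}

#' @export
print.methylome <- function(x, ...) {
  n_cpg <- sum(x$context == "CpG")
  cat(sprintf(
    "<methylome> %d cytosine entries (%d CpG, %d non-CpG), mean CpG level %.3f\n",
    nrow(x), n_cpg, nrow(x) - n_cpg,
    if (n_cpg) mean(x$true_level[x$context == "CpG"]) else NA_real_))
  invisible(x)
}

# fast per-(chrom,strand) lookup vectors of true level, indexed by pos + 1
methylome_lookup <- function(methylome, genome) {
  lk <- list()
  for (chrom in names(genome$sequences)) {
    L <- genome$chrom_lengths[[chrom]]
    for (strand in c("+", "-")) {
      v <- rep(NA_real_, L)
      sub <- methylome[methylome$chrom == chrom & methylome$strand == strand, ]
      v[sub$pos + 1L] <- sub$true_level
      lk[[paste0(chrom, strand)]] <- v
    }
  }
  lk
}
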