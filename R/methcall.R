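#' Per-cytosine methylation pileup
#'
#' C-to-T-space records inform Watson-strand cytosines: a read C over a
#' reference C is a methylated observation, a read T an unmethylated one;
#' G-to-A-space records symmetrically inform Crick-strand cytosines (read G
#' methylated, read A unmethylated). Any other read base at a reference
#' cytosine is ignored for that site, as are bases below the quality
#' threshold. The raw level is `mC reads / (C reads + mC reads) * 100`.
#'
#' @param alignment a deduplicated `bs_alignment`.
#' @param genome the `ref_genome` the records were aligned to.
#' @param min_base_quality minimum phred base quality (the simulator emits
#'   constant qualities, so the default 0 keeps every base).
#' @param quals optional named character vector of quality strings per read
#'   (`qname` + mate order as in the records); only needed when
#'   `min_base_quality > 0`.
#' @return an object of class `cytosine_calls`: a `data.table` with
#'   `chrom`, `pos` (0-based), `strand`, `context` (CpG/CHG/CHH),
#'   `count_methylated`, `count_unmethylated`, `depth`, `raw_level` (%).
#' @export
pileup <- function(alignment, genome, min_base_quality = 0, quals = NULL) {
  stopifnot(inherits(alignment, "bs_alignment"),
            inherits(genome, "ref_genome"))
  rec <- kept_records(alignment)
  if (nrow(rec) == 0L) return(empty_calls())

  lens <- genome$chrom_lengths
  if (any(rec$end > lens[rec$chrom] | rec$start < 0L))
    stop("alignment record overhangs a chromosome end (alignment bug)",
         call. = FALSE)

  ex <- explode_seqs(rec$seq)
  base <- ex$chars
  ri <- ex$seq_id
  gpos <- rec$start[ri] + ex$offset
  chrom <- rec$chrom[ri]
  space <- rec$space[ri]

  if (min_base_quality > 0 && !is.null(quals)) {
    qkey <- paste0(rec$qname, "/", rec$mate)
    qx <- explode_seqs(unname(quals[qkey]))
    keepq <- utf8ToInt(paste(qx$chars, collapse = "")) - 33L >=
      min_base_quality
    base <- base[keepq]; ri <- ri[keepq]; gpos <- gpos[keepq]
    chrom <- chrom[keepq]; space <- space[keepq]
  }

  # reference base under each read base
  refbase <- character(length(base))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    refbase[sel] <- genome_chars(genome, ch)[gpos[sel] + 1L]
  }

  watson <- space == "CT" & refbase == "C" & base %in% c("C", "T")
  crick <- space == "GA" & refbase == "G" & base %in% c("G", "A")

  obs <- data.table(
    chrom = c(chrom[watson], chrom[crick]),
    pos = c(gpos[watson], gpos[crick]),
    strand = rep(c("+", "-"), c(sum(watson), sum(crick))),
    meth = c(base[watson] == "C", base[crick] == "G"))
  if (nrow(obs) == 0L) return(empty_calls())

  calls <- obs[, .(count_methylated = sum(meth),
                   count_unmethylated = sum(!meth)),
               by = .(chrom, pos, strand)]
  calls[, depth := count_methylated + count_unmethylated]
  calls[, raw_level := 100 * count_methylated / depth]
  calls[, context := classify_context(genome, chrom, pos, strand)]
  setorder(calls, chrom, pos, strand)
  out <- calls[, .(chrom, pos, strand, context, count_methylated,
                   count_unmethylated, depth, raw_level)]
  setattr(out, "class", c("cytosine_calls", class(out)))
  out[]
}

empty_calls <- function() {
  out <- data.table(chrom = character(), pos = integer(),
                    strand = character(), context = character(),
                    count_methylated = integer(),
                    count_unmethylated = integer(), depth = integer(),
                    raw_level = numeric())
  setattr(out, "class", c("cytosine_calls", class(out)))
  out[]
}

#' Classify the trinucleotide context of cytosines
#'
#' Standard rule on the informative strand: `CG` -> CpG, `CHG` -> CHG,
#' otherwise CHH. Positions too close to a chromosome end to classify
#' default to CHH.
#'
#' @param genome a `ref_genome`.
#' @param chrom,pos,strand vectors describing cytosine positions (0-based).
#' @return a character vector of `"CpG"`, `"CHG"`, `"CHH"`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  stopifnot(inherits(genome, "ref_genome"))
  n <- length(pos)
  out <- character(n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    chars <- genome_chars(genome, ch)
    L <- length(chars)
    p <- pos[sel]
    s <- strand[sel]
    here <- ifelse(s == "+", chars[p + 1L], comp_base(chars[p + 1L]))
    if (any(here != "C"))
      stop("classify_context called on a non-cytosine position",
           call. = FALSE)
    nxt1 <- ifelse(s == "+",
                   ifelse(p + 1L < L, chars[pmin(p + 2L, L)], NA),
                   ifelse(p - 1L >= 0L, comp_base(chars[pmax(p, 1L)]), NA))
    nxt2 <- ifelse(s == "+",
                   ifelse(p + 2L < L, chars[pmin(p + 3L, L)], NA),
                   ifelse(p - 2L >= 0L, comp_base(chars[pmax(p - 1L, 1L)]),
                          NA))
    ctx <- rep("CHH", length(p))
    ctx[!is.na(nxt1) & nxt1 == "G"] <- "CpG"
    ctx[(is.na(nxt1) | nxt1 != "G") & !is.na(nxt2) & nxt2 == "G"] <- "CHG"
    out[sel] <- ctx
  }
  out
}

comp_base <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(comp[x])
}

#' Estimate the library non-conversion rate
#'
#' Unmethylated cytosines that escape bisulfite conversion still read as C;
#' since non-CpG methylation is essentially absent in human somatic cells,
#' the pooled methylated fraction at non-CpG sites estimates this
#' non-conversion background: `e = sum(mC) / sum(depth)` over non-CpG
#' calls, both strands, one global rate per library. When a fully
#' unmethylated carrier chromosome (e.g. a lambda spike-in) is present, its
#' cytosines can be used instead via `carrier_chroms`.
#'
#' @param calls a `cytosine_calls` table.
#' @param carrier_chroms optional chromosome names of an unmethylated
#'   carrier; when given, all cytosines on them (any context) are pooled.
#' @return an object of class `conversion_estimate`: list with
#'   `nonconversion_rate`, `n_sites`, `n_calls`.
#' @export
estimate_nonconversion <- function(calls, carrier_chroms = NULL) {
  sub <- if (is.null(carrier_chroms)) calls[context != "CpG"]
         else calls[chrom %in% carrier_chroms]
  sub <- sub[depth > 0L]
  if (nrow(sub) == 0L || sum(sub$depth) == 0L)
    stop("cannot estimate non-conversion: no qualifying cytosine depth",
         call. = FALSE)
  structure(list(
    nonconversion_rate = sum(sub$count_methylated) / sum(sub$depth),
    n_sites = nrow(sub), n_calls = sum(sub$depth)
  ), class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "<conversion_estimate> non-conversion %.4f (%d sites, %d calls)\n",
    x$nonconversion_rate, x$n_sites, x$n_calls))
  invisible(x)
}

#' Correct CpG methylation levels for incomplete conversion
#'
#' Background subtraction with renormalization: the corrected methylated
#' fraction is `max(0, (raw - e) / (1 - e))` where `e` is the global
#' non-conversion rate, reported in percent. Applied to CpG calls only;
#' non-CpG calls keep their raw levels (they define the background). The
#' raw level is always retained alongside, so the correction is invertible.
#'
#' @param calls a `cytosine_calls` table.
#' @param estimate a `conversion_estimate` (or a bare rate in `[0, 1)`).
#' @return the calls with an added `corrected_level` column (%).
#' @export
correct_levels <- function(calls, estimate) {
  e <- if (inherits(estimate, "conversion_estimate"))
    estimate$nonconversion_rate else estimate
  check_prob(e, "nonconversion rate")
  if (e >= 1)
    stop("non-conversion rate of 1: degenerate library, cannot correct",
         call. = FALSE)
  out <- copy(calls)
  raw_frac <- out$raw_level / 100
  corr <- pmax(0, (raw_frac - e) / (1 - e)) * 100
  out[, corrected_level := ifelse(context == "CpG", corr, raw_level)]
  setattr(out, "class", unique(c("cytosine_calls", class(out))))
  out[]
}
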