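# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: the Fisher oracle enumerates the
# hypergeometric support with choose(), and the alignment oracle scans
# every genome position.

oracle_fisher <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(1)
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  supp <- max(0, k - n):min(k, m)
  prob <- vapply(supp, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
  p_obs <- prob[match(a, supp)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp_chars <- function(ch) rev(unname(.ORACLE_COMP[ch]))

# position-exhaustive bisulfite-aware alignment of one read against a
# named list of chromosome character vectors; returns every placement
# within the seed and total mismatch budgets
oracle_align_read <- function(read, chrom_chars, seed_len = 30L,
                              seed_max = 2L, total_max = 5L) {
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  len <- length(rch)
  if (len < seed_len) return(NULL)
  out <- list()
  for (chrom in names(chrom_chars)) {
    g <- chrom_chars[[chrom]]
    L <- length(g)
    if (L < len) next
    n_start <- L - len + 1L
    for (space in c("CT", "GA")) {
      for (orient in c("fwd", "rc")) {
        form <- if (orient == "fwd") rch else oracle_revcomp_chars(rch)
        mm <- integer(n_start); smm <- integer(n_start)
        for (j in seq_len(len)) {
          rb <- form[j]
          gb <- g[j:(j + n_start - 1L)]
          allowed <- if (space == "CT") rb == "T" & gb == "C"
                     else rb == "A" & gb == "G"
          mis <- gb != rb & !allowed
          mm <- mm + mis
          in_seed <- if (orient == "fwd") j <= seed_len
                     else j > len - seed_len
          if (in_seed) smm <- smm + mis
        }
        keep <- which(smm <= seed_max & mm <= total_max)
        if (length(keep))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = keep - 1L,
            strand = if (orient == "fwd") "+" else "-",
            space = space, mm = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# independent pair resolution over oracle hit tables (simple loops):
# proper pairs (same chrom/space, opposite strand, plus leftmost, outer
# span bounded) outrank singles; fewest mismatches; unique iff one top
oracle_resolve_pair <- function(h1, h2, len1, len2, max_insert = 1000L) {
  pairs <- NULL
  if (!is.null(h1) && !is.null(h2)) {
    for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
      if (h1$chrom[i] != h2$chrom[j]) next
      if (h1$space[i] != h2$space[j]) next
      if (h1$strand[i] == h2$strand[j]) next
      sp <- if (h1$strand[i] == "+") h1$start[i] else h2$start[j]
      sm <- if (h1$strand[i] == "+") h2$start[j] else h1$start[i]
      if (sp > sm) next
      outer <- max(h1$start[i] + len1, h2$start[j] + len2) -
        min(h1$start[i], h2$start[j])
      if (outer > max_insert) next
      pairs <- rbind(pairs, data.frame(
        chrom = h1$chrom[i], start1 = h1$start[i], start2 = h2$start[j],
        space = h1$space[i], strand1 = h1$strand[i],
        mm1 = h1$mm[i], mm2 = h2$mm[j], score = h1$mm[i] + h2$mm[j]))
    }
  }
  if (!is.null(pairs)) {
    top <- pairs[pairs$score == min(pairs$score), , drop = FALSE]
    if (nrow(top) == 1L)
      return(list(status = "unique_pair", placement = top))
    return(list(status = "multi"))
  }
  single <- function(h) {
    if (is.null(h)) return(list(status = "unmapped"))
    top <- h[h$mm == min(h$mm), , drop = FALSE]
    if (nrow(top) == 1L) list(status = "unique", placement = top)
    else list(status = "multi")
  }
  list(status = "single", r1 = single(h1), r2 = single(h2))
}

genome_char_list <- function(genome) {
  lapply(setNames(names(genome$sequences), names(genome$sequences)),
         function(ch) strsplit(genome$sequences[[ch]], "", fixed = TRUE)[[1]])
}
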