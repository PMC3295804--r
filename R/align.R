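#' Aligner parameters
#'
#' Mirrors the short-read constraints the workflow assumes: a 30 bp seed
#' with at most 2 mismatches, at most 5 mismatches over the whole read, and
#' gap-free alignment (gap counts enter only the ranking and default to
#' disabled).
#'
#' Bisulfite-consistent substitutions (read T over reference C in C-to-T
#' space, read A over reference G in G-to-A space) never count as
#' mismatches, in the seed or in the total.
#'
#' @param seed_length seed length in bp (must not exceed the read length).
#' @param seed_max_mismatches mismatch budget inside the seed.
#' @param total_max_mismatches mismatch budget over the whole read.
#' @param max_gaps maximum gaps (only 0 is supported; gap-free alignment).
#' @param max_insert maximum outer distance of a properly paired alignment.
#' @return an object of class `aligner_params`.
#' @export
aligner_params <- function(seed_length = 30L, seed_max_mismatches = 2L,
                           total_max_mismatches = 5L, max_gaps = 0L,
                           max_insert = 1000L) {
  seed_length <- check_count(seed_length, "seed_length", min = 4L)
  seed_max_mismatches <- check_count(seed_max_mismatches,
                                     "seed_max_mismatches")
  total_max_mismatches <- check_count(total_max_mismatches,
                                      "total_max_mismatches")
  max_gaps <- check_count(max_gaps, "max_gaps")
  if (max_gaps != 0L)
    stop("gapped alignment is not supported (max_gaps must be 0)",
         call. = FALSE)
  if (seed_max_mismatches > total_max_mismatches)
    stop("seed_max_mismatches must be <= total_max_mismatches",
         call. = FALSE)
  k <- seed_length %/% (seed_max_mismatches + 1L)
  if (k < 4L)
    stop("seed too short for the mismatch budget (k-mer anchor < 4 bp)",
         call. = FALSE)
  structure(list(seed_length = seed_length,
                 seed_max_mismatches = seed_max_mismatches,
                 total_max_mismatches = total_max_mismatches,
                 max_gaps = max_gaps, max_insert = check_count(
                   max_insert, "max_insert", min = 1L),
                 kmer = k),
            class = "aligner_params")
}

#' Build bisulfite-converted reference indexes
#'
#' Creates two reduced-alphabet views of the reference — C-to-T (informative
#' for original-top-strand molecules) and G-to-A (original bottom) — each
#' with an exact k-mer anchor index. The anchor length is
#' `seed_length %/% (seed_max_mismatches + 1)`, so by pigeonhole every seed
#' alignment within the mismatch budget contains at least one exact anchor.
#' The original sequence is retained for bisulfite-aware mismatch
#' re-evaluation.
#'
#' @param genome a `ref_genome`.
#' @param params an `aligner_params` object.
#' @return an object of class `bs_index`.
#' @export
build_converted_indexes <- function(genome, params = aligner_params()) {
  stopifnot(inherits(genome, "ref_genome"))
  if (genome$total_length == 0L) stop("empty genome", call. = FALSE)
  k <- params$kmer

  chrom_names <- names(genome$sequences)
  lens <- unname(genome$chrom_lengths)
  offsets <- cumsum(c(0L, lens[-length(lens)]))  # global 0-based starts
  orig <- unlist(strsplit(genome$sequences, "", fixed = TRUE),
                 use.names = FALSE)
  n <- length(orig)

  base_code <- function(chars, space) {
    v <- match(chars, BASES) - 1
    if (space == "CT") v[chars == "C"] <- 3
    if (space == "GA") v[chars == "G"] <- 0
    v
  }
  chrom_of <- function(g) findInterval(g, offsets)  # 1-based chrom index

  make_index <- function(space) {
    v <- base_code(orig, space)
    m <- n - k + 1L
    if (m < 1L) stop("genome shorter than anchor k-mer", call. = FALSE)
    kc <- v[seq_len(m)]
    for (j in 2:k) kc <- kc * 4 + v[j:(m + j - 1L)]
    g <- seq_len(m) - 1L
    keep <- !is.na(kc) & chrom_of(g) == chrom_of(g + k - 1L)
    list2env(split(g[keep], kc[keep]), envir = new.env(hash = TRUE))
  }

  structure(list(
    chrom_names = chrom_names, chrom_lengths = lens, offsets = offsets,
    orig = orig, n = n, k = k,
    anchors = list(CT = make_index("CT"), GA = make_index("GA")),
    converted_seq = list(
      CT = chartr("C", "T", genome$sequences),
      GA = chartr("G", "A", genome$sequences))
  ), class = "bs_index")
}

#' @export
print.bs_index <- function(x, ...) {
  cat(sprintf("<bs_index> %d chromosome(s), %s bp, %d-mer anchors\n",
              length(x$chrom_names), format(x$n, big.mark = ","), x$k))
  invisible(x)
}

# candidate hits for a vector of reads in one space x orientation combo.
# Returns a data.table: read, chromi, start (0-based local), len, strand,
# space, mm, seed_mm.
find_hits_combo <- function(reads, index, params, space, orient) {
  n_reads <- length(reads)
  S <- params$seed_length
  k <- index$k
  lens <- nchar(reads)
  eligible <- which(lens >= S)
  if (length(eligible) == 0L) return(empty_hits())

  form <- if (orient == "fwd") reads else revcomp(reads)
  conv <- if (space == "CT") chartr("C", "T", form) else chartr("G", "A", form)

  n_chunks <- params$seed_max_mismatches + 1L
  env <- index$anchors[[space]]

  cand_read <- integer(0); cand_g <- numeric(0)
  acc_r <- vector("list", length(eligible)); acc_g <- vector("list", length(eligible))
  for (ii in seq_along(eligible)) {
    i <- eligible[ii]
    len <- lens[i]
    seed_from <- if (orient == "fwd") 1L else len - S + 1L
    cs <- seed_from + (seq_len(n_chunks) - 1L) * k
    keys <- chartr("ACGT", "0123", substring(conv[i], cs, cs + k - 1L))
    codes <- strtoi(keys, base = 4L)
    starts <- numeric(0)
    for (j in seq_len(n_chunks)) {
      if (is.na(codes[j])) next
      p <- env[[as.character(codes[j])]]
      if (!is.null(p)) starts <- c(starts, p - (cs[j] - 1L))
    }
    if (length(starts)) {
      starts <- unique(starts)
      acc_r[[ii]] <- rep.int(i, length(starts))
      acc_g[[ii]] <- starts
    }
  }
  cand_read <- unlist(acc_r, use.names = FALSE)
  cand_g <- unlist(acc_g, use.names = FALSE)
  if (length(cand_read) == 0L) return(empty_hits())

  cand_len <- lens[cand_read]
  # candidate must lie fully inside one chromosome
  ok <- cand_g >= 0 & cand_g + cand_len - 1 < index$n
  chromi <- findInterval(cand_g, index$offsets)
  chromi_end <- findInterval(cand_g + cand_len - 1, index$offsets)
  ok <- ok & chromi == chromi_end
  cand_read <- cand_read[ok]; cand_g <- cand_g[ok]
  cand_len <- cand_len[ok]; chromi <- chromi[ok]
  if (length(cand_read) == 0L) return(empty_hits())

  # vectorized bisulfite-aware mismatch counting in original space
  maxlen <- max(cand_len)
  ch <- strsplit(form, "", fixed = TRUE)
  mat <- matrix("X", n_reads, maxlen)
  use <- unique(cand_read)
  for (i in use) mat[i, seq_len(lens[i])] <- ch[[i]]

  m <- length(cand_read)
  tot <- integer(m); seed_cnt <- integer(m)
  for (j in seq_len(maxlen)) {
    sel <- which(cand_len >= j)
    if (length(sel) == 0L) break
    rb <- mat[cbind(cand_read[sel], j)]
    gb <- index$orig[cand_g[sel] + j]
    allowed <- if (space == "CT") rb == "T" & gb == "C"
               else rb == "A" & gb == "G"
    mism <- rb != gb & !allowed
    tot[sel] <- tot[sel] + mism
    in_seed <- if (orient == "fwd") j <= S
               else j > cand_len[sel] - S
    ss <- sel[in_seed & mism]
    seed_cnt[ss] <- seed_cnt[ss] + 1L
  }

  keep <- seed_cnt <= params$seed_max_mismatches &
    tot <= params$total_max_mismatches
  if (!any(keep)) return(empty_hits())
  data.table(read = cand_read[keep], chromi = chromi[keep],
             start = as.integer(cand_g[keep] -
                                  index$offsets[chromi[keep]]),
             len = cand_len[keep],
             strand = if (orient == "fwd") "+" else "-",
             space = space, mm = tot[keep], seed_mm = seed_cnt[keep])
}

empty_hits <- function() {
  data.table(read = integer(), chromi = integer(), start = integer(),
             len = integer(), strand = character(), space = character(),
             mm = integer(), seed_mm = integer())
}

# all candidate hits for a vector of reads (both spaces, both orientations)
find_hits <- function(reads, index, params) {
  rbindlist(list(
    find_hits_combo(reads, index, params, "CT", "fwd"),
    find_hits_combo(reads, index, params, "CT", "rc"),
    find_hits_combo(reads, index, params, "GA", "fwd"),
    find_hits_combo(reads, index, params, "GA", "rc")))
}

#' Candidate alignments for one read pair
#'
#' Searches the C-to-T converted read against the C-to-T reference space
#' (forward) and the G-to-A space (reverse-complement orientation), and
#' symmetrically for the G-to-A conversion; candidates must satisfy both
#' the seed and the total mismatch budgets, with bisulfite-consistent
#' substitutions exempt.
#'
#' @param read1,read2 read sequences (character scalars; `read2` may be
#'   `NA` for a single-end query).
#' @param index a `bs_index`.
#' @param params an `aligner_params`.
#' @return a list with `hits1` and `hits2`, each a `data.table` of
#'   candidate hits (`chrom`, `start`, `strand`, `space`, `mm`, `seed_mm`).
#' @export
align_pair <- function(read1, read2 = NA_character_, index,
                       params = aligner_params()) {
  stopifnot(inherits(index, "bs_index"))
  label_hit <- function(h) {
    h[, chrom := index$chrom_names[chromi]]
    h[, .(chrom, start, len, strand, space, mm, seed_mm)]
  }
  h1 <- label_hit(find_hits(read1, index, params))
  h2 <- if (is.na(read2)) empty_hits()[, .(chrom = character(), start, len,
                                           strand, space, mm, seed_mm)]
        else label_hit(find_hits(read2, index, params))
  list(hits1 = h1, hits2 = h2)
}

#' Select the unique best alignment for read pairs
#'
#' Properly paired placements (same chromosome and conversion space,
#' opposite strands, plus-strand mate leftmost, outer span within
#' `max_insert`) outrank single-end placements; within a rank class,
#' placements with fewer gaps plus mismatches win. A read is `unique` iff
#' exactly one top-ranked placement survives, `multi` if several tie, and
#' `unmapped` with no candidates. Only unique records feed downstream
#' counting.
#'
#' @param hits1,hits2 candidate tables from the hit search (internal
#'   column layout), one read pair.
#' @param params an `aligner_params`.
#' @return a `data.table` with one row per mate: `mate`, `status`, and for
#'   unique reads the placement columns.
#' @export
select_unique_best <- function(hits1, hits2, params = aligner_params()) {
  h1 <- copy(as.data.table(hits1)); h2 <- copy(as.data.table(hits2))
  if (!"chromi" %in% names(h1) || !"chromi" %in% names(h2)) {
    chroms <- sort(unique(c(h1$chrom, h2$chrom)))
    h1[, chromi := match(chrom, chroms)]
    h2[, chromi := match(chrom, chroms)]
  }
  h1[, `:=`(pid = 1L, mate = 1L)]
  h2[, `:=`(pid = 1L, mate = 2L)]
  sel <- select_pairs(h1, h2, params, n_pairs = 1L)
  sel$records
}

# vectorized pair selection over many pairs; hits carry pid and mate
select_pairs <- function(hits1, hits2, params, n_pairs) {
  proper <- NULL
  if (nrow(hits1) && nrow(hits2)) {
    proper <- merge(hits1, hits2, by = c("pid", "chromi", "space"),
                    suffixes = c("_1", "_2"), allow.cartesian = TRUE)
    if (nrow(proper)) {
      proper <- proper[strand_1 != strand_2]
      proper[, start_plus := ifelse(strand_1 == "+", start_1, start_2)]
      proper[, start_minus := ifelse(strand_1 == "+", start_2, start_1)]
      proper[, outer_start := pmin(start_1, start_2)]
      proper[, outer_end := pmax(start_1 + len_1, start_2 + len_2)]
      proper <- proper[start_plus <= start_minus &
                         outer_end - outer_start <= params$max_insert]
      proper[, score := mm_1 + mm_2]
    }
  }

  res_pairs <- NULL
  paired_pids <- integer(0)
  if (!is.null(proper) && nrow(proper)) {
    proper[, best := score == min(score), by = pid]
    top <- proper[best == TRUE]
    top[, n_top := .N, by = pid]
    paired_pids <- unique(top$pid)
    res_pairs <- top
  }

  # single-end resolution for pids without any proper pairing
  singles <- rbind(hits1, hits2)
  singles <- singles[!pid %in% paired_pids]
  res_single <- NULL
  if (nrow(singles)) {
    singles[, best := mm == min(mm), by = .(pid, mate)]
    res_single <- singles[best == TRUE]
    res_single[, n_top := .N, by = .(pid, mate)]
  }

  list(pairs = res_pairs, singles = res_single,
       records = build_pair_records(res_pairs, res_single))
}

build_pair_records <- function(pairs, singles) {
  out <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    uq <- pairs[n_top == 1L]
    if (nrow(uq)) {
      out[[length(out) + 1L]] <- rbind(
        uq[, .(pid, mate = 1L, chromi, start = start_1, len = len_1,
               strand = strand_1, space, mm = mm_1, paired = TRUE,
               outer_start, outer_end, status = "unique")],
        uq[, .(pid, mate = 2L, chromi, start = start_2, len = len_2,
               strand = strand_2, space, mm = mm_2, paired = TRUE,
               outer_start, outer_end, status = "unique")])
    }
    mu <- unique(pairs[n_top > 1L, .(pid)])
    if (nrow(mu)) {
      out[[length(out) + 1L]] <- rbind(
        mu[, .(pid, mate = 1L, chromi = NA_integer_, start = NA_integer_,
               len = NA_integer_, strand = NA_character_,
               space = NA_character_, mm = NA_integer_, paired = TRUE,
               outer_start = NA_integer_, outer_end = NA_integer_,
               status = "multi")],
        mu[, .(pid, mate = 2L, chromi = NA_integer_, start = NA_integer_,
               len = NA_integer_, strand = NA_character_,
               space = NA_character_, mm = NA_integer_, paired = TRUE,
               outer_start = NA_integer_, outer_end = NA_integer_,
               status = "multi")])
    }
  }
  if (!is.null(singles) && nrow(singles)) {
    uq <- singles[n_top == 1L]
    if (nrow(uq)) {
      out[[length(out) + 1L]] <-
        uq[, .(pid, mate, chromi, start, len, strand, space, mm,
               paired = FALSE, outer_start = start,
               outer_end = start + len, status = "unique")]
    }
    mu <- unique(singles[n_top > 1L, .(pid, mate)])
    if (nrow(mu)) {
      out[[length(out) + 1L]] <-
        mu[, .(pid, mate, chromi = NA_integer_, start = NA_integer_,
               len = NA_integer_, strand = NA_character_,
               space = NA_character_, mm = NA_integer_, paired = FALSE,
               outer_start = NA_integer_, outer_end = NA_integer_,
               status = "multi")]
    }
  }
  if (length(out) == 0L) return(empty_records())
  rbindlist(out)
}

empty_records <- function() {
  data.table(pid = integer(), mate = integer(), chromi = integer(),
             start = integer(), len = integer(), strand = character(),
             space = character(), mm = integer(), paired = logical(),
             outer_start = integer(), outer_end = integer(),
             status = character())
}

#' Align a simulated or real paired-end library
#'
#' Runs the candidate search, pair-aware unique-best selection and status
#' bookkeeping for every read pair in the library.
#'
#' @param reads1,reads2 character vectors of mate sequences.
#' @param qnames read-pair names.
#' @param index a `bs_index`.
#' @param params an `aligner_params`.
#' @return an object of class `bs_alignment`: `records` (unique alignments,
#'   one row per mate, with genome-forward sequence), `multi` (reads tied at
#'   the top rank), and `stats` (pairs, unique/multi/unmapped read counts,
#'   reads skipped as shorter than the seed).
#' @export
align_library <- function(reads1, reads2, qnames, index,
                          params = aligner_params()) {
  stopifnot(length(reads1) == length(reads2),
            length(qnames) == length(reads1))
  n_pairs <- length(reads1)
  if (n_pairs == 0L)
    return(structure(list(records = empty_records(), multi = NULL,
                          stats = list(n_pairs = 0L)),
                     class = "bs_alignment"))

  S <- params$seed_length
  skipped <- sum(nchar(reads1) < S) + sum(nchar(reads2) < S)

  h1 <- find_hits(reads1, index, params)
  setnames(h1, "read", "pid"); h1[, mate := 1L]
  h2 <- find_hits(reads2, index, params)
  setnames(h2, "read", "pid"); h2[, mate := 2L]

  sel <- select_pairs(h1, h2, params, n_pairs)
  rec <- sel$records

  uniq <- rec[status == "unique"]
  uniq[, qname := qnames[pid]]
  uniq[, chrom := index$chrom_names[chromi]]
  uniq[, end := start + len]
  # genome-forward read sequence for pileup
  uniq[, seq := ifelse(mate == 1L, reads1[pid], reads2[pid])]
  flip <- which(uniq$strand == "-")
  if (length(flip)) uniq$seq[flip] <- revcomp(uniq$seq[flip])

  multi <- rec[status == "multi"][, .(pid, mate)]
  multi[, qname := qnames[pid]]

  n_unique <- nrow(uniq)
  n_multi <- nrow(multi)
  n_unmapped <- 2L * n_pairs - n_unique - n_multi

  structure(list(
    records = uniq[, .(qname, pid, mate, chrom, start, end, len, strand,
                       space, mm, gaps = 0L, paired, outer_start,
                       outer_end, status, seq)],
    multi = multi,
    stats = list(n_pairs = n_pairs, n_reads = 2L * n_pairs,
                 unique_reads = n_unique, multi_reads = n_multi,
                 unmapped_reads = n_unmapped, skipped_short = skipped,
                 unique_map_rate = 100 * n_unique / (2L * n_pairs)),
    params = params
  ), class = "bs_alignment")
}

#' @export
print.bs_alignment <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<bs_alignment> %d pairs: %d unique reads (%.2f%%), %d multi, %d unmapped\n",
    s$n_pairs, s$unique_reads, s$unique_map_rate %||% NA_real_,
    s$multi_reads %||% 0L, s$unmapped_reads %||% 0L))
  invisible(x)
}

#' Collapse PCR duplicates among unique alignments
#'
#' Duplicate group key: chromosome, pair outer start, pair outer end,
#' conversion space and strand (single-end records use their own span).
#' Within a group the member with the fewest gaps plus mismatches is kept;
#' ties break by highest summed base quality, then lexicographically
#' smallest read name, so the outcome is deterministic.
#'
#' @param alignment a `bs_alignment`.
#' @param quals optional named list/vectors of base qualities used for the
#'   tie-break (summed phred); omitted = all equal.
#' @return the `bs_alignment` with `records` gaining `duplicate_group` and
#'   `is_duplicate`, and a `dedup_report` (`n_units`, `n_removed`,
#'   `duplication_rate` in % of unique-aligned units removed).
#' @export
deduplicate <- function(alignment, quals = NULL) {
  stopifnot(inherits(alignment, "bs_alignment"))
  rec <- copy(alignment$records)
  if (nrow(rec) == 0L) {
    alignment$dedup_report <- list(n_units = 0L, n_removed = 0L,
                                   duplication_rate = NA_real_)
    return(alignment)
  }
  # one unit per pair (or per single-end read)
  units <- rec[, .(
    chrom = chrom[1L],
    outer_start = outer_start[1L], outer_end = outer_end[1L],
    space = space[1L],
    strand = strand[mate == min(mate)][1L],
    mm_sum = sum(mm), len_sum = sum(len), paired = paired[1L]
  ), by = .(qname, pid)]
  if (!is.null(quals)) {
    qsum <- vapply(quals, function(q) sum(utf8ToInt(q)), numeric(1))
    units[, qual_sum := qsum[qname]]
  } else units[, qual_sum := as.numeric(len_sum)]

  setorder(units, chrom, outer_start, outer_end, space, strand,
           mm_sum, -qual_sum, qname)
  units[, duplicate_group := .GRP,
        by = .(chrom, outer_start, outer_end, space, strand)]
  units[, is_duplicate := seq_len(.N) > 1L, by = duplicate_group]

  rec <- merge(rec, units[, .(pid, duplicate_group, is_duplicate)],
               by = "pid", sort = FALSE)
  setorder(rec, pid, mate)
  alignment$records <- rec
  n_units <- nrow(units)
  n_removed <- sum(units$is_duplicate)
  alignment$dedup_report <- list(
    n_units = n_units, n_removed = n_removed,
    duplication_rate = 100 * n_removed / n_units)
  alignment
}

# records that feed all downstream counting: unique and duplicate-collapsed
kept_records <- function(alignment) {
  rec <- alignment$records
  if (!"is_duplicate" %in% names(rec))
    stop("run deduplicate() before downstream counting", call. = FALSE)
  rec[is_duplicate == FALSE]
}
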