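#' Generate simple gene models on a reference genome
#'
#' Places non-overlapping multi-exon gene models (uniform placement, both
#' strands) for metagene profiling. Coordinates are 0-based half-open.
#'
#' @param genome a `ref_genome`.
#' @param n_genes number of genes.
#' @param n_exons_range range of exon counts per gene.
#' @param exon_len_range,intron_len_range bp ranges.
#' @param flank clearance kept free around each gene (bp), so upstream and
#'   downstream windows do not run off the chromosome.
#' @param seed integer seed.
#' @return a `data.table` of class `gene_models`: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `exon_rank` (one row per exon, transcript
#'   order on the genome's forward coordinates).
#' @export
generate_gene_models <- function(genome, n_genes = 20L,
                                 n_exons_range = c(3L, 6L),
                                 exon_len_range = c(120L, 400L),
                                 intron_len_range = c(200L, 600L),
                                 flank = 2200L, seed = 1L) {
  stopifnot(inherits(genome, "ref_genome"))
  set.seed(substream_seed(seed, "genes"))
  lens <- genome$chrom_lengths
  out <- list()
  occupied <- data.table(chrom = character(), start = integer(),
                         end = integer())
  tries <- 0L
  while (length(out) < n_genes && tries < 200L * n_genes) {
    tries <- tries + 1L
    ch <- sample(names(lens), 1L, prob = lens)
    ne <- sample_int_range(n_exons_range[1], n_exons_range[2], 1L)
    ew <- sample_int_range(exon_len_range[1], exon_len_range[2], ne)
    iw <- if (ne > 1L)
      sample_int_range(intron_len_range[1], intron_len_range[2], ne - 1L)
    else integer(0)
    span <- sum(ew) + sum(iw)
    if (lens[[ch]] < span + 2L * flank) next
    s <- sample.int(lens[[ch]] - span - 2L * flank + 1L, 1L) - 1L + flank
    if (nrow(occupied[chrom == ch & start < s + span + flank &
                      end > s - flank])) next
    strand <- sample(c("+", "-"), 1L)
    starts <- s + cumsum(c(0L, head(ew, -1L) + iw))
    gid <- sprintf("gene_%03d", length(out) + 1L)
    occupied <- rbind(occupied,
                      data.table(chrom = ch, start = s, end = s + span))
    rank <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
    out[[length(out) + 1L]] <- data.table(
      gene_id = gid, chrom = ch, strand = strand,
      start = starts, end = starts + ew, exon_rank = rank)
  }
  if (length(out) < n_genes)
    stop("could not place the requested gene models", call. = FALSE)
  models <- rbindlist(out)
  setorder(models, chrom, start)
  setattr(models, "class", c("gene_models", class(models)))
  models[]
}

#' Metagene methylation profile
#'
#' Averages CpG methylation along a normalized gene axis of 70 ordered
#' sections: 2 kb upstream of the TSS split into 20 equal sections, the
#' first exon into 10, the internal exons (concatenated in transcript
#' order) into 10, the terminal exon into 10, and 2 kb downstream of the
#' TTS into 20. Coordinates are flipped for minus-strand genes so the axis
#' always follows transcription. Each covered CpG is assigned to exactly
#' one section of the gene features it falls in; the section mean is the
#' unweighted mean of CpG site levels pooled across genes. Genes with
#' fewer than three exons contribute first/terminal sections only (a
#' single-exon gene's exon serves as both).
#'
#' @param calls a `cytosine_calls` table (CpG context rows are used); the
#'   `corrected_level` column is preferred when present.
#' @param gene_models a `gene_models` table (or anything with its columns).
#' @param flank_bp upstream/downstream window width (default 2000).
#' @param n_flank_sections,n_exon_sections section counts (defaults 20/10).
#' @return a `data.table` of class `metagene_profile`: `section` (1-70),
#'   `feature`, `section_within`, `mean_level`, `n_cpg`.
#' @export
metagene_profile <- function(calls, gene_models, flank_bp = 2000L,
                             n_flank_sections = 20L,
                             n_exon_sections = 10L) {
  cpg <- as.data.table(calls)[context == "CpG" & depth > 0L]
  lev_col <- if ("corrected_level" %in% names(cpg)) "corrected_level"
             else "raw_level"
  cpg[, level := get(lev_col)]
  models <- as.data.table(gene_models)

  features <- c("upstream", "first_exon", "internal_exons",
                "terminal_exon", "downstream")
  n_sec <- c(n_flank_sections, n_exon_sections, n_exon_sections,
             n_exon_sections, n_flank_sections)
  names(n_sec) <- features

  assign_feature <- function(rel, width, nsec) {
    # rel in [0, width) -> section 1..nsec by equal bp width
    pmin(nsec, floor(rel / width * nsec) + 1L)
  }

  rows <- list()
  for (g in unique(models$gene_id)) {
    ex <- models[gene_id == g][order(exon_rank)]
    ch <- ex$chrom[1L]
    strand <- ex$strand[1L]
    gstart <- min(ex$start); gend <- max(ex$end)
    tss <- if (strand == "+") gstart else gend
    tts <- if (strand == "+") gend else gstart
    sites <- cpg[chrom == ch & pos >= gstart - flank_bp &
                   pos < gend + flank_bp]
    if (nrow(sites) == 0L) next
    ne <- nrow(ex)

    # transcription-oriented relative coordinate helpers
    up_rel <- if (strand == "+") sites$pos - (tss - flank_bp)
              else (tss + flank_bp - 1L) - sites$pos
    in_up <- if (strand == "+") sites$pos >= tss - flank_bp & sites$pos < tss
             else sites$pos >= tss & sites$pos < tss + flank_bp
    down_rel <- if (strand == "+") sites$pos - tts
                else tts - 1L - sites$pos
    in_down <- if (strand == "+") sites$pos >= tts & sites$pos < tts + flank_bp
               else sites$pos >= tts - flank_bp & sites$pos < tts

    add <- function(feature, sel, rel, width) {
      if (!any(sel)) return(NULL)
      data.table(feature = feature,
                 section_within = assign_feature(rel[sel], width,
                                                 n_sec[[feature]]),
                 level = sites$level[sel])
    }
    rows[[length(rows) + 1L]] <- add("upstream", in_up, up_rel, flank_bp)
    rows[[length(rows) + 1L]] <- add("downstream", in_down, down_rel,
                                     flank_bp)

    exon_rel <- function(e) {
      # transcript-oriented offset of each site within exon e, NA outside
      inside <- sites$pos >= e$start & sites$pos < e$end
      rel <- if (strand == "+") sites$pos - e$start
             else e$end - 1L - sites$pos
      list(inside = inside, rel = rel)
    }
    first <- exon_rel(ex[1L])
    rows[[length(rows) + 1L]] <- add("first_exon", first$inside, first$rel,
                                     ex[1L, end - start])
    term <- exon_rel(ex[ne])
    rows[[length(rows) + 1L]] <- add("terminal_exon", term$inside,
                                     term$rel, ex[ne, end - start])
    if (ne >= 3L) {
      internal <- ex[2:(ne - 1L)]
      widths <- internal$end - internal$start
      off0 <- cumsum(c(0L, head(widths, -1L)))
      total <- sum(widths)
      for (j in seq_len(nrow(internal))) {
        er <- exon_rel(internal[j])
        rows[[length(rows) + 1L]] <- add("internal_exons", er$inside,
                                         er$rel + off0[j], total)
      }
    }
  }

  obs <- rbindlist(rows)
  skeleton <- data.table(
    feature = rep(features, n_sec),
    section_within = unlist(lapply(n_sec, seq_len)))
  skeleton[, section := .I]
  if (nrow(obs)) {
    agg <- obs[, .(mean_level = mean(level), n_cpg = .N),
               by = .(feature, section_within)]
    prof <- merge(skeleton, agg, by = c("feature", "section_within"),
                  all.x = TRUE)
  } else {
    prof <- copy(skeleton)[, `:=`(mean_level = NA_real_, n_cpg = 0L)]
  }
  prof[is.na(n_cpg), n_cpg := 0L]
  setorder(prof, section)
  out <- prof[, .(section, feature, section_within, mean_level, n_cpg)]
  setattr(out, "class", c("metagene_profile", class(out)))
  out[]
}
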