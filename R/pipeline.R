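#' Pipeline configuration
#'
#' Builds a validated, nested configuration for [run_pipeline()]. Every
#' threshold the workflow uses lives here: the DMR gates (`alpha = 0.01`,
#' `fold = 2`, `diff = 20`), the dropout depth (`> 10`), the concordance
#' depth (`>= 9`) and the well-covered-region read count (`>= 10`).
#' Unknown keys are rejected, and a config written with
#' [write_pipeline_config()] reads back losslessly.
#'
#' @param ... named overrides, either nested lists matching the sections
#'   (`genome`, `methylome`, `targets`, `het_sites`, `genes`, `reads`,
#'   `aligner`, `thresholds`, `dmr_truth`) or the top-level `seed`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    genome = list(n_chroms = 1L, chrom_length = 100000L,
                  gc_fraction = 0.4, n_islands = 4L, island_length = 1000L,
                  island_cpg_density = 0.15),
    methylome = list(cpg_beta_high = c(8, 1), cpg_beta_low = c(1, 9),
                     p_high = 0.7, noncpg_level = 0.002),
    targets = list(n_regions = 25L, min_len = 300L, max_len = 600L),
    het_sites = list(density = 0.001, include_ambiguous = TRUE),
    genes = list(n_genes = 12L),
    reads = list(fragment_mean = 250, fragment_sd = 30, read_length = 90L,
                 n_fragments = 20000L, conversion_rate = 0.99,
                 inappropriate_conversion_rate = 0,
                 sequencing_error_rate = 0.001,
                 on_target_capture_prob = 0.8,
                 off_target_capture_prob = 0.01,
                 pcr_duplicate_mean = 1.7, strand_mode = "both",
                 quality_char = "I"),
    aligner = list(seed_length = 30L, seed_max_mismatches = 2L,
                   total_max_mismatches = 5L, max_gaps = 0L,
                   max_insert = 1000L),
    thresholds = list(alpha = 0.01, fold = 2, diff = 20,
                      dropout_min_depth = 10L, min_allele_reads = 2L,
                      concordance_min_depth = 9L, coverage_reads = 10L,
                      min_base_quality = 0L),
    dmr_truth = list(n_planted = 10L, shift = 40)
  )
  over <- list(...)
  cfg <- merge_config(defaults, over, path = "")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, over, path) {
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "),
         call. = FALSE)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(over[[nm]]))
        stop("configuration section '", nm, "' must be a list",
             call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], over[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  defaults
}

#' @describeIn pipeline_config write a configuration as YAML.
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @describeIn pipeline_config read a YAML configuration (unknown keys
#'   rejected; values re-validated).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full simulated capture bisulfite workflow
#'
#' Executes simulate, align, dedup, call, qc, dmr, metagene and
#' concordance in order for two samples (sample B's truth methylome gains
#' planted methylation shifts in a subset of target regions), writing every
#' report plus a `manifest.json` with the package version, the seed and a
#' digest of each artifact. All randomness flows from `config$seed`
#' through stable per-stage substreams, so a repeated run with the same
#' configuration is byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param output_dir artifact directory (created if missing).
#' @return (invisibly) a list with the in-memory results per stage and
#'   `dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    g <- config$genome
    islands <- if (g$n_islands > 0L) {
      L <- g$chrom_length
      at <- floor(seq(0.15, 0.85, length.out = g$n_islands) * L)
      data.frame(chrom = "chr1", start = at, end = at + g$island_length,
                 cpg_density = g$island_cpg_density)
    } else NULL
    genome <- generate_genome(g$n_chroms, g$chrom_length, g$gc_fraction,
                              islands, seed = substream_seed(seed, "genome"))
    m <- config$methylome
    meth_a <- generate_methylome(genome, m$cpg_beta_high, m$cpg_beta_low,
                                 m$p_high, m$noncpg_level,
                                 seed = substream_seed(seed, "methylome"))
    t <- config$targets
    targets <- define_targets(genome, t$n_regions, t$min_len, t$max_len,
                              seed = substream_seed(seed, "targets"))
    planted <- plant_dmr_truth(meth_a, targets,
                               config$dmr_truth$n_planted,
                               config$dmr_truth$shift,
                               seed = substream_seed(seed, "dmr-truth"))
    meth_a <- planted$methylome_a
    meth_b <- planted$methylome_b
    h <- config$het_sites
    hets <- plant_het_sites(genome, h$density, h$include_ambiguous,
                            seed = substream_seed(seed, "hets"))
    genes <- generate_gene_models(genome, config$genes$n_genes,
                                  seed = substream_seed(seed, "genes"))
    mk_params <- function(label) do.call(sim_params, c(
      config$reads, list(seed = substream_seed(seed, label))))
    lib_a <- simulate_reads(genome, meth_a, targets, hets,
                            mk_params("library-A"))
    lib_b <- simulate_reads(genome, meth_b, targets, hets,
                            mk_params("library-B"))
    write_genome_fasta(genome, file.path(output_dir, "reference.fasta"))
    write_targets_bed(targets, file.path(output_dir, "targets.bed"))
    write_het_tsv(hets, file.path(output_dir, "het_sites.tsv"))
    write_gene_models(genes, file.path(output_dir, "gene_models.tsv"))
    write_library_fastq(lib_a, file.path(output_dir, "sample_A"))
    write_library_fastq(lib_b, file.path(output_dir, "sample_B"))
    write_truth_tables(lib_a, file.path(output_dir, "truth_A"))
    write_truth_tables(lib_b, file.path(output_dir, "truth_B"))
    list(genome = genome, meth_a = meth_a, meth_b = meth_b,
         targets = targets, hets = hets, genes = genes,
         lib_a = lib_a, lib_b = lib_b)
  })

  aln_params <- do.call(aligner_params, config$aligner)
  aln <- run_stage("align", {
    index <- build_converted_indexes(sim$genome, aln_params)
    a <- align_library(sim$lib_a$read1, sim$lib_a$read2, sim$lib_a$qname,
                       index, aln_params)
    b <- align_library(sim$lib_b$read1, sim$lib_b$read2, sim$lib_b$qname,
                       index, aln_params)
    list(index = index, a = a, b = b)
  })

  ded <- run_stage("dedup", {
    a <- deduplicate(aln$a)
    b <- deduplicate(aln$b)
    write_alignment_sam(a, sim$genome,
                        file.path(output_dir, "sample_A.sam"))
    write_alignment_sam(b, sim$genome,
                        file.path(output_dir, "sample_B.sam"))
    write_alignment_tsv(a, file.path(output_dir, "sample_A_alignments.tsv"))
    write_alignment_tsv(b, file.path(output_dir, "sample_B_alignments.tsv"))
    list(a = a, b = b)
  })

  th <- config$thresholds
  calls <- run_stage("call", {
    call_one <- function(al, tag) {
      cl <- pileup(al, sim$genome, min_base_quality = th$min_base_quality)
      est <- estimate_nonconversion(cl)
      cl <- correct_levels(cl, est)
      write_cytosine_report(cl, file.path(
        output_dir, sprintf("sample_%s_cytosines.tsv", tag)))
      write_bedgraph(cl, file.path(
        output_dir, sprintf("sample_%s_cpg.bedGraph", tag)))
      list(calls = cl, estimate = est)
    }
    list(a = call_one(ded$a, "A"), b = call_one(ded$b, "B"))
  })

  qc <- run_stage("qc", {
    qa <- compute_capture_qc(ded$a, sim$targets,
                             length(sim$lib_a$qname), th$coverage_reads)
    qb <- compute_capture_qc(ded$b, sim$targets,
                             length(sim$lib_b$qname), th$coverage_reads)
    drop_a <- tryCatch(
      assess_allele_dropout(sim$hets, ded$a, sim$genome,
                            th$dropout_min_depth, th$min_allele_reads),
      error = function(e) NULL)
    write_qc_report(qa, file.path(output_dir, "sample_A_qc.tsv"))
    write_qc_report(qb, file.path(output_dir, "sample_B_qc.tsv"))
    if (!is.null(drop_a))
      write_tsv(data.table(
        metric = c("n_truth_het", "n_recovered_het", "dropout_rate",
                   "excluded_ambiguous"),
        value = c(drop_a$n_truth_het, drop_a$n_recovered_het,
                  drop_a$dropout_rate, drop_a$excluded_ambiguous)),
        file.path(output_dir, "sample_A_dropout.tsv"))
    list(a = qa, b = qb, dropout_a = drop_a)
  })

  dmr <- run_stage("dmr", {
    ra <- aggregate_regions(calls$a$calls, sim$targets)
    rb <- aggregate_regions(calls$b$calls, sim$targets)
    res <- call_dmrs(ra, rb, th$alpha, th$fold, th$diff)
    write_tsv(res, file.path(output_dir, "dmr_results.tsv"))
    list(regions_a = ra, regions_b = rb, results = res)
  })

  metagene <- run_stage("metagene", {
    prof <- metagene_profile(calls$a$calls, sim$genes)
    write_tsv(prof, file.path(output_dir, "metagene_profile.tsv"))
    prof
  })

  concord <- run_stage("concordance", {
    cc <- tryCatch(
      pearson_concordance(calls$a$calls, calls$b$calls,
                          th$concordance_min_depth),
      error = function(e) NULL)
    if (!is.null(cc))
      write_tsv(data.table(metric = c("r", "ci_lower", "ci_upper",
                                      "n_sites"),
                           value = c(cc$r, cc$conf_int, cc$n_sites)),
                file.path(output_dir, "concordance.tsv"))
    cc
  })

  files <- sort(setdiff(list.files(output_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "bscapture",
    version = as.character(packageVersion("bscapture")),
    seed = seed,
    stages = stages,
    files = lapply(setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(output_dir, f))),
           bytes = file.size(file.path(output_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dir = output_dir, sim = sim, alignment = ded,
                 calls = calls, qc = qc, dmr = dmr, metagene = metagene,
                 concordance = concord, manifest = manifest))
}

# Plant differential truth: the first n target regions become
# hypomethylated in sample A (island/promoter-like base levels) and gain
# `shift` percentage points in sample B, so true fold changes clear the
# two-fold gate. CpG pair symmetry is preserved (one level per pair).
plant_dmr_truth <- function(methylome, targets, n_planted, shift,
                            base_range = c(0.02, 0.2), seed = 1L) {
  a <- copy(methylome)
  b <- copy(methylome)
  n_planted <- min(n_planted, nrow(targets))
  planted_ids <- character(0)
  if (n_planted > 0L) {
    set.seed(seed)
    tgt <- as.data.table(targets)[seq_len(n_planted)]
    planted_ids <- tgt$id
    for (i in seq_len(nrow(tgt))) {
      sel <- which(a$chrom == tgt$chrom[i] & a$pos >= tgt$start[i] &
                     a$pos < tgt$end[i] & a$context == "CpG")
      if (length(sel) == 0L) next
      pair <- ifelse(a$strand[sel] == "+", a$pos[sel], a$pos[sel] - 1L)
      base <- runif(length(unique(pair)), base_range[1], base_range[2])
      lev <- base[match(pair, unique(pair))]
      a[sel, true_level := lev]
      b[sel, true_level := pmin(1, lev + shift / 100)]
    }
  }
  setattr(a, "class", unique(c("methylome", class(a))))
  setattr(b, "class", unique(c("methylome", class(b))))
  list(methylome_a = a, methylome_b = b, planted_ids = planted_ids)
}

#' Write a capture QC report as a machine-readable key-value TSV
#' @param report a `capture_qc_report`.
#' @param path file path.
#' @export
write_qc_report <- function(report, path) {
  scal <- c("raw_read_pairs", "unique_map_rate", "duplication_rate",
            "mean_target_depth", "fraction_targets_covered",
            "fraction_targets_ge10", "on_target_rate", "n_reads_counted")
  write_tsv(data.table(metric = scal,
                       value = vapply(scal, function(k)
                         as.numeric(report[[k]]), numeric(1))),
            path)
  write_tsv(report$per_chromosome_strand_depth,
            sub("\\.tsv$", "_per_chrom_strand.tsv", path))
  invisible(path)
}
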