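# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

toy_ref <- function(seqs) bscapture:::new_ref_genome(seqs)

# a minimal unique-alignment container for caller-level tests
make_alignment <- function(records, duplication_rate = 0) {
  rec <- data.table::as.data.table(records)
  n <- nrow(rec)
  defaults <- list(qname = sprintf("r%04d", seq_len(n)),
                   pid = seq_len(n), mate = 1L, strand = "+",
                   space = "CT", mm = 0L, gaps = 0L, paired = FALSE,
                   status = "unique", is_duplicate = FALSE,
                   duplicate_group = seq_len(n))
  for (nm in names(defaults))
    if (!nm %in% names(rec)) rec[[nm]] <- defaults[[nm]]
  if (!"end" %in% names(rec)) rec$end <- rec$start + nchar(rec$seq)
  if (!"len" %in% names(rec)) rec$len <- nchar(rec$seq)
  if (!"outer_start" %in% names(rec)) rec$outer_start <- rec$start
  if (!"outer_end" %in% names(rec)) rec$outer_end <- rec$end
  structure(list(
    records = rec,
    stats = list(n_pairs = n, n_reads = n, unique_reads = n,
                 multi_reads = 0L, unmapped_reads = 0L,
                 unique_map_rate = 100),
    dedup_report = list(n_units = n, n_removed = 0L,
                        duplication_rate = duplication_rate)
  ), class = "bs_alignment")
}

# small fully-captured library with its complete analysis chain
small_run <- function() {
  fixture("small_run", function() {
    genome <- generate_genome(1, 20000, 0.45, seed = 101)
    methylome <- generate_methylome(genome, seed = 101)
    targets <- define_targets(genome, 8, 300, 600, seed = 101)
    hets <- plant_het_sites(genome, 0.0008, seed = 101)
    params <- sim_params(n_fragments = 3000, on_target_capture_prob = 1,
                         off_target_capture_prob = 1,
                         pcr_duplicate_mean = 1.3, seed = 101)
    lib <- simulate_reads(genome, methylome, targets, hets, params)
    index <- build_converted_indexes(genome)
    aln <- deduplicate(align_library(lib$read1, lib$read2, lib$qname,
                                     index))
    calls <- pileup(aln, genome)
    est <- estimate_nonconversion(calls)
    calls <- correct_levels(calls, est)
    list(genome = genome, methylome = methylome, targets = targets,
         hets = hets, params = params, lib = lib, index = index,
         aln = aln, calls = calls, est = est)
  })
}

# parse truth origin out of a simulated read name
parse_qname <- function(qname) {
  parts <- data.table::tstrsplit(qname, ":", fixed = TRUE)
  data.table::data.table(chrom = parts[[1]],
                         start = as.integer(parts[[2]]),
                         end = as.integer(parts[[3]]),
                         strand = parts[[4]],
                         frag_id = as.integer(parts[[5]]),
                         copy_index = as.integer(parts[[6]]))
}
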