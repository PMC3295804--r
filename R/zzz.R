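.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", ".GRP", "..cols", "id", "chrom", "start", "end", "pos",
  "strand", "context", "true_level", "frag_id", "on_target", "homolog",
  "seq", "n_copies", "copy_index", "qname", "read", "chromi", "len", "mm",
  "seed_mm", "space", "mate", "pid", "best", "n_top", "score", "start_1",
  "start_2", "len_1", "len_2", "mm_1", "mm_2", "strand_1", "strand_2",
  "start_plus", "start_minus", "outer_start", "outer_end", "status",
  "paired", "is_duplicate", "duplicate_group", "mm_sum", "len_sum",
  "qual_sum", "meth", "count_methylated", "count_unmethylated", "depth",
  "raw_level", "corrected_level", "level", "covered", "total",
  "sum_methylated", "sum_unmethylated", "level_a", "level_b", "covered_a",
  "covered_b", "sum_methylated_a", "sum_methylated_b",
  "sum_unmethylated_a", "sum_unmethylated_b", "p_value", "abs_diff",
  "fold_change", "passes_p", "passes_fold", "passes_diff", "is_dmr",
  "depth_a", "depth_b", "site", "methylated", "methylated_lhc",
  "unmethylated_lhc", "methylated_clone", "unmethylated_clone",
  "significant", "gene_id", "exon_rank", "exon_starts", "exon_ends",
  "section", "section_within", "n_cpg", "feature", "ref", "alt",
  "bisulfite_ambiguous", "N", "n", "base", "ref_reads", "alt_reads",
  "recovered", "read_as_T", "m", "u", "key", "value"))
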