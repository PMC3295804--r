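#' Read and write package file formats
#'
#' All genomic coordinates on disk follow BED conventions: 0-based,
#' half-open. FASTA is wrapped and upper-cased on read; FASTQ is phred+33;
#' every writer's output is accepted by its reader.
#'
#' @name bscapture-io
NULL

#' @describeIn bscapture-io write a reference genome as wrapped FASTA.
#' @param genome a `ref_genome`.
#' @param path output/input file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome), path, width = 70L)
  invisible(path)
}

#' @describeIn bscapture-io read a FASTA reference into a `ref_genome`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  new_ref_genome(setNames(toupper(as.character(x)), names(x)))
}

#' @describeIn bscapture-io write capture targets as BED3+ (name column).
#' @param targets a `target_set`.
#' @export
write_targets_bed <- function(targets, path) {
  gr <- targets_granges(targets)
  names(gr) <- targets$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @describeIn bscapture-io read a BED file into a `target_set`.
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("target_%04d", seq_along(gr))
  out[, id := nm]
  setorder(out, chrom, start)
  setattr(out, "total_span", sum(out$end - out$start))
  setattr(out, "class", c("target_set", class(out)))
  out[]
}

#' @describeIn bscapture-io write paired FASTQ files for a library.
#' @param lib a `bs_library`.
#' @param prefix path prefix; `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @export
write_library_fastq <- function(lib, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  write_fastq(lib$read1, lib$qual1, lib$qname, p1)
  write_fastq(lib$read2, lib$qual2, lib$qname, p2)
  invisible(c(p1, p2))
}

write_fastq <- function(seqs, quals, names, path) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- character(4L * length(seqs))
  lines[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", names)
  lines[seq(2L, by = 4L, length.out = length(seqs))] <- seqs
  lines[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(seqs))] <- quals
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn bscapture-io read one FASTQ file (phred+33).
#' @return for `read_fastq`: a list with `names`, `seqs`, `quals`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(names = names(x), seqs = unname(as.character(x)),
       quals = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @describeIn bscapture-io write paired reads loaded by `read_fastq`
#'   against a library's truth tables as TSV files under `dir`.
#' @param dir output directory.
#' @export
write_truth_tables <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("truth_fragments.tsv", "truth_molecules.tsv",
                            "truth_conversions.tsv"))
  write_tsv(lib$truth_fragments, paths[1])
  write_tsv(lib$truth_molecules, paths[2])
  write_tsv(lib$truth_conversions, paths[3])
  invisible(paths)
}

#' @describeIn bscapture-io write a het-site table as TSV
#'   (chrom, pos, ref, alt, bisulfite_ambiguous).
#' @param het_sites table from [plant_het_sites()].
#' @export
write_het_tsv <- function(het_sites, path) write_tsv(het_sites, path)

#' @describeIn bscapture-io generic TSV writer (tab-separated, header,
#'   full precision, no quoting).
#' @param x a data.frame/data.table.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @describeIn bscapture-io generic TSV reader.
#' @export
read_tsv <- function(path) fread(path, sep = "\t", na.strings = "NA")

#' @describeIn bscapture-io write a per-cytosine report
#'   (chrom, pos, strand, context, counts, raw and corrected levels).
#' @param calls a `cytosine_calls` table.
#' @export
write_cytosine_report <- function(calls, path) {
  write_tsv(as.data.table(calls), path)
}

#' @describeIn bscapture-io read a cytosine report back.
#' @export
read_cytosine_report <- function(path) {
  out <- read_tsv(path)
  setattr(out, "class", c("cytosine_calls", class(out)))
  out[]
}

#' @describeIn bscapture-io export corrected CpG levels as bedGraph.
#' @export
write_bedgraph <- function(calls, path) {
  x <- as.data.table(calls)[context == "CpG" & depth > 0L]
  score <- if ("corrected_level" %in% names(x)) x$corrected_level
           else x$raw_level
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$pos + 1L, x$pos + 1L),
                               score = score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @describeIn bscapture-io write unique alignment records as a minimal
#'   SAM file (QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ/QUAL plus `XS` for the
#'   conversion space, `NM` for mismatches, duplicate flag 0x400).
#' @param alignment a `bs_alignment` (deduplicated records get flags).
#' @export
write_alignment_sam <- function(alignment, genome, path) {
  rec <- alignment$records
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
                   genome$chrom_lengths))
  if (nrow(rec) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  dup <- if ("is_duplicate" %in% names(rec)) rec$is_duplicate else FALSE
  flag <- 1L * rec$paired +
    2L * (rec$paired & rec$status == "unique") +
    16L * (rec$strand == "-") +
    64L * (rec$mate == 1L) + 128L * (rec$mate == 2L) +
    1024L * dup
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tXS:Z:%s\tNM:i:%d",
                  rec$qname, flag, rec$chrom, rec$start + 1L, 30L,
                  rec$len, rec$seq, rec$space, rec$mm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @describeIn bscapture-io write unique alignment records as TSV
#'   (equivalent dialect to the SAM subset).
#' @export
write_alignment_tsv <- function(alignment, path) {
  cols <- intersect(c("qname", "mate", "chrom", "start", "end", "strand",
                      "space", "mm", "gaps", "paired", "status",
                      "duplicate_group", "is_duplicate"),
                    names(alignment$records))
  write_tsv(alignment$records[, ..cols], path)
}

#' @describeIn bscapture-io read gene models from the package's TSV
#'   dialect (`gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`;
#'   comma-separated 0-based half-open exon lists) or BED12.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    x <- read_tsv(path)
    out <- x[, {
      s <- as.integer(strsplit(exon_starts, ",")[[1]])
      e <- as.integer(strsplit(exon_ends, ",")[[1]])
      rank <- if (strand == "+") seq_along(s) else rev(seq_along(s))
      list(chrom = chrom, strand = strand, start = s, end = e,
           exon_rank = rank)
    }, by = gene_id]
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    out <- rbindlist(lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      s <- GenomicRanges::start(gr)[i] - 1L + GenomicRanges::start(b) - 1L
      e <- GenomicRanges::start(gr)[i] - 1L + GenomicRanges::end(b)
      strand <- as.character(GenomicRanges::strand(gr)[i])
      rank <- if (strand == "-") rev(seq_along(s)) else seq_along(s)
      data.table(gene_id = gr$name[i] %||% sprintf("gene_%03d", i),
                 chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                 strand = strand, start = s, end = e, exon_rank = rank)
    }))
  }
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

#' @describeIn bscapture-io write gene models in the TSV dialect.
#' @param models a `gene_models` table.
#' @export
write_gene_models <- function(models, path) {
  x <- as.data.table(models)
  setorder(x, gene_id, start)
  flat <- x[, .(chrom = chrom[1L], strand = strand[1L],
                exon_starts = paste(start, collapse = ","),
                exon_ends = paste(end, collapse = ",")),
            by = gene_id]
  write_tsv(flat, path)
}
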