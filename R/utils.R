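#' @import data.table
#' @importFrom stats rnorm rpois rbinom rbeta runif cor qnorm dhyper chisq.test
#' @importFrom utils head tail packageVersion
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed fan-out: one user-facing seed, stable labelled
# substreams so stages reproduce when run standalone. Kept below 2^31 - 1.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131) %% 2147483629)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

BASES <- c("A", "C", "G", "T")

# sample integers uniformly from [lo, hi] (safe when lo == hi)
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a vector of sequences into one long char vector plus an index
explode_seqs <- function(seqs) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  list(chars = unlist(chars, use.names = FALSE), lens = lens,
       seq_id = rep(seq_along(seqs), lens),
       offset = sequence(lens) - 1L)
}
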