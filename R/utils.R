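# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (IUPAC letters).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GTTTC")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split sequences into a character matrix of single bases; all inputs must
# share one length
seq_to_mat <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L)
    stop("sequences must all have the same length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = n, byrow = TRUE)
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(sprintf("%s contains non-%s characters (first offender: '%s')",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 x[which(bad)[1L]]), call. = FALSE)
  invisible(x)
}

# extract [start, end] (1-based inclusive) from a single chromosome string,
# on the requested strand; out-of-range positions are an error
subseq_strand <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  len <- nchar(genome[[chrom]])
  if (start < 1L || end > len || end < start)
    stop(sprintf("range [%d, %d] out of bounds for %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  s <- substr(genome[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# Hamming distance between two equal-length strings (N counts as mismatch
# against any base, including N, unless identical is all we compare)
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(av) != length(bv)) stop("hamming: unequal lengths")
  sum(av != bv | av == "N" | bv == "N")
}

# geometric mean
gmean <- function(x) exp(mean(log(x)))

# stable per-column SEM
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# validate and normalise a seed argument
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  as.integer(seed)
}
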