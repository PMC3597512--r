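# Readers and writers for the on-disk formats used by the pipeline.
#
# All genomic intervals are converted at this boundary between the BED
# 0-based half-open on-disk convention and the 1-based inclusive convention
# used internally (the native R/Biostrings convention). FASTA/FASTQ parsing
# is delegated to Biostrings.

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences (empty if the
#'   file contains no records).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = toupper(unname(as.character(x))),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `id`, `seq` and optionally `qual`
#'   (constant 'I' qualities are written when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

# tokenize a whitespace-delimited text file into a list of character
# vectors, skipping blank and track/browser lines, keeping line numbers
.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(track|browser|#)", lines)
  list(fields = strsplit(trimws(lines[keep]), "[ \t]+"),
       lineno = which(keep))
}

.parse_int <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop(sprintf("%s, line %d: %s is not numeric ('%s')",
                 path, lineno[which(is.na(v))[1L]], what,
                 x[which(is.na(v))[1L]]), call. = FALSE)
  v
}

#' Read a BED file of intervals
#'
#' BED coordinates on disk are 0-based half-open; the returned data frame
#' uses 1-based inclusive `start`/`end`.
#'
#' @param path path to a BED file (3-6 columns).
#' @return data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (missing optional columns filled with `"."`, `0`,
#'   `"+"` respectively).
#' @export
read_bed <- function(path) {
  tk <- .read_tsv_lines(path)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (length(tk$fields) == 0L) return(empty)
  nf <- lengths(tk$fields)
  if (any(nf < 3L))
    stop(sprintf("%s, line %d: BED record has fewer than 3 fields",
                 path, tk$lineno[which(nf < 3L)[1L]]), call. = FALSE)
  getf <- function(i, default) vapply(tk$fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  start0 <- .parse_int(getf(2L, NA), path, tk$lineno, "start")
  end0 <- .parse_int(getf(3L, NA), path, tk$lineno, "end")
  bad <- end0 <= start0
  if (any(bad))
    stop(sprintf("%s, line %d: BED end (%d) <= start (%d)",
                 path, tk$lineno[which(bad)[1L]],
                 end0[which(bad)[1L]], start0[which(bad)[1L]]),
         call. = FALSE)
  strand <- getf(6L, "+")
  if (!all(strand %in% c("+", "-", ".")))
    stop(sprintf("%s, line %d: invalid strand", path,
                 tk$lineno[which(!strand %in% c("+", "-", "."))[1L]]),
         call. = FALSE)
  data.frame(chrom = getf(1L, NA),
             start = as.integer(start0 + 1L),
             end = as.integer(end0),
             name = getf(4L, "."),
             score = suppressWarnings(as.numeric(getf(5L, "0"))),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED file
#'
#' @param bed data frame as returned by [read_bed()] (1-based inclusive
#'   coordinates; converted to 0-based half-open on disk).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  out <- data.frame(bed$chrom, bed$start - 1L, bed$end,
                    bed$name %||% ".", bed$score %||% 0,
                    bed$strand %||% "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path path to a bedGraph file.
#' @return data frame with 1-based inclusive columns `chrom`, `start`,
#'   `end` and `value`.
#' @export
read_bedgraph <- function(path) {
  tk <- .read_tsv_lines(path)
  if (length(tk$fields) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  nf <- lengths(tk$fields)
  if (any(nf < 4L))
    stop(sprintf("%s, line %d: bedGraph record has fewer than 4 fields",
                 path, tk$lineno[which(nf < 4L)[1L]]), call. = FALSE)
  f <- function(i) vapply(tk$fields, `[`, character(1), i)
  start0 <- .parse_int(f(2L), path, tk$lineno, "start")
  end0 <- .parse_int(f(3L), path, tk$lineno, "end")
  if (any(end0 <= start0))
    stop(sprintf("%s, line %d: bedGraph end <= start", path,
                 tk$lineno[which(end0 <= start0)[1L]]), call. = FALSE)
  data.frame(chrom = f(1L), start = as.integer(start0 + 1L),
             end = as.integer(end0),
             value = .parse_int(f(4L), path, tk$lineno, "value"),
             stringsAsFactors = FALSE)
}

#' Write a signal track to bedGraph
#'
#' @param track data frame as returned by [read_bedgraph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(track$chrom, track$start - 1L, track$end, track$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-library count table
#'
#' The on-disk format is TSV with a header row: a `species_id` column
#' followed by one non-negative integer column per library.
#'
#' @param path path to the TSV file.
#' @return data frame with `species_id` plus one numeric column per library.
#' @export
read_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1L] != "species_id")
    stop(sprintf("%s: first column must be 'species_id'", path))
  num <- x[-1L]
  if (!all(vapply(num, is.numeric, logical(1))))
    stop(sprintf("%s: count columns must be numeric", path))
  if (any(unlist(num) < 0))
    stop(sprintf("%s: counts must be non-negative", path))
  x
}

#' Write a per-library count table
#'
#' @param counts data frame as returned by [read_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# count data frame -> numeric matrix with species_id rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[-1L])
  rownames(m) <- counts$species_id
  m
}
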