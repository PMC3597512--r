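# 3'-linker removal cascade.
#
# Small RNA reads carry an artificial 3' linker. The cascade searches, in
# strict order: (1) leftmost perfect occurrence of the full linker anywhere
# in the read; (2) leftmost occurrence of the full linker with exactly one
# mismatch; (3)-(8) alignment of the last k nt of the read to the first k
# nt of the linker for k = 5, 4, 3, first with 0 then with 1 mismatch.
# The first satisfied rule wins; reads matching no rule are discarded.
# N bases count as mismatches.

TRIM_STATUSES <- c("trimmed_full_0mm", "trimmed_full_1mm",
                   "trimmed_suffix_5_0mm", "trimmed_suffix_5_1mm",
                   "trimmed_suffix_4_0mm", "trimmed_suffix_4_1mm",
                   "trimmed_suffix_3_0mm", "trimmed_suffix_3_1mm",
                   "discarded")

# leftmost start of an occurrence of `pat` in `chars` with exactly `mm`
# mismatches (N always mismatches); 0 if none
.leftmost_occurrence <- function(chars, pat, mm) {
  n <- length(chars)
  L <- length(pat)
  if (n < L) return(0L)
  for (p in seq_len(n - L + 1L)) {
    w <- chars[p:(p + L - 1L)]
    d <- sum(w != pat | w == "N" | pat == "N")
    if (d == mm) return(p)
  }
  0L
}

#' Trim the 3' linker from a single read
#'
#' Applies the eight-rule cascade described above and returns the insert
#' (the read prefix before the trim point) together with the rule that
#' fired. `trim_position` is the 1-based index of the first trimmed base
#' (`insert == substr(read, 1, trim_position - 1)`); for discarded reads it
#' is `NA`.
#'
#' @param read a single read sequence (ACGTN).
#' @param linker the linker sequence, length >= 5.
#' @param allow_1mm_short allow the 1-mismatch variant at suffix length 3
#'   (the last cascade rule); a 1-mismatch 3-mer is nearly vacuous, so this
#'   can be disabled.
#' @return list with elements `insert`, `status`, `trim_position`.
#' @export
#' @examples
#' trim_read(paste0("TGATATGCGATGTAGTAGACT", "TCGTATGCCG"), "TCGTATGCCG")
trim_read <- function(read, linker, allow_1mm_short = TRUE) {
  check_dna(read, "read")
  check_dna(linker, "linker")
  if (nchar(linker) < 5L) stop("linker must be at least 5 nt")
  if (nchar(read) < 1L) stop("read must be at least 1 nt")
  rc <- strsplit(read, "", fixed = TRUE)[[1L]]
  lc <- strsplit(linker, "", fixed = TRUE)[[1L]]
  n <- length(rc)

  done <- function(pos, status)
    list(insert = substr(read, 1L, pos - 1L), status = status,
         trim_position = as.integer(pos))

  # (1) full linker, perfect, leftmost -- fast path via fixed regexpr when
  # the linker has no N
  if (!any(lc == "N")) {
    p <- regexpr(linker, read, fixed = TRUE)
    if (p > 0L) return(done(as.integer(p), "trimmed_full_0mm"))
  } else if ((p <- .leftmost_occurrence(rc, lc, 0L)) > 0L) {
    return(done(p, "trimmed_full_0mm"))
  }
  # (2) full linker, exactly one mismatch, leftmost
  p <- .leftmost_occurrence(rc, lc, 1L)
  if (p > 0L) return(done(p, "trimmed_full_1mm"))
  # (3)-(8) suffix rules
  for (k in c(5L, 4L, 3L)) {
    for (mm in 0:1) {
      if (k == 3L && mm == 1L && !allow_1mm_short) next
      if (n < k) next
      w <- rc[(n - k + 1L):n]
      pk <- lc[1:k]
      d <- sum(w != pk | w == "N" | pk == "N")
      if (d == mm)
        return(done(n - k + 1L, sprintf("trimmed_suffix_%d_%dmm", k, mm)))
    }
  }
  list(insert = NA_character_, status = "discarded",
       trim_position = NA_integer_)
}

#' Trim the 3' linker from a whole library
#'
#' @param reads data frame of reads as from [read_fastq()] (columns `id`,
#'   `seq`), or a character vector of sequences.
#' @param linker the linker sequence.
#' @param allow_1mm_short see [trim_read()].
#' @return list with `reads` (data frame: `id`, `insert`, `status`,
#'   `trim_position`; discarded reads retained with `insert = NA`) and
#'   `report` (data frame: `status`, `count`, `fraction` over all eight
#'   statuses plus `discarded`).
#' @export
trim_library <- function(reads, linker, allow_1mm_short = TRUE) {
  if (is.character(reads))
    reads <- data.frame(id = sprintf("read_%d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  n <- nrow(reads)
  res <- vector("list", n)
  for (i in seq_len(n))
    res[[i]] <- trim_read(reads$seq[i], linker, allow_1mm_short)
  status <- vapply(res, `[[`, character(1), "status")
  out <- data.frame(
    id = if (n) reads$id else character(0),
    insert = vapply(res, `[[`, character(1), "insert"),
    status = status,
    trim_position = vapply(res, `[[`, integer(1), "trim_position"),
    stringsAsFactors = FALSE)
  counts <- table(factor(status, levels = TRIM_STATUSES))
  report <- data.frame(status = names(counts),
                       count = as.integer(counts),
                       fraction = if (n) as.integer(counts) / n else
                         rep(0, length(counts)),
                       stringsAsFactors = FALSE)
  list(reads = out, report = report)
}
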