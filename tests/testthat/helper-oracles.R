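# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition by naive enumeration, sharing no code with
# the implementation they check.

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

mm_between <- function(a, b) {
  av <- chars_of(a); bv <- chars_of(b)
  stopifnot(length(av) == length(bv))
  sum(av != bv | av == "N" | bv == "N")
}

# naive linker-trim: try all 8 rules in order by explicit substring scans
oracle_trim <- function(read, linker, allow_1mm_short = TRUE) {
  n <- nchar(read); L <- nchar(linker)
  hit <- function(p, status) list(insert = substr(read, 1L, p - 1L),
                                  status = status,
                                  trim_position = as.integer(p))
  for (mm in 0:1) {
    if (n >= L) {
      for (p in seq_len(n - L + 1L)) {
        if (mm_between(substr(read, p, p + L - 1L), linker) == mm)
          return(hit(p, sprintf("trimmed_full_%dmm", mm)))
      }
    }
  }
  for (k in c(5L, 4L, 3L)) {
    for (mm in 0:1) {
      if (k == 3L && mm == 1L && !allow_1mm_short) next
      if (n < k) next
      if (mm_between(substr(read, n - k + 1L, n),
                     substr(linker, 1L, k)) == mm)
        return(hit(n - k + 1L, sprintf("trimmed_suffix_%d_%dmm", k, mm)))
    }
  }
  list(insert = NA_character_, status = "discarded",
       trim_position = NA_integer_)
}

# all-positions Hamming scan of one insert over a genome, both strands;
# returns data.frame(chrom, strand, start, mm) of hits with mm <= max_mm
oracle_scan_genome <- function(insert, genome, max_mm) {
  rc_insert <- pirna21::revcomp(insert)
  out <- list()
  w <- nchar(insert)
  for (ch in names(genome)) {
    gc <- chars_of(genome[[ch]])
    npos <- length(gc) - w + 1L
    if (npos < 1L) next
    for (strand in c("+", "-")) {
      pat <- chars_of(if (strand == "+") insert else rc_insert)
      mm <- integer(npos)
      for (o in seq_len(w))
        mm <- mm + (gc[o:(o + npos - 1L)] != pat[o])
      at <- which(mm <= max_mm)
      if (length(at))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, strand = strand, start = at, mm = mm[at],
          stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), mm = integer(0))
  res
}

# best-stratum filter applied to the oracle hits
oracle_map <- function(insert, genome, max_mm = 2L) {
  h <- oracle_scan_genome(insert, genome, max_mm)
  if (nrow(h) == 0L) return(h)
  h <- h[h$mm == min(h$mm), , drop = FALSE]
  h[order(h$chrom, h$strand, h$start), , drop = FALSE]
}

# naive upstream motif scan: enumerate every GTTTC in the 60-nt window by
# character loop, apply the nearest-39 selection
oracle_scan_upstream <- function(locus, genome, window = 60L,
                                 optimum = 39L) {
  ch <- locus$chrom; strand <- locus$strand; pos5 <- locus$pos5
  L <- nchar(genome[[ch]])
  up <- character(0)
  # strand-space upstream bases at distances 1..window+2 from the T
  for (d in seq_len(window + 2L)) {
    p <- if (strand == "+") pos5 - d else pos5 + d
    if (p < 1L || p > L) break
    b <- substr(genome[[ch]], p, p)
    if (strand == "-") b <- c(A = "T", C = "G", G = "C", T = "A",
                              N = "N")[[b]]
    up[d] <- b   # up[d] = base at distance d upstream (strand space)
  }
  cand <- list()
  if (length(up) < 8L)
    return(list(has_gtttc = FALSE, five_prime_nt = "NM",
                spacer_length = NA_integer_))
  for (d in 6:min(window, length(up) - 2L)) {
    # GTTTC with its G at distance d: bases at d, d-1, ..., d-4
    if (identical(up[d:(d - 4L)], c("G", "T", "T", "T", "C"))) {
      spacer <- d - 6L   # 8mer 3' end at distance d-5; gap = d-5-1
      if (length(up) >= d + 2L)
        cand[[length(cand) + 1L]] <- list(d = d, spacer = spacer)
    }
  }
  if (length(cand) == 0L)
    return(list(has_gtttc = FALSE, five_prime_nt = "NM",
                spacer_length = NA_integer_))
  sp <- vapply(cand, `[[`, numeric(1), "spacer")
  best <- order(abs(sp - optimum), sp)[1L]
  d <- cand[[best]]$d
  list(has_gtttc = TRUE, five_prime_nt = up[d + 2L],
       spacer_length = as.integer(sp[best]),
       core_8mer = paste(rev(up[(d - 5L):(d + 2L)]), collapse = ""))
}

# sliding Hamming scan for antisense target sites
oracle_find_targets <- function(u21, transcripts, max_mm = 3L) {
  out <- list()
  for (k in seq_along(u21)) {
    pat <- pirna21::revcomp(u21[[k]])
    for (tx in names(transcripts)) {
      s <- transcripts[[tx]]
      for (p in seq_len(nchar(s) - 20L)) {
        mm <- mm_between(substr(s, p, p + 20L), pat)
        if (mm <= max_mm)
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = tx, start = p, end = p + 20L,
            source_21u = names(u21)[k], n_mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), source_21u = character(0),
                      n_mismatches = integer(0))
  res
}

# textbook Welch t statistic and two-tailed p
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

random_reads <- function(n, len_range = 15:40, seed = 1) {
  set.seed(seed)
  vapply(sample(len_range, n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1))
}

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
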