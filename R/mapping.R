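# Read mapping and annotation.
#
# An internal exact/low-mismatch mapper adequate for synthetic-scale
# genomes: for every insert it enumerates all ungapped alignments with at
# most `max_mismatches` substitutions on both strands (via
# Biostrings::matchPattern) and reports only the best stratum -- the
# alignments achieving the minimum observed mismatch count -- capped at
# `max_loci` hits.

# all ungapped hits of `pattern` in one chromosome string, both strands,
# with <= max.mismatch substitutions; returns data.frame(start, strand, mm)
.match_one <- function(pattern, subject_fwd, max_mm) {
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else revcomp(pattern)
    m <- Biostrings::matchPattern(pat, subject_fwd,
                                  max.mismatch = max_mm, fixed = TRUE)
    if (length(m) > 0L) {
      mm <- Biostrings::neditAt(Biostrings::DNAString(pat), subject_fwd,
                                at = IRanges::start(m), fixed = TRUE)
      hits[[strand]] <- data.frame(start = IRanges::start(m),
                                   strand = strand, mm = mm,
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      mm = integer(0)))
  do.call(rbind, hits)
}

#' Map inserts to a genome (best stratum, capped)
#'
#' @param inserts character vector of insert sequences (ACGT), or the
#'   `reads` data frame from [trim_library()] (discarded rows skipped).
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatches maximum substitutions allowed per alignment.
#' @param max_loci alignments per insert beyond which the insert is
#'   flagged as exceeding the multi-mapping cap (its alignments are
#'   dropped and `capped` is set).
#' @return data frame of alignments: `insert`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive forward coordinates), `mismatches`,
#'   `n_mapped_loci` (size of the best stratum), `capped`.
#' @export
map_reads <- function(inserts, genome, max_mismatches = 2L,
                      max_loci = 50L) {
  if (is.data.frame(inserts))
    inserts <- inserts$insert[!is.na(inserts$insert)]
  uniq <- unique(inserts)
  check_dna(uniq, "insert")
  subj <- lapply(genome, Biostrings::DNAString)
  out <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    ins <- uniq[i]
    hits <- do.call(rbind, lapply(names(genome), function(ch) {
      h <- .match_one(ins, subj[[ch]], max_mismatches)
      if (nrow(h)) h$chrom <- ch
      h
    }))
    if (is.null(hits) || nrow(hits) == 0L) next
    best <- min(hits$mm)
    hits <- hits[hits$mm == best, , drop = FALSE]
    k <- nrow(hits)
    capped <- k > max_loci
    if (capped) hits <- hits[0L, , drop = FALSE]
    if (nrow(hits))
      out[[i]] <- data.frame(insert = ins, chrom = hits$chrom,
                             strand = hits$strand, start = hits$start,
                             end = hits$start + nchar(ins) - 1L,
                             mismatches = hits$mm, n_mapped_loci = k,
                             capped = capped, stringsAsFactors = FALSE)
    else
      out[[i]] <- data.frame(insert = ins, chrom = NA_character_,
                             strand = NA_character_, start = NA_integer_,
                             end = NA_integer_, mismatches = NA_integer_,
                             n_mapped_loci = k, capped = TRUE,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(insert = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      n_mapped_loci = integer(0), capped = logical(0))
  res
}

#' Build 21U RNA genomic coordinates from known sequences
#'
#' Only perfect, full-length 21-nt alignments define valid coordinates;
#' sequences with no perfect hit are dropped and counted.
#'
#' @param known named character vector of known 21U sequences (21 nt,
#'   DNA alphabet: the 5' uridine is a genomic T).
#' @param genome named character vector of chromosome sequences.
#' @return list with `loci` (data frame: `locus_id`, `chrom`, `strand`,
#'   `start`, `end`, `pos5`, `sequence`, `n_mapped_loci`, `unique`) and
#'   `n_dropped`.
#' @export
build_21u_coordinates <- function(known, genome) {
  if (is.null(names(known)) || any(!nzchar(names(known))))
    stop("'known' must be a named vector of sequences")
  if (any(nchar(known) != 21L))
    stop("21U sequences must be 21 nt")
  aln <- map_reads(known, genome, max_mismatches = 0L,
                   max_loci = .Machine$integer.max)
  aln <- aln[!is.na(aln$start), , drop = FALSE]
  idx <- match(aln$insert, known)
  loci <- data.frame(
    locus_id = sprintf("%s_L%d", names(known)[idx],
                       stats::ave(idx, idx, FUN = seq_along)),
    species_id = names(known)[idx],
    chrom = aln$chrom, strand = aln$strand,
    start = aln$start, end = aln$end,
    pos5 = ifelse(aln$strand == "+", aln$start, aln$end),
    sequence = aln$insert, n_mapped_loci = aln$n_mapped_loci,
    stringsAsFactors = FALSE)
  loci$unique <- loci$n_mapped_loci == 1L
  list(loci = loci, n_dropped = sum(!known %in% aln$insert))
}

#' Annotate mapped reads to small RNA species
#'
#' A read counts toward a 21U species iff its alignment interval is wholly
#' contained within the locus interval on the same strand. Trimmed inserts
#' of length 22 with a 5' G are annotated as 22G species and inserts of
#' length 26 with a 5' G as 26G species (keyed by sequence).
#'
#' @param alignments data frame from [map_reads()], plus a `count` column
#'   (reads per insert; defaults to 1 per alignment row's insert).
#' @param loci 21U locus table (from [build_21u_coordinates()] or truth).
#' @param exact_length_only if `TRUE`, only 21-nt reads count toward 21U
#'   species (the stricter reading of the containment rule).
#' @return list of data frames `u21`, `g22`, `g26`: per-species weighted
#'   counts, where each read contributes `1 / n_mapped_loci` per locus.
#' @export
annotate_reads <- function(alignments, loci, exact_length_only = FALSE) {
  aln <- alignments[!is.na(alignments$start) & !alignments$capped, ,
                    drop = FALSE]
  if (!"count" %in% names(aln)) aln$count <- 1
  ilen <- nchar(aln$insert)
  u21 <- data.frame(species_id = character(0), count = numeric(0))
  if (nrow(loci)) {
    keep <- if (exact_length_only) ilen == 21L else ilen <= 21L
    a <- aln[keep, , drop = FALSE]
    if (nrow(a)) {
      species <- loci$species_id %||% loci$locus_id
      hits <- lapply(seq_len(nrow(a)), function(i) {
        sel <- loci$chrom == a$chrom[i] & loci$strand == a$strand[i] &
          loci$start <= a$start[i] & loci$end >= a$end[i]
        if (!any(sel)) return(NULL)
        data.frame(species_id = species[sel],
                   w = a$count[i] / a$n_mapped_loci[i],
                   stringsAsFactors = FALSE)
      })
      hits <- do.call(rbind, hits)
      if (!is.null(hits) && nrow(hits)) {
        agg <- stats::aggregate(list(count = hits$w),
                                list(species_id = hits$species_id), sum)
        u21 <- agg
      }
    }
  }
  class_tab <- function(len) {
    sel <- ilen == len & substr(aln$insert, 1L, 1L) == "G"
    if (!any(sel)) return(data.frame(species_id = character(0),
                                     count = numeric(0)))
    d <- stats::aggregate(
      list(count = aln$count[sel] / aln$n_mapped_loci[sel]),
      list(species_id = aln$insert[sel]), sum)
    d
  }
  list(u21 = u21, g22 = class_tab(22L), g26 = class_tab(26L))
}

#' Normalize raw counts to RPM with multi-locus weighting
#'
#' Counts are first divided by the number of genomic loci each species
#' maps to, then scaled to reads per million mapped reads per library.
#'
#' @param counts count data frame (`species_id` + raw counts per library).
#' @param design manifest providing `total_mapped_reads` per library.
#' @param n_mapped_loci integer vector (per species, recycled from 1) of
#'   mapping multiplicities.
#' @return data frame of the same shape with RPM values.
#' @export
normalize_counts <- function(counts, design, n_mapped_loci = 1L) {
  validate_design(design, counts)
  libs <- setdiff(names(counts), "species_id")
  totals <- design$total_mapped_reads[match(libs, design$id)]
  out <- counts
  k <- rep_len(n_mapped_loci, nrow(counts))
  for (j in seq_along(libs))
    out[[libs[j]]] <- counts[[libs[j]]] / k * 1e6 / totals[j]
  out
}
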