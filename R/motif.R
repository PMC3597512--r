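# Upstream core-motif analysis.
#
# Each 21U locus is scanned 60 nt upstream (on its own strand) for the
# best-conserved central GTTTC of the 8-nt core motif. When several GTTTC
# occurrences exist, the one whose implied spacer is closest to the 39-nt
# optimum is selected (ties go to the shorter spacer); this selection is
# configurable. The spacer is the number of nucleotides strictly between
# the 8-mer's 3' end and the 21U 5' T -- all constants (canonical range
# 35-42, optimum 39, fallback anchor -44) are interpreted under this
# convention, which matters because alternative conventions shift them by
# one. Loci without any GTTTC in the window get class "NM" (no motif) and
# a fallback anchor that places the G of the core motif at position -44
# relative to the 5' T.

#' Scan upstream of 21U loci for the core motif
#'
#' @param loci data frame of loci with `locus_id` (or `species_id`),
#'   `chrom`, `strand`, `pos5` (1-based forward coordinate of the 5' T).
#' @param genome named character vector of chromosome sequences.
#' @param window upstream scan width (nt).
#' @param select rule for choosing among multiple GTTTC occurrences:
#'   `"nearest39"` (spacer closest to the optimum, ties to the shorter),
#'   `"leftmost"` (largest spacer) or `"rightmost"` (smallest spacer).
#' @param spacer_optimum the optimal spacer used by `"nearest39"`.
#' @return data frame of motif calls: `locus_id`, `has_gtttc`,
#'   `motif_start` (forward coordinate of the 8-mer's first strand-space
#'   base; fallback anchor for NM calls), `gtttc_start` (same for the G),
#'   `core_8mer`, `five_prime_nt` (`C`/`A`/`G`/`T`/`NM`), `spacer_length`
#'   (`NA` for NM), `in_canonical_range`, `window_truncated`,
#'   `motif_key` (chrom:strand:gtttc_start, shared by minicluster members).
#' @export
scan_upstream <- function(loci, genome, window = 60L,
                          select = c("nearest39", "leftmost", "rightmost"),
                          spacer_optimum = 39L) {
  select <- match.arg(select)
  ids <- loci$locus_id %||% loci$species_id
  n <- nrow(loci)
  out <- data.frame(locus_id = ids, has_gtttc = FALSE,
                    motif_start = NA_integer_, gtttc_start = NA_integer_,
                    core_8mer = NA_character_, five_prime_nt = "NM",
                    spacer_length = NA_integer_,
                    in_canonical_range = FALSE, window_truncated = FALSE,
                    motif_key = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- loci$chrom[i]; strand <- loci$strand[i]; pos5 <- loci$pos5[i]
    clen <- nchar(genome[[ch]])
    # upstream availability in strand space (plus 2 nt of 8mer context)
    avail <- if (strand == "+") pos5 - 1L else clen - pos5
    w <- min(window, avail)
    out$window_truncated[i] <- w < window
    if (w < 8L) next                      # chromosome edge: no-motif call
    # strand-space upstream sequence, u[w] adjacent to the 5' T; extend by
    # 2 nt further upstream so the 8mer context is available at the edge
    ext <- min(w + 2L, avail)
    useq <- if (strand == "+")
      subseq_strand(genome, ch, pos5 - ext, pos5 - 1L, "+")
    else subseq_strand(genome, ch, pos5 + 1L, pos5 + ext, "-")
    off0 <- ext  # strand-space distance of useq end from pos5 is 1
    # GTTTC occurrences; position j in useq is at distance (ext - j + 1)
    # upstream of the T; spacer for occurrence starting at j is
    # ext - j - 5 (nt strictly between the 8mer 3' end and the T)
    hits <- gregexpr("(?=GTTTC)", useq, perl = TRUE)[[1L]]
    sel_hit <- NA_integer_
    if (hits[1L] != -1L) {
      j <- as.integer(hits)
      spacer <- ext - j - 5L
      # in-window occurrences with the full 8mer context available
      keep <- spacer >= 0L & (ext - j + 1L) <= window & j >= 3L
      j <- j[keep]; spacer <- spacer[keep]
      if (length(j)) {
        ord <- switch(select,
          nearest39 = order(abs(spacer - spacer_optimum), spacer),
          leftmost = order(-spacer),
          rightmost = order(spacer))
        sel_hit <- j[ord[1L]]
        sp <- spacer[ord[1L]]
      }
    }
    if (!is.na(sel_hit)) {
      j <- sel_hit
      # 8mer = 2 nt upstream of GTTTC + GTTTC + 1 nt downstream
      left <- substr(useq, j - 2L, j - 1L)
      right <- substr(useq, j + 5L, j + 5L)
      core <- paste0(left, "GTTTC", right)
      out$has_gtttc[i] <- TRUE
      out$core_8mer[i] <- core
      out$five_prime_nt[i] <- substr(left, 1L, 1L)
      out$spacer_length[i] <- sp
      out$in_canonical_range[i] <- sp >= 35L && sp <= 42L
      # strand-space offset of the G upstream of the T
      d_g <- ext - j + 1L
      gf <- if (strand == "+") pos5 - d_g else pos5 + d_g
      mf <- if (strand == "+") gf - 2L else gf + 2L
      out$gtttc_start[i] <- gf
      out$motif_start[i] <- mf
      out$motif_key[i] <- sprintf("%s:%s:%d", ch, strand, gf)
    } else {
      # fallback: align the G of the core motif to position -44
      gf <- if (strand == "+") pos5 - 44L else pos5 + 44L
      out$gtttc_start[i] <- gf
      out$motif_start[i] <- if (strand == "+") gf - 2L else gf + 2L
    }
  }
  # a truncated 8mer context (locus too close to the edge for the 2 nt
  # upstream of GTTTC) keeps has_gtttc but reports NM class
  out
}

#' Cross-tabulate motif 5' nucleotide by enrichment class
#'
#' Only uniquely mapping loci should be supplied (loci mapping to several
#' genomic positions can have different upstream sequences).
#'
#' @param calls motif calls from [scan_upstream()].
#' @param classifications data frame with `species_id` (or `locus_id`) and
#'   `classification` (as from an `enrichment_fit`'s `$results`), or a
#'   named character vector keyed by locus id.
#' @return list with `table` (class x five_prime_nt counts), `chisq_p`
#'   (Pearson, no continuity correction), and `spacer_histograms` (list of
#'   spacer-length tables per class).
#' @export
classify_motifs <- function(calls, classifications) {
  if (is.data.frame(classifications)) {
    key <- classifications$species_id %||% classifications$locus_id
    cls <- stats::setNames(classifications$classification, key)
  } else cls <- classifications
  cc <- unname(cls[calls$locus_id])
  keep <- !is.na(cc)
  tab <- table(class = cc[keep],
               five_prime_nt = factor(calls$five_prime_nt[keep],
                                      levels = c("C", "A", "G", "T",
                                                 "NM")))
  if (nrow(tab) < 2L || sum(colSums(tab) > 0) < 2L)
    stop("contingency table is degenerate (need >= 2 classes and >= 2 ",
         "motif categories with counts); chi-square is undefined")
  # small expected cells are routine for sparse motif categories; the
  # approximation warning is not actionable here
  p <- suppressWarnings(
    stats::chisq.test(tab[, colSums(tab) > 0], correct = FALSE)$p.value)
  spl <- split(calls$spacer_length[keep], cc[keep])
  hists <- lapply(spl, function(x) table(x[!is.na(x)]))
  list(table = tab, chisq_p = p, spacer_histograms = hists)
}

#' Mean abundance by motif 5'-nt class
#'
#' Libraries prepared with 5'-monophosphate-dependent and -independent
#' protocols are averaged separately; pass the subset of interest.
#'
#' @param calls motif calls.
#' @param abundances RPM data frame (`species_id` + libraries).
#' @param libraries character vector of library ids to average over.
#' @return list with `stats` (per five_prime_nt class: n, mean RPM, SEM;
#'   single-member classes get `NA` SEM and are excluded from tests) and
#'   `welch_p` (matrix of pairwise two-tailed Welch p-values).
#' @export
abundance_by_motif_class <- function(calls, abundances, libraries) {
  m <- counts_matrix(abundances)
  x <- rowMeans(m[, libraries, drop = FALSE])
  v <- x[calls$locus_id]
  keep <- !is.na(v)
  grp <- split(unname(v[keep]), calls$five_prime_nt[keep])
  st <- data.frame(
    five_prime_nt = names(grp),
    n = lengths(grp),
    mean_rpm = vapply(grp, mean, numeric(1)),
    sem = vapply(grp, sem, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  testable <- names(grp)[lengths(grp) >= 2L]
  p <- matrix(NA_real_, length(testable), length(testable),
              dimnames = list(testable, testable))
  if (length(testable) >= 2L)
    for (a in seq_along(testable)) for (b in seq_along(testable))
      if (a < b)
        p[a, b] <- p[b, a] <- stats::t.test(grp[[testable[a]]],
                                            grp[[testable[b]]])$p.value
  list(stats = st, welch_p = p)
}

#' Background-corrected motif matrix
#'
#' Upstream windows are aligned on the central three Ts of the core motif
#' (the TTT inside GTTTC); loci without a motif are aligned via the -44
#' fallback anchor. Per-position information content is the relative
#' entropy sum(f_b * log2(f_b / q_b)) against the genome background
#' composition.
#'
#' @param calls motif calls from [scan_upstream()].
#' @param loci the locus table the calls were made from.
#' @param genome named character vector.
#' @param upstream,downstream window half-extents around the alignment
#'   anchor (the first central T).
#' @param background optional named base frequencies (A, C, G, T);
#'   defaults to the genome composition.
#' @return list with `freq` (position x 4 frequency matrix), `bits`
#'   (information content per position), `background` and `n_windows`.
#'   Positions are labelled by offset from the first central T.
#' @export
motif_matrix <- function(calls, loci, genome, upstream = 10L,
                         downstream = 49L, background = NULL) {
  if (is.null(background)) {
    cnt <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(genome), letters = DNA_BASES))
    background <- cnt / sum(cnt)
  }
  background <- background[DNA_BASES]
  ids <- loci$locus_id %||% loci$species_id
  width <- upstream + downstream + 1L
  rows <- character(0)
  for (i in seq_len(nrow(calls))) {
    li <- match(calls$locus_id[i], ids)
    ch <- loci$chrom[li]; strand <- loci$strand[li]
    # anchor = first central T = base after the G of GTTTC
    ga <- calls$gtttc_start[i]
    anchor <- if (strand == "+") ga + 1L else ga - 1L
    from <- if (strand == "+") anchor - upstream else anchor - downstream
    to <- if (strand == "+") anchor + downstream else anchor + upstream
    if (from < 1L || to > nchar(genome[[ch]])) next
    rows <- c(rows, subseq_strand(genome, ch, from, to, strand))
  }
  if (length(rows) == 0L) stop("no alignable windows")
  m <- seq_to_mat(rows)
  freq <- t(apply(m, 2L, function(col) {
    col <- col[col %in% DNA_BASES]
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L) /
      max(length(col), 1L)
  }))
  colnames(freq) <- DNA_BASES
  rownames(freq) <- as.character(seq_len(width) - upstream - 1L)
  bits <- apply(freq, 1L, function(f) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / background[nz]))
  })
  list(freq = freq, bits = bits, background = background,
       n_windows = length(rows))
}

#' k-mer density in genomic regions (occurrences per kilobase)
#'
#' Counts occurrences of `kmer` on both strands (overlapping occurrences
#' all count) within the given regions and divides by the total region
#' length in kb.
#'
#' @param genome named character vector.
#' @param regions data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param kmer the k-mer (default the conserved core `GTTTC`).
#' @param both_strands count the reverse complement too.
#' @return occurrences per kilobase (numeric scalar).
#' @export
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 100), "GTTTC", strrep("A", 895)))
#' kmer_density(g, data.frame(chrom = "chr1", start = 1, end = 1000))
kmer_density <- function(genome, regions, kmer = "GTTTC",
                         both_strands = TRUE) {
  count_in <- function(s, pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }
  total <- 0L; bp <- 0
  rc <- revcomp(kmer)
  for (i in seq_len(nrow(regions))) {
    s <- subseq_strand(genome, regions$chrom[i], regions$start[i],
                       regions$end[i], "+")
    total <- total + count_in(s, kmer)
    if (both_strands && rc != kmer) total <- total + count_in(s, rc)
    bp <- bp + nchar(s)
  }
  total / (bp / 1000)
}
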