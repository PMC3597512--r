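# 21U target search and 22G RNA attribution.
#
# A 21U RNA targets a transcript wherever the transcript's reverse
# complement matches the 21U with at most 3 substitutions (pure Hamming
# model: no gaps, no G:U wobble, every position weighted equally). 22G
# RNAs mapping antisense to a transcript within 40 nt of a target site are
# attributed to the site's 21U class; species detected in a prg-1 mutant
# library are excluded first (they are not piRNA-dependent).

#' Find 21U target sites on transcripts
#'
#' @param u21 named character vector of 21U sequences (21 nt, DNA).
#' @param transcripts named character vector of transcript sequences.
#' @param max_mismatches maximum Hamming distance (default 3).
#' @return data frame of sites: `transcript_id`, `start`, `end` (1-based
#'   inclusive 21-nt footprint on the transcript), `source_21u`,
#'   `n_mismatches`.
#' @export
find_targets <- function(u21, transcripts, max_mismatches = 3L) {
  if (any(nchar(u21) != 21L)) stop("21U sequences must be 21 nt")
  if (any(nchar(transcripts) < 21L)) stop("transcripts must be >= 21 nt")
  if (is.null(names(u21))) names(u21) <- paste0("u21_", seq_along(u21))
  subj <- lapply(transcripts, Biostrings::DNAString)
  out <- list()
  for (k in seq_along(u21)) {
    pat <- revcomp(u21[[k]])
    for (tx in names(transcripts)) {
      m <- Biostrings::matchPattern(pat, subj[[tx]],
                                    max.mismatch = max_mismatches,
                                    fixed = TRUE)
      if (length(m) == 0L) next
      mm <- Biostrings::neditAt(Biostrings::DNAString(pat), subj[[tx]],
                                at = IRanges::start(m), fixed = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, start = IRanges::start(m),
        end = IRanges::start(m) + 20L, source_21u = names(u21)[k],
        n_mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), source_21u = character(0),
                      n_mismatches = integer(0))
  res
}

# footprint gap between [s1,e1] and [s2,e2]; 0 when they overlap or touch
.footprint_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2, s2 - e1) - 1L)
}

#' Attribute 22G RNAs to male / female 21U target sites
#'
#' A 22G species is attributed to the classes of all target sites on the
#' same transcript whose footprint lies within `distance` nt of the 22G
#' footprint (overlap counts as distance 0): `male_only`, `female_only`,
#' `ambiguous` (within range of at least one site of each class) or
#' `none`. Species with any read in the prg-1 library are excluded before
#' attribution (`none`, flagged `prg1_detected`).
#'
#' @param g22 data frame of 22G species with `species_22g`,
#'   `transcript_id`, `start`, `end` and count columns `counts_wt`,
#'   `counts_prg1` (or supply `prg1_detected` directly).
#' @param sites target-site data frame (as from [find_targets()]) plus a
#'   `class` column (`"male"`/`"female"`, e.g. from the source 21U's
#'   enrichment classification).
#' @param distance maximum footprint gap (nt).
#' @return data frame per species: `species_22g`, `attributed_to`,
#'   `n_male_sites`, `n_female_sites`, `min_gap`, `prg1_detected`.
#' @export
attribute_22g <- function(g22, sites, distance = 40L) {
  if (!"class" %in% names(sites))
    stop("'sites' needs a 'class' column (male/female)")
  prg1 <- if ("prg1_detected" %in% names(g22)) g22$prg1_detected else
    g22$counts_prg1 > 0
  out <- data.frame(species_22g = g22$species_22g,
                    attributed_to = "none",
                    n_male_sites = 0L, n_female_sites = 0L,
                    min_gap = NA_integer_, prg1_detected = prg1,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g22))) {
    s <- sites[sites$transcript_id == g22$transcript_id[i], ,
               drop = FALSE]
    if (nrow(s) == 0L) next
    gap <- .footprint_gap(g22$start[i], g22$end[i], s$start, s$end)
    near <- gap <= distance
    out$min_gap[i] <- min(gap)
    out$n_male_sites[i] <- sum(near & s$class == "male")
    out$n_female_sites[i] <- sum(near & s$class == "female")
    if (prg1[i]) next
    out$attributed_to[i] <-
      if (out$n_male_sites[i] > 0L && out$n_female_sites[i] > 0L)
        "ambiguous"
      else if (out$n_male_sites[i] > 0L) "male_only"
      else if (out$n_female_sites[i] > 0L) "female_only"
      else "none"
  }
  out
}

#' Randomization test for male / female target overlap
#'
#' Draws disjoint random "male" and "female" 21U sets of the observed
#' sizes, recomputes the number of 22G species attributable to both
#' classes (or of shared target genes), and compares the observed count to
#' the randomization mean by 2x2 chi-square.
#'
#' @param u21 named character vector of all 21U sequences.
#' @param classes named classification per 21U (values `male`/`female`/
#'   other; only used for the observed statistic and set sizes).
#' @param transcripts named character vector of transcripts.
#' @param g22 22G species table (see [attribute_22g()]).
#' @param sizes optional `c(n_male, n_female)`; defaults to the observed
#'   class sizes.
#' @param n_reps randomization replicates.
#' @param distance attribution distance.
#' @param max_mismatches target-search mismatch cap.
#' @param statistic `"both_22g"` (22G species near both classes) or
#'   `"shared_genes"` (transcripts targeted by both classes).
#' @param seed random seed.
#' @return list with `observed`, `random` (per-rep counts), `expected`
#'   (their mean), `quantiles`, `chisq_p` and `fisher_p`.
#' @export
overlap_randomization <- function(u21, classes, transcripts, g22,
                                  sizes = NULL, n_reps = 1000L,
                                  distance = 40L, max_mismatches = 3L,
                                  statistic = c("both_22g",
                                                "shared_genes"),
                                  seed = 1) {
  statistic <- match.arg(statistic)
  seed <- check_seed(seed)
  classes <- classes[names(u21)]
  if (is.null(sizes))
    sizes <- c(sum(classes == "male", na.rm = TRUE),
               sum(classes == "female", na.rm = TRUE))
  # precompute, per 22G species / per transcript, the set of source 21Us
  # within range, so each replicate is a membership lookup
  sites <- find_targets(u21, transcripts, max_mismatches)
  prg1 <- if ("prg1_detected" %in% names(g22)) g22$prg1_detected else
    g22$counts_prg1 > 0
  neighbors <- lapply(seq_len(nrow(g22)), function(i) {
    if (prg1[i]) return(character(0))
    s <- sites[sites$transcript_id == g22$transcript_id[i], ,
               drop = FALSE]
    if (nrow(s) == 0L) return(character(0))
    gap <- .footprint_gap(g22$start[i], g22$end[i], s$start, s$end)
    unique(s$source_21u[gap <= distance])
  })
  tx_by_source <- split(sites$transcript_id, sites$source_21u)
  count_stat <- function(male_set, female_set) {
    if (statistic == "both_22g") {
      sum(vapply(neighbors, function(nb)
        any(nb %in% male_set) && any(nb %in% female_set), logical(1)))
    } else {
      tm <- unique(unlist(tx_by_source[male_set], use.names = FALSE))
      tf <- unique(unlist(tx_by_source[female_set], use.names = FALSE))
      length(intersect(tm, tf))
    }
  }
  observed <- count_stat(names(u21)[which(classes == "male")],
                         names(u21)[which(classes == "female")])
  total <- if (statistic == "both_22g") sum(!prg1) else
    length(transcripts)
  withr_seed(seed, {
    random <- vapply(seq_len(n_reps), function(b) {
      pick <- sample(names(u21), sum(sizes))
      count_stat(pick[seq_len(sizes[1L])],
                 pick[sizes[1L] + seq_len(sizes[2L])])
    }, numeric(1))
  })
  expected <- mean(random)
  tab <- rbind(observed = c(both = observed, not = total - observed),
               expected = c(both = expected, not = total - expected))
  chisq_p <- tryCatch(stats::chisq.test(round(tab),
                                        correct = FALSE)$p.value,
                      error = function(e) NA_real_,
                      warning = function(w)
                        suppressWarnings(stats::chisq.test(
                          round(tab), correct = FALSE)$p.value))
  fisher_p <- tryCatch(stats::fisher.test(round(tab))$p.value,
                       error = function(e) NA_real_)
  list(observed = observed, random = random, expected = expected,
       quantiles = stats::quantile(random, c(0.025, 0.5, 0.975)),
       chisq_p = chisq_p, fisher_p = fisher_p, sizes = sizes,
       statistic = statistic)
}

#' Gene-set enrichment by randomization
#'
#' Compares the number of target genes falling in a category (e.g.
#' spermatogenesis-enriched transcripts) against random gene lists of the
#' same size drawn from the universe, with a 2x2 chi-square of observed vs
#' expected in-category counts.
#'
#' @param target_genes character vector of target gene ids.
#' @param category character vector of category gene ids (non-empty).
#' @param universe character vector of all gene ids.
#' @param n_random number of random lists.
#' @param seed random seed.
#' @return list with `observed`, `expected`, `chisq_p`, `direction`.
#' @export
geneset_enrichment <- function(target_genes, category, universe,
                               n_random = 1000L, seed = 1) {
  if (length(category) == 0L) stop("category is empty")
  seed <- check_seed(seed)
  target_genes <- unique(target_genes)
  k <- length(target_genes)
  if (k == 0L) stop("no target genes supplied")
  observed <- sum(target_genes %in% category)
  withr_seed(seed, {
    random <- vapply(seq_len(n_random), function(b)
      sum(sample(universe, k) %in% category), numeric(1))
  })
  expected <- mean(random)
  tab <- rbind(observed = c(observed, k - observed),
               expected = c(expected, k - expected))
  chisq_p <- tryCatch(
    suppressWarnings(stats::chisq.test(round(tab),
                                       correct = FALSE)$p.value),
    error = function(e) NA_real_)
  list(observed = observed, expected = expected, chisq_p = chisq_p,
       direction = if (observed < expected) "depleted" else "enriched",
       random = random)
}
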