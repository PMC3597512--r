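# Minicluster analysis.
#
# Overlapping 21U loci expressed from thymidines downstream of one shared
# core motif form "miniclusters"; loci whose motif is not shared are
# "solitary". Two-member germline-enriched miniclusters are tested for
# random assortment of their members' enrichment classes: with member
# male fraction p and female fraction q = 1 - p, random pairing predicts
# p^2 male:male, q^2 female:female and 2pq mixed pairs.

#' Group uniquely mapping loci into miniclusters by shared motif
#'
#' @param calls motif calls from [scan_upstream()] restricted to uniquely
#'   mapping loci; only calls with a motif (`has_gtttc`) can share one.
#' @return list with `miniclusters` (data frame: `motif_key`, `size`,
#'   `members` comma-joined), `membership` (per-locus data frame with
#'   `motif_key` and `miniclustered` flag), and `solitary` (locus ids).
#' @export
group_miniclusters <- function(calls) {
  has <- calls$has_gtttc
  key <- ifelse(has, calls$motif_key, NA_character_)
  tab <- table(key[!is.na(key)])
  shared <- names(tab)[tab >= 2L]
  mini <- ifelse(!is.na(key) & key %in% shared, key, NA_character_)
  membership <- data.frame(locus_id = calls$locus_id, motif_key = key,
                           miniclustered = !is.na(mini),
                           stringsAsFactors = FALSE)
  mc <- if (length(shared)) {
    grp <- split(calls$locus_id[!is.na(mini)], mini[!is.na(mini)])
    # sort by key for input-order invariance
    grp <- grp[order(names(grp))]
    data.frame(motif_key = names(grp), size = lengths(grp),
               members = vapply(grp, function(m)
                 paste(sort(m), collapse = ","), character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(motif_key = character(0), size = integer(0),
                    members = character(0))
  list(miniclusters = mc, membership = membership,
       solitary = calls$locus_id[!membership$miniclustered])
}

#' Spacer-length abundance profile, miniclustered vs solitary
#'
#' @param calls motif calls (need `spacer_length`).
#' @param membership membership data frame from [group_miniclusters()].
#' @param abundances RPM data frame (`species_id` + libraries), or a named
#'   numeric vector of per-locus abundances.
#' @param libraries library ids averaged per locus (ignored for a vector).
#' @return list with `profile` (data frame: `spacer`, `group`, `n`,
#'   `mean_rpm`, `sem`), `welch` (per matched spacer length: two-tailed
#'   Welch p), and `argmax` (per group, the spacer with maximal mean).
#' @export
spacer_abundance_profile <- function(calls, membership, abundances,
                                     libraries = NULL) {
  if (is.data.frame(abundances)) {
    m <- counts_matrix(abundances)
    if (is.null(libraries)) libraries <- colnames(m)
    ab <- rowMeans(m[, libraries, drop = FALSE])
  } else ab <- abundances
  v <- unname(ab[calls$locus_id])
  grp <- ifelse(membership$miniclustered[match(calls$locus_id,
                                               membership$locus_id)],
                "miniclustered", "solitary")
  keep <- !is.na(v) & !is.na(calls$spacer_length)
  d <- data.frame(spacer = calls$spacer_length[keep], group = grp[keep],
                  rpm = v[keep])
  spl <- split(d$rpm, list(spacer = d$spacer, group = d$group),
               drop = TRUE)
  meta <- do.call(rbind, strsplit(names(spl), ".", fixed = TRUE))
  profile <- data.frame(spacer = as.integer(meta[, 1L]),
                        group = meta[, 2L], n = lengths(spl),
                        mean_rpm = vapply(spl, mean, numeric(1)),
                        sem = vapply(spl, sem, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  profile <- profile[order(profile$group, profile$spacer), ]
  # Welch tests at spacer lengths observed in both groups (>= 2 each)
  common <- intersect(profile$spacer[profile$group == "miniclustered" &
                                       profile$n >= 2L],
                      profile$spacer[profile$group == "solitary" &
                                       profile$n >= 2L])
  welch <- vapply(common, function(s)
    stats::t.test(d$rpm[d$spacer == s & d$group == "miniclustered"],
                  d$rpm[d$spacer == s & d$group == "solitary"])$p.value,
    numeric(1))
  argmax <- vapply(split(profile, profile$group), function(p)
    p$spacer[which.max(p$mean_rpm)], integer(1))
  list(profile = profile,
       welch = data.frame(spacer = common, p = welch),
       argmax = argmax)
}

#' Thymidine richness of the optimal window downstream of motifs
#'
#' Counts genomic thymidines at the eight positions whose implied spacer
#' lies in 35-42 nt downstream of each GTTTC-containing motif, and
#' compares shared (miniclustered) vs non-shared motifs by two-tailed
#' Welch's t-test.
#'
#' @param calls motif calls with `has_gtttc`, `gtttc_start`, `motif_key`.
#' @param loci locus table (for `chrom`/`strand`).
#' @param genome named character vector.
#' @param membership membership from [group_miniclusters()]; `NULL` skips
#'   the shared/non-shared comparison.
#' @param window integer spacer window (default 35:42).
#' @return list with `counts` (per motif: `motif_key`, `shared`,
#'   `n_window_T`) and `welch_p`.
#' @export
window_T_richness <- function(calls, loci, genome, membership = NULL,
                              window = 35:42) {
  ids <- loci$locus_id %||% loci$species_id
  calls <- calls[calls$has_gtttc, , drop = FALSE]
  # one row per distinct motif
  calls <- calls[!duplicated(calls$motif_key), , drop = FALSE]
  nT <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    li <- match(calls$locus_id[i], ids)
    ch <- loci$chrom[li]; strand <- loci$strand[li]
    # 8mer 3' end is 5 strand-space positions downstream of the G; a T
    # with spacer s sits s + 1 past it
    g <- calls$gtttc_start[i]
    offs <- 5L + window + 1L
    pos <- if (strand == "+") g + offs else g - offs
    pos <- pos[pos >= 1L & pos <= nchar(genome[[ch]])]
    bases <- vapply(pos, function(p)
      subseq_strand(genome, ch, p, p, strand), character(1))
    nT[i] <- sum(bases == "T")
  }
  shared <- if (is.null(membership)) rep(NA, nrow(calls)) else {
    mk <- membership$motif_key[membership$miniclustered]
    calls$motif_key %in% mk
  }
  counts <- data.frame(motif_key = calls$motif_key, shared = shared,
                       n_window_T = nT, stringsAsFactors = FALSE)
  welch_p <- if (!is.null(membership) && sum(shared) >= 2L &&
                 sum(!shared) >= 2L)
    stats::t.test(nT[shared], nT[!shared])$p.value else NA_real_
  list(counts = counts, welch_p = welch_p)
}

#' Pair-composition random-assortment test
#'
#' Analyzes miniclusters of exactly two germline-enriched members. The
#' expectation under random assortment is computed analytically from the
#' member fractions (p^2, q^2, 2pq) and, optionally, by permutation
#' (random re-pairing of the observed members). Pair counts may be given
#' directly (`n_pairs` with observed fractions) instead of a pair table.
#'
#' @param pairs either a data frame with columns `class1`, `class2`
#'   (values `"male"`/`"female"`, one row per 2-member minicluster), or
#'   `NULL` when `observed` is supplied.
#' @param observed optional named numeric `c(mm=, ff=, mf=)` of observed
#'   pair fractions (or counts) used with `n_pairs` for the desk version.
#' @param n_pairs number of pairs (required with `observed`).
#' @param n_perm permutation replicates (0 = analytic only).
#' @param seed seed for the permutation.
#' @return a `pair_composition` list: `n_pairs`, observed and expected
#'   fractions (`mm`, `ff`, `mf`), member fractions `p`/`q`, matching
#'   observed/expected fractions, `chisq_p`, and (when permuted)
#'   `perm_expected`.
#' @export
#' @examples
#' pair_composition(observed = c(mm = 0.73, ff = 0.12, mf = 0.15),
#'                  n_pairs = 1026)
pair_composition <- function(pairs = NULL, observed = NULL, n_pairs = NULL,
                             n_perm = 0L, seed = 1) {
  if (is.null(pairs)) {
    if (is.null(observed) || is.null(n_pairs))
      stop("need either a pair table or observed fractions with n_pairs")
    obs <- observed / sum(observed)
    members <- NULL
  } else {
    if (nrow(pairs) == 0L) stop("no pairs to analyze")
    if (!all(unlist(pairs[c("class1", "class2")]) %in%
             c("male", "female")))
      stop("pair members must be male or female germline-enriched")
    n_pairs <- nrow(pairs)
    mm <- mean(pairs$class1 == "male" & pairs$class2 == "male")
    ff <- mean(pairs$class1 == "female" & pairs$class2 == "female")
    obs <- c(mm = mm, ff = ff, mf = 1 - mm - ff)
    members <- c(pairs$class1, pairs$class2)
  }
  p <- unname(obs[["mm"]] + obs[["mf"]] / 2)   # member male fraction
  q <- 1 - p
  expected <- c(mm = p^2, ff = q^2, mf = 2 * p * q)
  degenerate <- p == 0 || q == 0
  obs_counts <- c(matching = (obs[["mm"]] + obs[["ff"]]) * n_pairs,
                  mixed = obs[["mf"]] * n_pairs)
  chisq_p <- if (degenerate) NA_real_ else
    stats::chisq.test(round(obs_counts),
                      p = c(expected[["mm"]] + expected[["ff"]],
                            expected[["mf"]]))$p.value
  out <- list(n_pairs = n_pairs, observed = obs, expected = expected,
              p = p, q = q,
              observed_matching = unname(obs[["mm"]] + obs[["ff"]]),
              expected_matching = unname(expected[["mm"]] +
                                           expected[["ff"]]),
              chisq_p = chisq_p, degenerate = degenerate)
  if (n_perm > 0L && !is.null(members)) {
    seed <- check_seed(seed)
    withr_seed(seed, {
      reps <- matrix(0, n_perm, 3L)
      for (b in seq_len(n_perm)) {
        sh <- sample(members)
        a <- sh[seq_len(n_pairs)]
        bb <- sh[n_pairs + seq_len(n_pairs)]
        reps[b, ] <- c(mean(a == "male" & bb == "male"),
                       mean(a == "female" & bb == "female"),
                       mean(a != bb))
      }
    })
    out$perm_expected <- stats::setNames(colMeans(reps),
                                         c("mm", "ff", "mf"))
    out$perm_se <- stats::setNames(apply(reps, 2L, stats::sd) /
                                     sqrt(n_perm), c("mm", "ff", "mf"))
  }
  class(out) <- "pair_composition"
  out
}

#' @export
print.pair_composition <- function(x, ...) {
  cat(sprintf("Pair composition of %d two-member miniclusters\n",
              x$n_pairs))
  cat(sprintf("  member fractions: male %.3f, female %.3f\n", x$p, x$q))
  m <- rbind(observed = x$observed, expected = x$expected)
  print(round(m, 3))
  cat(sprintf("  matching: observed %.1f%%, expected %.1f%% (chi-sq p = %.3g)\n",
              100 * x$observed_matching, 100 * x$expected_matching,
              x$chisq_p))
  invisible(x)
}

#' Extract two-member germline-enriched pairs from miniclusters
#'
#' @param miniclusters data frame from [group_miniclusters()].
#' @param classifications data frame with `species_id`/`locus_id` and
#'   `classification`.
#' @return data frame with `motif_key`, `class1`, `class2` for the
#'   miniclusters of exactly two members both classified male or female.
#' @export
enriched_pairs <- function(miniclusters, classifications) {
  key <- classifications$species_id %||% classifications$locus_id
  cls <- stats::setNames(classifications$classification, key)
  two <- miniclusters[miniclusters$size == 2L, , drop = FALSE]
  out <- lapply(seq_len(nrow(two)), function(i) {
    m <- strsplit(two$members[i], ",", fixed = TRUE)[[1L]]
    c1 <- unname(cls[m[1L]]); c2 <- unname(cls[m[2L]])
    if (is.na(c1) || is.na(c2)) return(NULL)
    if (!all(c(c1, c2) %in% c("male", "female"))) return(NULL)
    data.frame(motif_key = two$motif_key[i], class1 = c1, class2 = c2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(motif_key = character(0), class1 = character(0),
                      class2 = character(0))
  out
}
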