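# Enrichment Score classification.
#
# For each small RNA species, abundance is compared between every male and
# every female germline library prepared with the same 5'-monophosphate
# protocol. Starting from 0, the Enrichment Score decreases by 1 for every
# comparison in which the species is more than `fold_threshold`-fold
# abundant in the male library and increases by 1 when more than
# `fold_threshold`-fold abundant in the female library. Scores <= -3
# define male germline-enriched species, >= +3 female. The comparison is a
# strict multiplicative inequality, so a zero-vs-positive pair always
# scores for the positive side and a zero-vs-zero pair contributes 0; no
# pseudocount enters the score.

# list of (male index, female index) column pairs within protocol groups
.comparison_pairs <- function(design) {
  g <- germline_libraries(design)
  pairs <- list()
  for (prot in unique(g$protocol)) {
    m <- g$id[g$protocol == prot & g$sex == "male"]
    f <- g$id[g$protocol == prot & g$sex == "female"]
    for (mi in m) for (fi in f)
      pairs[[length(pairs) + 1L]] <- c(male = mi, female = fi)
  }
  pairs
}

#' Number of male x female library comparisons in a design
#'
#' The sum over protocol groups of (number of male germline libraries) x
#' (number of female germline libraries).
#'
#' @param design library manifest.
#' @return integer comparison count.
#' @export
#' @examples
#' count_comparisons(default_design())  # 23
count_comparisons <- function(design) {
  validate_design(design)
  length(.comparison_pairs(design))
}

#' Enrichment Score per species
#'
#' @param abundances numeric matrix (species x libraries; column names are
#'   library ids) of normalized abundances (RPM) -- or raw counts for the
#'   randomization null, which simulates unnormalized data.
#' @param design library manifest covering all abundance columns.
#' @param fold_threshold fold-change needed for a comparison to score.
#' @return integer vector of scores, one per row; bounded by +/- the
#'   number of comparisons. Negative scores indicate male enrichment.
#' @export
enrichment_score <- function(abundances, design, fold_threshold = 5) {
  if (is.data.frame(abundances) && "species_id" %in% names(abundances))
    abundances <- counts_matrix(abundances)
  if (is.null(dim(abundances)))
    abundances <- matrix(abundances, nrow = 1,
                         dimnames = list(NULL, names(abundances)))
  if (any(abundances < 0)) stop("abundances must be non-negative")
  pairs <- .comparison_pairs(design)
  if (length(pairs) == 0L)
    stop("design has no male x female comparisons within any protocol")
  g <- germline_libraries(design)
  missing_cols <- setdiff(g$id, colnames(abundances))
  if (length(missing_cols))
    stop("abundances lack germline libraries: ",
         paste(missing_cols, collapse = ", "))
  score <- integer(nrow(abundances))
  for (p in pairs) {
    m <- abundances[, p[["male"]]]
    f <- abundances[, p[["female"]]]
    score <- score - (m > fold_threshold * f) + (f > fold_threshold * m)
  }
  as.integer(score)
}

#' Average fold abundance between male and female libraries
#'
#' Per comparison the fold is `(male + pseudocount) / (female +
#' pseudocount)`; the male average is the geometric mean over all
#' comparisons and the female average its reciprocal. The pseudocount is
#' needed only here (ratios of zeros are undefined); it never enters the
#' Enrichment Score itself.
#'
#' @inheritParams enrichment_score
#' @param pseudocount added to both sides of every ratio (RPM units).
#' @return data frame with `avg_fold_male`, `avg_fold_female` per row.
#' @export
average_fold <- function(abundances, design, pseudocount = 0.25) {
  if (is.data.frame(abundances) && "species_id" %in% names(abundances))
    abundances <- counts_matrix(abundances)
  pairs <- .comparison_pairs(design)
  lf <- matrix(0, nrow(abundances), length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    lf[, k] <- log((abundances[, p[["male"]]] + pseudocount) /
                     (abundances[, p[["female"]]] + pseudocount))
  }
  fold_m <- exp(rowMeans(lf))
  data.frame(avg_fold_male = fold_m, avg_fold_female = 1 / fold_m)
}

#' Classify species as male / female germline-enriched
#'
#' Applies, in order: exclusion of species with no reads in any germline
#' library (`excluded_zero`); exclusion of species with higher abundance
#' in a prg-1 mutant library than in the wild-type reference library
#' (`excluded_mutant`: such species are not piRNA-dependent); threshold
#' classification on the Enrichment Score; and reclassification to
#' `non_enriched` of any classified species whose average fold abundance
#' does not favor its class.
#'
#' @param counts count data frame (`species_id` + one column per library)
#'   of raw counts.
#' @param design library manifest.
#' @param abundances optional matching data frame of normalized RPM; when
#'   `NULL` it is computed with [normalize_counts()].
#' @param fold_threshold,score_threshold,pseudocount classifier settings.
#' @param mutant_lib,reference_lib library ids for the dependence filter
#'   (both must exist in the counts or the filter is skipped).
#' @return an object of class `enrichment_fit`: see
#'   [summary.enrichment_fit()]. Its `$results` data frame has one row per
#'   species with `score`, `classification`, `avg_fold_male`,
#'   `avg_fold_female` and `reclassified`.
#' @export
#' @examples
#' sim <- simulate_counts(data.frame(species_id = paste0("u", 1:50),
#'                                   truth_class = "male"),
#'                        seed = 42)
#' fit <- classify_enrichment(sim$counts, default_design())
#' table(fit$results$classification)
classify_enrichment <- function(counts, design,
                                abundances = NULL,
                                fold_threshold = 5, score_threshold = 3L,
                                pseudocount = 0.25,
                                mutant_lib = "prg1_ya",
                                reference_lib = "n2_ya") {
  validate_design(design, counts, require_germline = TRUE)
  raw <- counts_matrix(counts)
  rpm <- if (is.null(abundances)) counts_matrix(normalize_counts(counts,
                                                                 design))
  else counts_matrix(abundances)
  g <- germline_libraries(design)
  score <- enrichment_score(rpm, design, fold_threshold)
  folds <- average_fold(rpm, design, pseudocount)

  cls <- rep("non_enriched", nrow(raw))
  cls[score <= -score_threshold] <- "male"
  cls[score >= score_threshold] <- "female"
  reclassified <- rep(FALSE, nrow(raw))
  reclassified[cls == "male" & folds$avg_fold_male <= 1] <- TRUE
  reclassified[cls == "female" & folds$avg_fold_female <= 1] <- TRUE
  cls[reclassified] <- "non_enriched"
  # exclusions take precedence over everything
  zero <- rowSums(raw[, g$id, drop = FALSE]) == 0
  cls[zero] <- "excluded_zero"
  if (all(c(mutant_lib, reference_lib) %in% colnames(rpm))) {
    mut <- rpm[, mutant_lib] > rpm[, reference_lib]
    cls[!zero & mut] <- "excluded_mutant"
  }
  res <- data.frame(species_id = counts$species_id, score = score,
                    classification = cls,
                    avg_fold_male = folds$avg_fold_male,
                    avg_fold_female = folds$avg_fold_female,
                    reclassified = reclassified & cls == "non_enriched",
                    stringsAsFactors = FALSE)
  structure(list(results = res, design = design,
                 n_comparisons = count_comparisons(design),
                 fold_threshold = fold_threshold,
                 score_threshold = score_threshold,
                 pseudocount = pseudocount,
                 call = match.call()),
            class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("Enrichment Score classification\n")
  cat(sprintf("  %d species, %d male x female comparisons (fold > %g, |score| >= %d)\n",
              nrow(x$results), x$n_comparisons, x$fold_threshold,
              x$score_threshold))
  tab <- table(factor(x$results$classification,
                      levels = c("male", "female", "non_enriched",
                                 "excluded_zero", "excluded_mutant")))
  for (k in names(tab))
    cat(sprintf("  %-16s %6d (%.1f%%)\n", k, tab[[k]],
                100 * tab[[k]] / nrow(x$results)))
  invisible(x)
}

#' Summarize an enrichment fit
#'
#' @param object an `enrichment_fit`.
#' @param ... unused.
#' @return list with the classification table, class proportions, mean
#'   average folds per class and the reclassified count.
#' @export
summary.enrichment_fit <- function(object, ...) {
  r <- object$results
  tab <- table(r$classification)
  classified <- r[r$classification %in% c("male", "female"), ]
  out <- list(
    n = nrow(r),
    classification = tab,
    proportions = tab / nrow(r),
    n_reclassified = sum(r$reclassified),
    mean_fold_male = mean(r$avg_fold_male[r$classification == "male"]),
    mean_fold_female = mean(r$avg_fold_female[r$classification ==
                                                "female"]),
    fraction_enriched = nrow(classified) / nrow(r))
  class(out) <- "summary.enrichment_fit"
  out
}

#' @export
print.summary.enrichment_fit <- function(x, ...) {
  cat(sprintf("%d species; %.1f%% germline-enriched (%d reclassified)\n",
              x$n, 100 * x$fraction_enriched, x$n_reclassified))
  print(x$classification)
  cat(sprintf("mean fold (male class, male/female libraries): %.2f\n",
              x$mean_fold_male))
  cat(sprintf("mean fold (female class, female/male libraries): %.2f\n",
              x$mean_fold_female))
  invisible(x)
}

#' Score histogram of an enrichment fit
#'
#' @param x an `enrichment_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.enrichment_fit <- function(x, ...) {
  s <- x$results$score[!startsWith(x$results$classification, "excluded")]
  C <- x$n_comparisons
  tab <- table(factor(s, levels = -C:C))
  cols <- ifelse(as.integer(names(tab)) <= -x$score_threshold, "steelblue",
                 ifelse(as.integer(names(tab)) >= x$score_threshold,
                        "firebrick", "grey70"))
  graphics::barplot(tab, col = cols, border = NA,
                    xlab = "Enrichment Score (negative = male)",
                    ylab = "species", ...)
  invisible(x)
}

#' Embryo enrichment comparison between male and female species
#'
#' Computes, per enriched species, the geometric-mean embryo:germline fold
#' over all (own-sex germline library, embryo library) pairs, and tests
#' (i) detection in embryo (raw count > 0 in at least one embryo library)
#' between classes by Pearson chi-square without continuity correction and
#' (ii) the log fold distributions by two-tailed Welch's t-test.
#'
#' @param counts raw count data frame.
#' @param design manifest (must contain embryo libraries).
#' @param fit an `enrichment_fit` for these species.
#' @param pseudocount for the fold ratios (RPM units).
#' @return list with `detection` (2x2 table), `chisq_p`, `welch_p`,
#'   `fold_ratio` (female over male mean embryo fold) and the per-species
#'   fold data frame.
#' @export
embryo_comparison <- function(counts, design, fit, pseudocount = 0.25) {
  rpm <- counts_matrix(normalize_counts(counts, design))
  raw <- counts_matrix(counts)
  emb <- design$id[design$sex == "embryo"]
  if (length(emb) == 0L) stop("design has no embryo libraries")
  r <- fit$results
  keep <- r$classification %in% c("male", "female")
  r <- r[keep, , drop = FALSE]
  folds <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    own <- design$id[design$sex == r$classification[i]]
    x <- rpm[r$species_id[i], , drop = TRUE]
    lf <- outer(x[emb] + pseudocount, x[own] + pseudocount, "/")
    folds[i] <- gmean(as.vector(lf))
  }
  detected <- rowSums(raw[r$species_id, emb, drop = FALSE] > 0) > 0
  detection <- table(class = factor(r$classification,
                                    levels = c("male", "female")),
                     detected = factor(detected,
                                       levels = c(FALSE, TRUE)))
  chisq_p <- if (all(rowSums(detection) > 0) &&
                 all(colSums(detection) > 0))
    stats::chisq.test(detection, correct = FALSE)$p.value else NA_real_
  lm_ <- log(folds[r$classification == "male"])
  lf_ <- log(folds[r$classification == "female"])
  welch <- if (length(lm_) > 1L && length(lf_) > 1L)
    stats::t.test(lf_, lm_) else NULL
  list(detection = detection, chisq_p = chisq_p,
       welch_p = if (is.null(welch)) NA_real_ else welch$p.value,
       fold_ratio = gmean(folds[r$classification == "female"]) /
         gmean(folds[r$classification == "male"]),
       folds = data.frame(species_id = r$species_id,
                          classification = r$classification,
                          embryo_fold = folds, stringsAsFactors = FALSE))
}
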