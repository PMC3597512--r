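# Poisson randomization null for the false discovery rate.
#
# The Enrichment Score has no analytic null, so false discovery is
# estimated by simulation: each species' rate lambda is set to its count
# in a reference library, 17 control libraries of Poisson counts are drawn
# per species, the control libraries are randomly grouped to mirror the
# male/female and protocol structure of the real design, and the standard
# scoring and thresholding are applied. The fraction of (all simulated)
# species classified as enriched, averaged over replicates, estimates the
# FDR. The null deliberately draws raw Poisson counts -- the real analysis
# normalizes, the null does not.

#' Configure the randomization null
#'
#' @param lambda numeric vector of per-species Poisson rates (typically
#'   the species counts in a reference library).
#' @param design library manifest; the germline rows define the label
#'   multiset (sex x protocol) permuted over the control libraries.
#' @param n_reps number of randomization replicates.
#' @param fold_threshold,score_threshold classifier settings.
#' @param seed random seed.
#' @return a `null_simulation_config` list.
#' @export
null_simulation_config <- function(lambda, design = default_design(),
                                   n_reps = 1000L, fold_threshold = 5,
                                   score_threshold = 3L, seed = 1) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  g <- germline_libraries(design)
  structure(list(lambda = lambda, design = design,
                 n_control = nrow(g), n_reps = as.integer(n_reps),
                 fold_threshold = fold_threshold,
                 score_threshold = as.integer(score_threshold),
                 seed = check_seed(seed)),
            class = "null_simulation_config")
}

#' Run the Poisson randomization null
#'
#' @param config a [null_simulation_config()].
#' @return list with `fractions` (classified fraction per replicate, with
#'   all simulated species in the denominator), `mean_fraction`, and the
#'   config. Deterministic given the config seed.
#' @export
#' @examples
#' cfg <- null_simulation_config(lambda = rep(2, 200), n_reps = 50,
#'                               seed = 11)
#' fdr_simulation(cfg)$mean_fraction
fdr_simulation <- function(config) {
  stopifnot(inherits(config, "null_simulation_config"))
  g <- germline_libraries(config$design)
  labels <- paste(g$sex, g$protocol, sep = ".")
  n_lib <- nrow(g)
  n_sp <- length(config$lambda)
  thr <- config$score_threshold
  fold <- config$fold_threshold
  fractions <- numeric(config$n_reps)
  withr_seed(config$seed, {
    for (rep_i in seq_len(config$n_reps)) {
      counts <- matrix(stats::rpois(n_sp * n_lib, config$lambda),
                       nrow = n_sp, ncol = n_lib)
      lab <- sample(labels)          # random grouping of control columns
      score <- integer(n_sp)
      for (prot in unique(g$protocol)) {
        m <- which(lab == paste("male", prot, sep = "."))
        f <- which(lab == paste("female", prot, sep = "."))
        for (mi in m) for (fi in f) {
          cm <- counts[, mi]; cf <- counts[, fi]
          score <- score - (cm > fold * cf) + (cf > fold * cm)
        }
      }
      zero <- rowSums(counts) == 0
      classified <- !zero & abs(score) >= thr
      fractions[rep_i] <- sum(classified) / n_sp
    }
  })
  list(fractions = fractions, mean_fraction = mean(fractions),
       config = config)
}
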