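make_rpm <- function(design, male = 10, female = 1, other = 0) {
  m <- matrix(other, 1, nrow(design), dimnames = list("s1", design$id))
  m[, design$id[design$sex == "male"]] <- male
  m[, design$id[design$sex == "female"]] <- female
  m
}

test_that("count_comparisons sums within-protocol male x female pairs", {
  expect_equal(count_comparisons(default_design()), 23L)
  expect_equal(count_comparisons(design_26g()), 16L)
  one <- data.frame(id = c("m", "f"), sex = c("male", "female"),
                    protocol = "monoP_dependent", genotype = "N2",
                    stage = "germline", total_mapped_reads = 1e6)
  expect_equal(count_comparisons(one), 1L)
  # no female libraries: zero comparisons, and scoring refuses to run
  males <- one[1, ]
  expect_equal(count_comparisons(males), 0L)
  expect_error(enrichment_score(make_rpm(males), males),
               "no male x female comparisons")
})

test_that("enrichment_score applies the strict 5-fold rule per pair", {
  d <- default_design()
  # 10 vs 1 exceeds 5-fold in every one of the 23 comparisons
  expect_equal(enrichment_score(make_rpm(d, 10, 1), d), -23L)
  # identical abundances score zero
  expect_equal(enrichment_score(make_rpm(d, 3, 3), d), 0L)
  # exactly 5-fold does not score (strict inequality)
  expect_equal(enrichment_score(make_rpm(d, 5, 1), d), 0L)
  # zero-vs-positive counts as exceeding any fold; zero-vs-zero is silent
  expect_equal(enrichment_score(make_rpm(d, 0.01, 0), d), -23L)
  expect_equal(enrichment_score(make_rpm(d, 0, 0), d), 0L)
  expect_error(enrichment_score(make_rpm(d, -1, 0), d), "non-negative")
})

test_that("swapping sex labels negates every score exactly", {
  d <- default_design()
  set.seed(41)
  truth <- data.frame(species_id = paste0("u", 1:300),
                      truth_class = sample(c("male", "female",
                                             "non_enriched"), 300, TRUE))
  sim <- simulate_counts(truth, d, seed = 42)
  rpm <- as.matrix(normalize_counts(sim$counts, d)[-1])
  d_swap <- d
  d_swap$sex[d$sex == "male"] <- "female"
  d_swap$sex[d$sex == "female"] <- "male"
  expect_identical(enrichment_score(rpm, d),
                   -enrichment_score(rpm, d_swap))
})

test_that("a library with all-zero counts never changes a score", {
  d <- default_design()
  set.seed(43)
  rpm <- matrix(rexp(100 * nrow(d)), 100, nrow(d),
                dimnames = list(NULL, d$id))
  s0 <- enrichment_score(rpm, d)
  d2 <- rbind(d, data.frame(id = "extra_male", sex = "male",
                            protocol = "monoP_dependent", genotype = "N2",
                            stage = "germline", total_mapped_reads = 1e6))
  rpm2 <- cbind(rpm, extra_male = 0)
  s2 <- enrichment_score(rpm2, d2)
  # new comparisons are 0-vs-x: they only ever favour the female side
  # when x > 0 ... so instead plant zeros on both sides
  rpm3 <- rpm2
  rpm3[, d2$id[d2$sex == "female" & d2$protocol == "monoP_dependent"]] <- 0
  s3a <- enrichment_score(rpm3[, d$id], d)
  s3b <- enrichment_score(rpm3, d2)
  expect_identical(s3a, s3b)   # 0-vs-0 pairs contribute nothing
  expect_true(all(abs(s0) <= count_comparisons(d)))
})

test_that("average_fold is the geometric mean of pairwise ratios", {
  d <- default_design()
  # constant ratio in every pair: the average is that ratio (pseudocount 0)
  f <- average_fold(make_rpm(d, 6.8, 1), d, pseudocount = 0)
  expect_equal(f$avg_fold_male, 6.8)
  expect_equal(f$avg_fold_female, 1 / 6.8)
  f1 <- average_fold(make_rpm(d, 2, 2), d)
  expect_equal(f1$avg_fold_male, 1)
  # random table vs direct recomputation
  set.seed(44)
  rpm <- matrix(rexp(20 * nrow(d)), 20, nrow(d),
                dimnames = list(NULL, d$id))
  got <- average_fold(rpm, d, pseudocount = 0.25)
  g <- d[d$sex %in% c("male", "female"), ]
  want <- apply(rpm, 1, function(x) {
    r <- c()
    for (prot in unique(g$protocol))
      for (mi in g$id[g$protocol == prot & g$sex == "male"])
        for (fi in g$id[g$protocol == prot & g$sex == "female"])
          r <- c(r, (x[mi] + 0.25) / (x[fi] + 0.25))
    exp(mean(log(r)))
  })
  expect_equal(got$avg_fold_male, unname(want))
})

test_that("classify_enrichment applies filters in precedence order", {
  d <- default_design()
  g_ids <- d$id[d$sex %in% c("male", "female")]
  base <- matrix(0, 4, nrow(d), dimnames = list(NULL, d$id))
  counts <- data.frame(species_id = c("male_like", "zero", "mutant",
                                      "flat"), base, check.names = FALSE)
  counts[1, d$id[d$sex == "male"]] <- 100      # clear male
  counts[3, g_ids] <- 50                        # flat but prg-1 dependent?
  counts[3, "prg1_ya"] <- 5; counts[3, "n2_ya"] <- 2  # prg1 > N2: excluded
  counts[4, g_ids] <- 10
  fit <- classify_enrichment(counts, d)
  r <- fit$results
  expect_equal(r$classification,
               c("male", "excluded_zero", "excluded_mutant",
                 "non_enriched"))
  expect_s3_class(fit, "enrichment_fit")
  expect_output(print(fit), "23 male x female comparisons")
  s <- summary(fit)
  expect_equal(s$n, 4L)
  expect_equal(unname(s$classification["male"]), 1L)
})

test_that("score-classified species failing the fold check are reclassified", {
  d <- default_design()
  # 5 scoring male comparisons (dep group) against 18 sub-threshold but
  # female-leaning indep comparisons: the score reaches -5 while the
  # pseudocounted average fold tips female
  m <- matrix(0, 1, nrow(d), dimnames = list("s", d$id))
  m[, paste0("dep_male_", 1:5)] <- 1
  m[, "dep_female_1"] <- 0.15
  m[, paste0("indep_male_", 1:9)] <- 0.05
  m[, paste0("indep_female_", 1:2)] <- 0.25
  sc <- enrichment_score(m, d)
  expect_lte(sc, -3L)
  counts <- data.frame(species_id = "s", m, check.names = FALSE)
  fit <- classify_enrichment(counts, d, abundances = counts)
  expect_equal(fit$results$classification, "non_enriched")
  expect_true(fit$results$reclassified)
})

test_that("embryo comparison recovers planted female carryover", {
  # shallow embryo detection regime: weakly expressed species so that
  # male species are often undetected in embryo while carried-over
  # female species are seen
  d <- default_design(depth = 1e5)
  truth <- data.frame(species_id = paste0("u", 1:600),
                      truth_class = rep(c("male", "female"), each = 300))
  sim <- simulate_counts(truth, d,
                         expression_model(baseline_log_mean = log(5),
                                          baseline_log_sd = 0.5,
                                          embryo_carryover = 4),
                         seed = 46)
  fit <- classify_enrichment(sim$counts, d)
  emb <- embryo_comparison(sim$counts, d, fit)
  # female species carry ~4x into embryo relative to male species --
  # male species are also diluted by their male-library enrichment, so
  # the ratio recovered is >= the planted carryover
  expect_gt(emb$fold_ratio, 2.5)
  expect_lt(emb$chisq_p, 0.01)
  expect_lt(emb$welch_p, 0.01)
  # female class more often detected in embryo
  det <- prop.table(emb$detection, 1)
  expect_gt(det["female", "TRUE"], det["male", "TRUE"])
})

test_that("Welch's t-test matches the textbook formula", {
  set.seed(47)
  x <- rnorm(40, 1, 2); y <- rnorm(25, 0, 1)
  want <- oracle_welch(x, y)
  got <- t.test(x, y)
  expect_equal(unname(got$statistic), want$t)
  expect_equal(unname(got$parameter), want$df)
  expect_equal(got$p.value, want$p)
})

test_that("the engine reuses cleanly for the 26G design", {
  d26 <- design_26g()
  expect_equal(count_comparisons(d26), 16L)
  expect_equal(enrichment_score(make_rpm(d26, 10, 1), d26), -16L)
  expect_identical(enrichment_score(make_rpm(d26, 1, 10), d26),
                   -enrichment_score(make_rpm(d26, 10, 1), d26))
})
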