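test_that("find_targets equals the sliding Hamming oracle", {
  set.seed(91)
  tx <- setNames(vapply(1:5, function(i) random_seq(2000),
                        character(1)), paste0("tx", 1:5))
  u21 <- setNames(vapply(1:4, function(i)
    paste0("T", random_seq(20)), character(1)), paste0("u", 1:4))
  # plant one exact site so the scan has guaranteed structure
  s <- tx[[2]]
  substr(s, 500, 520) <- revcomp(u21[[1]])
  tx[[2]] <- s
  got <- find_targets(u21, tx, max_mismatches = 3)
  got <- got[order(got$source_21u, got$transcript_id, got$start), ]
  want <- oracle_find_targets(u21, tx, max_mm = 3)
  want <- want[order(want$source_21u, want$transcript_id, want$start), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  # the planted site is a 0-mismatch hit at the planted coordinate
  expect_true(any(got$source_21u == "u1" & got$transcript_id == "tx2" &
                    got$start == 500 & got$n_mismatches == 0))
  # a 4-mismatch site is absent at threshold 3
  s4 <- revcomp(u21[[2]])
  for (p in c(2, 7, 12, 18))
    substr(s4, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(s4, p, p))[1]
  tx2 <- c(txX = paste0(random_seq(100), s4, random_seq(100)))
  f4 <- find_targets(u21["u2"], tx2, max_mismatches = 3)
  expect_false(any(f4$start == 101))
})

test_that("22G attribution honours the 40-nt rule, classes and prg-1", {
  sites <- data.frame(transcript_id = "tx1",
                      start = c(100L, 400L, 300L),
                      end = c(120L, 420L, 320L),
                      source_21u = c("m1", "f1", "m3"),
                      n_mismatches = 0L,
                      class = c("male", "female", "male"))
  g22 <- data.frame(
    species_22g = c("overlap_m", "gap41", "between", "prg1_hit",
                    "far"),
    transcript_id = "tx1",
    start = c(110L, 462L, 350L, 130L, 1500L),
    end = c(131L, 483L, 371L, 151L, 1521L),
    counts_wt = 5L,
    counts_prg1 = c(0L, 0L, 0L, 2L, 0L))
  att <- attribute_22g(g22, sites, distance = 40L)
  expect_equal(att$attributed_to[att$species_22g == "overlap_m"],
               "male_only")
  # footprint gap of exactly 41 nt misses the 40-nt rule
  expect_equal(att$min_gap[att$species_22g == "gap41"], 41L)
  expect_equal(att$attributed_to[att$species_22g == "gap41"], "none")
  # within 40 nt of a male and a female site: ambiguous
  expect_equal(att$attributed_to[att$species_22g == "between"],
               "ambiguous")
  # prg-1-detected species are excluded regardless of proximity
  expect_equal(att$attributed_to[att$species_22g == "prg1_hit"], "none")
  expect_true(att$prg1_detected[att$species_22g == "prg1_hit"])
  expect_equal(att$attributed_to[att$species_22g == "far"], "none")
})

test_that("attribution is monotone in the distance threshold", {
  sites <- data.frame(transcript_id = "tx1", start = 100L, end = 120L,
                      source_21u = "m1", n_mismatches = 0L,
                      class = "male")
  g22 <- data.frame(species_22g = paste0("g", 1:30),
                    transcript_id = "tx1",
                    start = 120L + seq(0, 145, 5), counts_wt = 1L,
                    counts_prg1 = 0L)
  g22$end <- g22$start + 21L
  prev <- rep(FALSE, nrow(g22))
  for (dist in c(0L, 10L, 40L, 80L, 200L)) {
    att <- attribute_22g(g22, sites, distance = dist)
    now <- att$attributed_to == "male_only"
    expect_true(all(now | !prev))   # once attributed, stays attributed
    prev <- now
  }
})

test_that("boundary constructions from the generator behave at 40/41 nt", {
  g <- generate_genome(1, 20000, 0.36, seed = 92)
  pl <- plant_cassettes(g, list(cassette_spec("male"),
                                cassette_spec("female")), seed = 93)
  plan <- data.frame(locus_id = pl$loci$locus_id,
                     transcript = c(1L, 2L), pos = c(200L, 200L),
                     mismatches = 0L, g22_gaps = c("40", "41"))
  tr <- simulate_transcriptome_and_22g(pl$loci, n_transcripts = 2,
                                       target_plan = plan, seed = 94)
  sites <- tr$sites
  sites$class <- sites$truth_class
  att <- attribute_22g(tr$g22, sites)
  id40 <- tr$g22$species_22g[which(tr$g22$truth_gap == 40)]
  id41 <- tr$g22$species_22g[which(tr$g22$truth_gap == 41)]
  at40 <- att[att$species_22g == id40, ]
  at41 <- att[att$species_22g == id41, ]
  expect_equal(at40$attributed_to, "male_only")
  expect_equal(at41$attributed_to, "none")
  # background species are prg-1 detected, hence never attributed
  bg <- att[att$species_22g %in%
              tr$g22$species_22g[tr$g22$truth_class == "background"], ]
  expect_true(all(bg$attributed_to == "none"))
})

test_that("overlap randomization is reproducible and sees planted structure", {
  g <- generate_genome(1, 90000, 0.36, seed = 95)
  specs <- c(lapply(1:12, function(i) cassette_spec("male")),
             lapply(1:12, function(i) cassette_spec("female")))
  pl <- plant_cassettes(g, specs, seed = 96)
  # same-class 21U pairs share a transcript with one 22G within 40 nt of
  # both sites; male pairs on tx 1..6, female pairs on tx 7..12, so the
  # observed both-class count is 0 while random label draws mix pairs
  males <- which(pl$loci$truth_class == "male")
  females <- which(pl$loci$truth_class == "female")
  pair_of <- function(idx, tx0) {
    k <- length(idx) %/% 2L
    data.frame(locus_id = pl$loci$locus_id[idx[seq_len(2L * k)]],
               transcript = rep(tx0 + seq_len(k) - 1L, each = 2L),
               pos = rep(c(300L, 335L), k),
               mismatches = 0L,
               g22_gaps = rep(c("5", ""), k),
               stringsAsFactors = FALSE)
  }
  plan <- rbind(pair_of(males, 1L), pair_of(females, 7L))
  tr <- simulate_transcriptome_and_22g(pl$loci, n_transcripts = 12,
                                       transcript_length = 1800,
                                       target_plan = plan,
                                       prg1_background = 0, seed = 97)
  u21 <- setNames(pl$loci$sequence, pl$loci$locus_id)
  classes <- setNames(pl$loci$truth_class, pl$loci$locus_id)
  res <- overlap_randomization(u21, classes, tr$transcripts, tr$g22,
                               n_reps = 100, seed = 98)
  # planted disjoint targeting: observed both-count below the 2.5th
  # percentile of the random distribution
  expect_equal(res$observed, 0)
  expect_lt(res$observed, unname(res$quantiles[1]))
  # determinism
  res2 <- overlap_randomization(u21, classes, tr$transcripts, tr$g22,
                                n_reps = 100, seed = 98)
  expect_identical(res$random, res2$random)
  # shared-gene statistic runs on the same inputs
  resg <- overlap_randomization(u21, classes, tr$transcripts, tr$g22,
                                n_reps = 20, seed = 99,
                                statistic = "shared_genes")
  expect_equal(resg$observed, 0)
})

test_that("gene-set randomization flags planted depletion and nulls", {
  set.seed(100)
  universe <- paste0("gene", 1:500)
  category <- paste0("gene", 1:100)
  # targets avoid the category entirely
  targets <- paste0("gene", 301:420)
  res <- geneset_enrichment(targets, category, universe,
                            n_random = 300, seed = 101)
  expect_equal(res$observed, 0)
  expect_equal(res$direction, "depleted")
  expect_lt(res$chisq_p, 0.01)
  # a random category shows no signal
  res0 <- geneset_enrichment(sample(universe, 120), category, universe,
                             n_random = 300, seed = 102)
  expect_gt(res0$chisq_p, 0.001)
  expect_error(geneset_enrichment(targets, character(0), universe),
               "empty")
})
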