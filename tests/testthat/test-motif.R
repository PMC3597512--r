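test_that("scan_upstream recovers planted cassettes exactly", {
  g <- generate_genome(2, c(30000, 30000), 0.36, seed = 51)
  specs <- random_cassette_specs(40, seed = 52)
  pl <- plant_cassettes(g, specs, seed = 53)
  calls <- scan_upstream(pl$loci, pl$genome)
  expect_true(all(calls$has_gtttc))
  expect_equal(calls$spacer_length, pl$loci$spacer)
  expect_equal(calls$motif_key, pl$loci$motif_key)
  # the 5' nt class matches each cassette's planted motif
  want_5p <- pl$motifs$five_prime_class[pl$loci$cassette_id]
  expect_equal(calls$five_prime_nt, want_5p)
  expect_true(all(calls$in_canonical_range ==
                    (pl$loci$spacer >= 35 & pl$loci$spacer <= 42)))
})

test_that("no GTTTC in the window gives the -44 fallback anchor", {
  g <- c(chr1 = paste0(strrep("A", 200), "T", random_seq(40, seed = 54),
                       strrep("A", 800)))
  loci <- data.frame(locus_id = "x", chrom = "chr1", strand = "+",
                     pos5 = 201L)
  call <- scan_upstream(loci, g)
  expect_false(call$has_gtttc)
  expect_equal(call$five_prime_nt, "NM")
  expect_true(is.na(call$spacer_length))
  expect_equal(call$gtttc_start, 201L - 44L)

  # chromosome edge with < 8 nt upstream: no-motif, truncation flagged
  edge <- data.frame(locus_id = "e", chrom = "chr1", strand = "+",
                     pos5 = 5L)
  ce <- scan_upstream(edge, g)
  expect_false(ce$has_gtttc)
  expect_true(ce$window_truncated)
})

test_that("among several GTTTC hits the spacer closest to 39 wins", {
  # place GTTTC at spacers 36 and 50 upstream of a T
  u <- strrep("A", 70)
  place <- function(u, spacer) {
    # G of GTTTC sits spacer+6 upstream of the T at position 71
    p <- 71 - (spacer + 6)
    substr(u, p, p + 4) <- "GTTTC"
    u
  }
  u <- place(place(u, 36), 50)
  g <- c(chr1 = paste0(strrep("C", 30), u, "T", random_seq(25, seed = 55),
                       strrep("C", 900)))
  loci <- data.frame(locus_id = "y", chrom = "chr1", strand = "+",
                     pos5 = 101L)
  call <- scan_upstream(loci, g)
  expect_equal(call$spacer_length, 36L)
  # selection is configurable
  expect_equal(scan_upstream(loci, g, select = "leftmost")$spacer_length,
               50L)
  expect_equal(scan_upstream(loci, g, select = "rightmost")$spacer_length,
               36L)
  # ties go to the shorter spacer: 36 and 42 are equidistant from 39
  # (chosen non-overlapping: the 5-mers must not collide)
  u2 <- place(place(strrep("A", 70), 36), 42)
  g2 <- c(chr1 = paste0(strrep("C", 30), u2, "T",
                        random_seq(25, seed = 56), strrep("C", 900)))
  expect_equal(scan_upstream(data.frame(locus_id = "z", chrom = "chr1",
                                        strand = "+", pos5 = 101L),
                             g2)$spacer_length, 36L)
})

test_that("scan_upstream equals the brute-force enumeration on random loci", {
  g <- generate_genome(1, 60000, 0.45, seed = 57)  # GC-rich: many GTTTC
  set.seed(58)
  pos <- sample(200:59000, 500)
  loci <- data.frame(locus_id = paste0("l", seq_along(pos)),
                     chrom = "chr1",
                     strand = sample(c("+", "-"), length(pos), TRUE),
                     pos5 = pos)
  calls <- scan_upstream(loci, g)
  for (i in seq_len(nrow(loci))) {
    want <- oracle_scan_upstream(loci[i, ], g)
    expect_identical(calls$has_gtttc[i], want$has_gtttc, info = i)
    expect_identical(calls$spacer_length[i], want$spacer_length,
                     info = i)
    if (want$has_gtttc) {
      expect_identical(calls$five_prime_nt[i], want$five_prime_nt,
                       info = i)
      expect_identical(calls$core_8mer[i], want$core_8mer, info = i)
    }
  }
})

test_that("motif calls are invariant under genome reverse complement", {
  g <- generate_genome(1, 20000, 0.4, seed = 59)
  pl <- plant_cassettes(g, random_cassette_specs(10, seed = 60), seed = 61)
  calls <- scan_upstream(pl$loci, pl$genome)
  L <- nchar(pl$genome[[1]])
  g_rc <- c(chr1 = revcomp(pl$genome[[1]]))
  loci_rc <- pl$loci
  loci_rc$pos5 <- L - pl$loci$pos5 + 1L
  loci_rc$strand <- ifelse(pl$loci$strand == "+", "-", "+")
  calls_rc <- scan_upstream(loci_rc, g_rc)
  expect_equal(calls_rc$has_gtttc, calls$has_gtttc)
  expect_equal(calls_rc$spacer_length, calls$spacer_length)
  expect_equal(calls_rc$five_prime_nt, calls$five_prime_nt)
  expect_equal(calls_rc$core_8mer, calls$core_8mer)
})

test_that("classify_motifs cross-tabulates and rejects degenerate tables", {
  g <- generate_genome(1, 80000, 0.36, seed = 62)
  specs <- random_cassette_specs(60, seed = 63)
  pl <- plant_cassettes(g, specs, seed = 64)
  calls <- scan_upstream(pl$loci, pl$genome)
  cls <- data.frame(locus_id = pl$loci$locus_id,
                    classification = pl$loci$truth_class)
  cm <- classify_motifs(calls, cls)
  expect_true(all(rownames(cm$table) %in%
                    c("male", "female", "non_enriched")))
  expect_equal(sum(cm$table), nrow(pl$loci))
  expect_true(cm$chisq_p >= 0 && cm$chisq_p <= 1)
  # degenerate: one class, one motif category
  deg_calls <- calls[pl$loci$truth_class == "male", ][1:3, ]
  deg_calls$five_prime_nt <- "C"
  expect_error(classify_motifs(deg_calls,
                               cls[cls$classification == "male", ]),
               "degenerate")
})

test_that("abundance by motif class finds a planted 5'-C effect", {
  d <- default_design()
  set.seed(65)
  n <- 400
  five <- sample(c("C", "A", "G", "T"), n, TRUE)
  calls <- data.frame(locus_id = paste0("u", 1:n), five_prime_nt = five)
  dep_libs <- d$id[d$protocol == "monoP_dependent" & d$sex == "male"]
  rpm <- data.frame(species_id = calls$locus_id,
                    matrix(rexp(n * nrow(d),
                                rate = ifelse(five == "C", 0.25, 1)),
                           n, nrow(d), dimnames = list(NULL, d$id)),
                    check.names = FALSE)
  res <- abundance_by_motif_class(calls, rpm, dep_libs)
  expect_equal(sort(res$stats$five_prime_nt), sort(unique(five)))
  expect_true(all(res$welch_p["C", c("A", "G", "T")] < 0.01))
  # a single-member class is excluded from testing with NA SEM
  calls2 <- calls; calls2$five_prime_nt[1] <- "NM"
  calls2$five_prime_nt[-1][calls2$five_prime_nt[-1] == "NM"] <- "A"
  res2 <- abundance_by_motif_class(calls2, rpm, dep_libs)
  expect_true(is.na(res2$stats$sem[res2$stats$five_prime_nt == "NM"]))
  expect_false("NM" %in% rownames(res2$welch_p))
})

test_that("motif_matrix reproduces hand-computed relative entropy", {
  # four identical windows: information content is -log2(q_b) of the
  # observed base at each position
  g <- c(chr1 = paste0(strrep("ACGT", 250)))  # uniform background
  calls <- data.frame(locus_id = paste0("w", 1:4), has_gtttc = TRUE,
                      gtttc_start = c(101, 201, 301, 401))
  loci <- data.frame(locus_id = paste0("w", 1:4), chrom = "chr1",
                     strand = "+", pos5 = c(146, 246, 346, 446))
  mm <- motif_matrix(calls, loci, g, upstream = 2, downstream = 2)
  expect_equal(mm$n_windows, 4L)
  expect_true(all(abs(rowSums(mm$freq) - 1) < 1e-9))
  # all windows identical and background uniform: 2 bits everywhere
  expect_equal(unname(mm$bits), rep(2, 5))

  # hand-built 4-window toy set against hand-computed relative entropy
  g2 <- c(chr1 = paste0(strrep("A", 400), strrep("C", 100),
                        strrep("G", 100), strrep("T", 400)))
  # windows: AAAA/AAAC-style columns via four anchors in the A and C runs
  calls2 <- data.frame(locus_id = paste0("x", 1:4), has_gtttc = TRUE,
                       gtttc_start = c(50, 100, 150, 499))
  loci2 <- data.frame(locus_id = paste0("x", 1:4), chrom = "chr1",
                      strand = "+", pos5 = c(95, 145, 195, 544))
  mm2 <- motif_matrix(calls2, loci2, g2, upstream = 0, downstream = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25))
  # column 1: three A (gtttc_start+1 = 51, 101, 151) and one C (500)
  f <- c(0.75, 0.25)
  want_bits <- sum(f * log2(f / 0.25))
  expect_equal(unname(mm2$bits[1]), want_bits)
})

test_that("uniform random windows carry ~zero information", {
  g <- generate_genome(1, 50000, 0.5, seed = 66)
  set.seed(67)
  anchors <- sample(100:49000, 300)
  calls <- data.frame(locus_id = paste0("r", seq_along(anchors)),
                      has_gtttc = TRUE, gtttc_start = anchors)
  loci <- data.frame(locus_id = calls$locus_id, chrom = "chr1",
                     strand = "+", pos5 = anchors + 45L)
  mm <- motif_matrix(calls, loci, g, upstream = 5, downstream = 5)
  expect_lt(max(mm$bits), 0.05)
})

test_that("kmer_density counts overlapping occurrences on both strands", {
  # 1 kb with 4 forward GTTTC and nothing on the reverse strand
  s <- strrep("A", 1000)
  for (p in c(101, 301, 501, 701)) substr(s, p, p + 4) <- "GTTTC"
  g <- c(chr1 = s)
  reg <- data.frame(chrom = "chr1", start = 1, end = 1000)
  expect_equal(kmer_density(g, reg), 4.0)
  # poly-A region: zero
  expect_equal(kmer_density(c(chr1 = strrep("A", 1000)), reg), 0)
  # overlapping occurrences both count: GTTTCGTTTC has two
  s2 <- paste0("GTTTCGTTTC", strrep("A", 990))
  expect_equal(kmer_density(c(chr1 = s2), reg), 2.0)
  # reverse-strand occurrences count too
  s3 <- paste0(revcomp("GTTTC"), strrep("A", 995))
  expect_equal(kmer_density(c(chr1 = s3), reg), 1.0)
  expect_equal(kmer_density(c(chr1 = s3), reg, both_strands = FALSE), 0)
})
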