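# Synthetic-data generators.
#
# Every downstream stage of the pipeline is exercised on data generated
# here with known truth: genomes with planted core-motif/21U cassettes,
# multi-library negative-binomial counts with configurable male/female
# fold enrichment, linkered raw reads, transcripts with planted target
# sites and antisense 22G reads, and per-nucleotide signal tracks. All
# generators are pure functions of their arguments and a seed.
#
# Cassette geometry (strand space, 1-based offsets within the cassette):
# a 62-nt A/T-only upstream flank, the 8-nt core motif, then the spacer.
# With the motif 8-mer at offsets 63..70, a 21U locus with spacer s starts
# its 5' T at offset 71 + s, so that exactly s nucleotides lie strictly
# between the motif 3' end and the T. Thymidines at spacers 35-42 form the
# "optimal window"; planting several of them yields a minicluster sharing
# one motif.

CASSETTE_FLANK <- 62L
SPACER_WINDOW <- 35:42

#' Generate a random genome
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector (length `n_chrom`) of chromosome lengths,
#'   each >= 1000.
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed random seed.
#' @return named character vector of chromosome sequences (`chr1`, ...).
#' @export
#' @examples
#' g <- generate_genome(1, 5000, gc_fraction = 0.36, seed = 7)
generate_genome <- function(n_chrom, lengths, gc_fraction = 0.36, seed = 1) {
  seed <- check_seed(seed)
  if (length(lengths) == 1L) lengths <- rep(lengths, n_chrom)
  if (length(lengths) != n_chrom)
    stop("'lengths' must have one entry per chromosome")
  if (any(lengths < 1L)) stop("chromosome lengths must be positive")
  if (any(lengths < 1000L)) stop("chromosome lengths must be >= 1 kb")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  withr_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
  })
  stats::setNames(seqs, paste0("chr", seq_len(n_chrom)))
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specify a 21U cassette to plant
#'
#' @param truth_class `"male"`, `"female"` or `"non_enriched"`; the known
#'   enrichment class of every locus expressed from this cassette.
#' @param motif_8mer the 8-nt core motif to plant (canonical consensus
#'   `CTGTTTCA`; positions 3-7 must be `GTTTC` for the cassette to be
#'   recoverable by the scanner).
#' @param spacer_length spacer (nt strictly between motif 3' end and the
#'   21U 5' T) of the primary locus, support 30-50.
#' @param n_window_Ts number of thymidines (1-8) planted at spacer
#'   distances 35-42; values > 1 create miniclusters. Only used when
#'   `spacer_length` falls in 35-42 (the primary T then counts as one of
#'   them); otherwise a single locus at `spacer_length` is planted.
#' @param strand `"+"` or `"-"`.
#' @return a `cassette_spec` list.
#' @export
cassette_spec <- function(truth_class = c("male", "female", "non_enriched"),
                          motif_8mer = "CTGTTTCA", spacer_length = 39L,
                          n_window_Ts = 1L, strand = "+") {
  truth_class <- match.arg(truth_class)
  check_dna(motif_8mer, "motif_8mer", allow_n = FALSE)
  if (nchar(motif_8mer) != 8L) stop("motif_8mer must be 8 nt")
  if (spacer_length < 0L) stop("spacer_length must be >= 0")
  if (spacer_length < 30L || spacer_length > 50L)
    stop("spacer_length must lie in 30-50")
  if (n_window_Ts < 1L || n_window_Ts > 8L)
    stop("n_window_Ts must lie in 1-8")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(truth_class = truth_class, motif_8mer = motif_8mer,
                 five_prime_class = substr(motif_8mer, 1L, 1L),
                 spacer_length = as.integer(spacer_length),
                 n_window_Ts = as.integer(n_window_Ts), strand = strand),
            class = "cassette_spec")
}

#' Draw a realistic random set of cassette specs
#'
#' Class proportions default to the observed composite-dataset breakdown
#' (56% male, 16% female, 28% non-enriched); male motifs carry a 5'
#' cytidine at 77%, female and non-enriched motifs at ~21%; spacers are
#' drawn from a discrete distribution over 30-50 peaked at 39 nt; about a
#' third of cassettes plant 2-3 window thymidines (miniclusters).
#'
#' @param n number of cassettes.
#' @param seed random seed.
#' @param class_probs named probabilities over male/female/non_enriched.
#' @param minicluster_prob probability of planting more than one window T.
#' @return list of [cassette_spec()] objects.
#' @export
random_cassette_specs <- function(n, seed = 1,
                                  class_probs = c(male = 0.56,
                                                  female = 0.16,
                                                  non_enriched = 0.28),
                                  minicluster_prob = 0.3) {
  seed <- check_seed(seed)
  five_probs <- list(
    male = c(C = 0.77, A = 0.09, G = 0.07, T = 0.07),
    female = c(C = 0.21, A = 0.40, G = 0.19, T = 0.20),
    non_enriched = c(C = 0.21, A = 0.40, G = 0.19, T = 0.20))
  spacer_support <- 30:50
  spacer_probs <- stats::dnorm(spacer_support, mean = 39, sd = 2)
  spacer_probs <- spacer_probs / sum(spacer_probs)
  withr_seed(seed, {
    classes <- sample(names(class_probs), n, replace = TRUE,
                      prob = class_probs)
    specs <- lapply(seq_len(n), function(i) {
      cls <- classes[i]
      fp <- sample(names(five_probs[[cls]]), 1L,
                   prob = five_probs[[cls]])
      spacer <- sample(spacer_support, 1L, prob = spacer_probs)
      nT <- if (spacer %in% SPACER_WINDOW &&
                stats::runif(1) < minicluster_prob)
        sample(2:3, 1L) else 1L
      cassette_spec(cls, motif_8mer = paste0(fp, "TGTTTCA"),
                    spacer_length = spacer, n_window_Ts = nT,
                    strand = sample(c("+", "-"), 1L))
    })
  })
  specs
}

# build one cassette string in strand space plus locus bookkeeping
.build_cassette <- function(spec) {
  s0 <- spec$spacer_length
  spacers <- if (s0 %in% SPACER_WINDOW && spec$n_window_Ts > 1L)
    sort(c(s0, sample(setdiff(SPACER_WINDOW, s0),
                      spec$n_window_Ts - 1L))) else s0
  s_max <- max(spacers)
  len <- CASSETTE_FLANK + 8L + s_max + 21L
  chars <- sample(DNA_BASES, len, replace = TRUE)
  # A/T-only upstream flank: no GTTTC can precede the planted motif
  chars[1:CASSETTE_FLANK] <- sample(c("A", "T"), CASSETTE_FLANK,
                                    replace = TRUE, prob = c(0.6, 0.4))
  chars[(CASSETTE_FLANK + 1L):(CASSETTE_FLANK + 8L)] <-
    strsplit(spec$motif_8mer, "", fixed = TRUE)[[1L]]
  # spacer: A-fill (no G or C, so no spurious GTTTC between motif and T);
  # a T with spacer s sits at offset flank + 8 + s + 1, leaving exactly s
  # nt strictly between the 8mer 3' end and the T
  spacer_pos <- (CASSETTE_FLANK + 9L):(CASSETTE_FLANK + 8L + s_max)
  chars[spacer_pos] <- "A"
  # optimal-window positions: T where planted, A otherwise
  wpos <- CASSETTE_FLANK + 9L + SPACER_WINDOW
  wpos <- wpos[wpos <= len]
  chars[wpos] <- "A"
  t_off <- CASSETTE_FLANK + 9L + spacers
  chars[t_off] <- "T"
  # 21U bodies downstream of the last constrained position: random, but
  # G/C-free until past the last planted T to keep member windows clean
  body_from <- max(c(wpos, t_off)) + 1L
  if (body_from <= len)
    chars[body_from:len] <- sample(DNA_BASES, len - body_from + 1L,
                                   replace = TRUE)
  list(seq = paste(chars, collapse = ""), spacers = spacers,
       t_offsets = t_off, motif_offset = CASSETTE_FLANK + 1L, len = len)
}

#' Plant 21U cassettes in a genome
#'
#' Cassettes are written left to right on each chromosome (alternating as
#' needed across chromosomes) separated by at least `min_separation` nt of
#' untouched genome. Minus-strand cassettes are written as the reverse
#' complement of the strand-space construction, so the core 8-mer appears
#' reverse-complemented on the forward genome string.
#'
#' @param genome named character vector (as from [generate_genome()]).
#' @param specs list of [cassette_spec()] objects.
#' @param min_separation minimum gap (nt) between cassette footprints.
#' @param seed random seed (controls extra window-T placement and gaps).
#' @return list with `genome` (edited), `loci` (truth data frame: one row
#'   per planted 21U locus with 1-based inclusive forward coordinates,
#'   strand, `pos5` (forward coordinate of the 5' T), 21-nt `sequence` in
#'   strand space, `spacer`, `truth_class`, `cassette_id`, and the shared
#'   `motif_key`), and `motifs` (one row per cassette).
#' @export
plant_cassettes <- function(genome, specs, min_separation = 60L, seed = 1) {
  seed <- check_seed(seed)
  if (inherits(specs, "cassette_spec")) specs <- list(specs)
  withr_seed(seed, {
    built <- lapply(specs, .build_cassette)
    chrom_names <- names(genome)
    chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
    cursor <- stats::setNames(rep(1L, length(genome)), chrom_names)
    ci <- 1L
    loci <- list(); motifs <- list()
    for (i in seq_along(specs)) {
      spec <- specs[[i]]; b <- built[[i]]
      gap <- min_separation + sample.int(min_separation, 1L)
      placed <- FALSE
      for (k in seq_along(chrom_names)) {
        ch <- chrom_names[ci]
        start <- cursor[ch] + gap
        if (start + b$len - 1L <= length(chars[[ch]])) {
          placed <- TRUE
          break
        }
        ci <- ci %% length(chrom_names) + 1L
      }
      if (!placed)
        stop(sprintf("insufficient genome space for cassette %d (%s)",
                     i, spec$truth_class))
      cass_seq <- if (spec$strand == "+") b$seq else revcomp(b$seq)
      chars[[ch]][start:(start + b$len - 1L)] <-
        strsplit(cass_seq, "", fixed = TRUE)[[1L]]
      cursor[ch] <- start + b$len
      # strand-space offset -> forward coordinate
      o2f <- if (spec$strand == "+") function(o) start + o - 1L else
        function(o) start + b$len - o
      pos5 <- vapply(b$t_offsets, o2f, integer(1))
      lstart <- if (spec$strand == "+") pos5 else pos5 - 20L
      lend <- if (spec$strand == "+") pos5 + 20L else pos5
      m_start_f <- o2f(b$motif_offset)         # fwd coord of 8mer 1st base
      gtttc_f <- o2f(b$motif_offset + 2L)      # fwd coord of the G
      loci[[i]] <- data.frame(
        locus_id = sprintf("u%04d_%d", i, seq_along(pos5)),
        chrom = ch, start = lstart, end = lend, strand = spec$strand,
        pos5 = pos5, spacer = b$spacers, truth_class = spec$truth_class,
        cassette_id = i,
        motif_key = sprintf("%s:%s:%d", ch, spec$strand, gtttc_f),
        stringsAsFactors = FALSE)
      motifs[[i]] <- data.frame(
        cassette_id = i, chrom = ch, strand = spec$strand,
        motif_start = m_start_f, motif_8mer = spec$motif_8mer,
        five_prime_class = spec$five_prime_class,
        n_loci = length(pos5), truth_class = spec$truth_class,
        stringsAsFactors = FALSE)
    }
    genome_out <- stats::setNames(
      vapply(chars, paste, character(1), collapse = ""), chrom_names)
  })
  loci <- do.call(rbind, loci)
  # read each locus sequence back from the edited genome
  loci$sequence <- vapply(seq_len(nrow(loci)), function(j)
    subseq_strand(genome_out, loci$chrom[j], loci$start[j], loci$end[j],
                  loci$strand[j]), character(1))
  stopifnot(all(substr(loci$sequence, 1L, 1L) == "T"))
  list(genome = genome_out, loci = loci, motifs = do.call(rbind, motifs))
}

#' Expression model for simulated counts
#'
#' @param baseline_log_mean,baseline_log_sd log-scale parameters of the
#'   per-species baseline abundance (RPM).
#' @param sex_fold_male,sex_fold_female fold enrichment of male-truth
#'   species in male libraries and female-truth species in female
#'   libraries (both >= 1; defaults 8 and 4, mirroring the asymmetry of
#'   observed male vs female enrichment).
#' @param dispersion negative-binomial overdispersion (variance = mu +
#'   dispersion * mu^2); `0` gives Poisson sampling.
#' @param embryo_carryover abundance multiplier for female-truth species
#'   in embryo libraries (maternal piRNA inheritance).
#' @param prg1_depletion multiplier applied to all species in prg-1
#'   mutant libraries (piRNAs require prg-1).
#' @param spacer_effect optional `function(spacer) -> multiplier`
#'   expressing the spacer-length dependence of abundance.
#' @return an `expression_model` list.
#' @export
expression_model <- function(baseline_log_mean = log(50),
                             baseline_log_sd = 1,
                             sex_fold_male = 8, sex_fold_female = 4,
                             dispersion = 0.1, embryo_carryover = 4,
                             prg1_depletion = 0.05,
                             spacer_effect = NULL) {
  if (sex_fold_male < 1 || sex_fold_female < 1)
    stop("sex_fold must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 sex_fold_male = sex_fold_male,
                 sex_fold_female = sex_fold_female,
                 dispersion = dispersion,
                 embryo_carryover = embryo_carryover,
                 prg1_depletion = prg1_depletion,
                 spacer_effect = spacer_effect),
            class = "expression_model")
}

#' Simulate per-library raw counts with known enrichment truth
#'
#' Each species receives a log-normal baseline abundance (RPM scale). Its
#' expected abundance is multiplied by `sex_fold_male` in male libraries
#' when its truth class is male, by `sex_fold_female` in female libraries
#' when female, by `embryo_carryover` in embryo libraries when female, and
#' by `prg1_depletion` in prg-1 mutant libraries. Raw counts are drawn
#' negative-binomially at the depth of each library.
#'
#' @param truth data frame with columns `locus_id` (or `species_id`) and
#'   `truth_class`; a `spacer` column is used when the model has a
#'   `spacer_effect`.
#' @param design library manifest (see [default_design()]).
#' @param model an [expression_model()].
#' @param seed random seed.
#' @return list with `counts` (data frame: `species_id` + one raw-count
#'   column per library) and `truth` (the input truth, with the baseline
#'   added).
#' @export
simulate_counts <- function(truth, design = default_design(),
                            model = expression_model(), seed = 1) {
  seed <- check_seed(seed)
  validate_design(design)
  ids <- truth$species_id %||% truth$locus_id
  n <- length(ids)
  cls <- truth$truth_class
  withr_seed(seed, {
    baseline <- exp(stats::rnorm(n, model$baseline_log_mean,
                                 model$baseline_log_sd))
    if (!is.null(model$spacer_effect)) {
      if (is.null(truth$spacer))
        stop("spacer_effect given but truth has no 'spacer' column")
      baseline <- baseline * vapply(truth$spacer, model$spacer_effect,
                                    numeric(1))
    }
    mat <- matrix(0L, n, nrow(design),
                  dimnames = list(ids, design$id))
    for (j in seq_len(nrow(design))) {
      lib <- design[j, ]
      fold <- rep(1, n)
      if (lib$sex == "male") fold[cls == "male"] <- model$sex_fold_male
      if (lib$sex == "female") fold[cls == "female"] <- model$sex_fold_female
      if (lib$sex == "embryo")
        fold[cls == "female"] <- model$embryo_carryover
      if (grepl("prg-1", lib$genotype)) fold <- fold * model$prg1_depletion
      mu <- baseline * fold * lib$total_mapped_reads / 1e6
      mat[, j] <- if (model$dispersion == 0) stats::rpois(n, mu) else
        stats::rnbinom(n, mu = mu, size = 1 / model$dispersion)
    }
  })
  truth$baseline <- baseline
  counts <- data.frame(species_id = ids, mat, check.names = FALSE,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Emit linkered raw reads for planted loci
#'
#' Each read is a 21-nt insert followed by the full linker (probability
#' `p_full`), a linker prefix truncated to 3-5 nt (`p_trunc`), or no
#' linker at all (`p_absent`; such reads cannot be trimmed and fall
#' through the cascade). Substitution errors are applied uniformly at
#' `error_rate` per base. Truth trim points are recorded.
#'
#' @param loci truth loci (need `locus_id`, `sequence`).
#' @param counts raw count data frame (as from [simulate_counts()]);
#'   reads are emitted per library column.
#' @param linker linker sequence.
#' @param p_full,p_trunc,p_absent linker-state probabilities (sum to 1).
#' @param error_rate per-base substitution probability.
#' @param seed random seed.
#' @return named list (one entry per library) of lists with `reads` (data
#'   frame `id`, `seq`, `qual`) and `truth` (data frame `id`, `locus_id`,
#'   `linker_state`, `trim_position`).
#' @export
emit_raw_reads <- function(loci, counts, linker, p_full = 0.8,
                           p_trunc = 0.15, p_absent = 0.05,
                           error_rate = 0, seed = 1) {
  seed <- check_seed(seed)
  check_dna(linker, "linker")
  if (abs(p_full + p_trunc + p_absent - 1) > 1e-8)
    stop("linker-state probabilities must sum to 1")
  seqs <- stats::setNames(loci$sequence, loci$locus_id)
  libs <- setdiff(names(counts), "species_id")
  out <- vector("list", length(libs)); names(out) <- libs
  withr_seed(seed, {
    for (lib in libs) {
      nrep <- counts[[lib]]
      locus <- rep(counts$species_id, nrep)
      ntot <- length(locus)
      if (ntot == 0L) {
        out[[lib]] <- list(
          reads = data.frame(id = character(0), seq = character(0),
                             qual = character(0)),
          truth = data.frame(id = character(0), locus_id = character(0),
                             linker_state = character(0),
                             trim_position = integer(0)))
        next
      }
      state <- sample(c("full", "trunc", "absent"), ntot, replace = TRUE,
                      prob = c(p_full, p_trunc, p_absent))
      klen <- ifelse(state == "full", nchar(linker),
                     ifelse(state == "trunc",
                            sample(3:5, ntot, replace = TRUE), 0L))
      ins <- unname(seqs[locus])
      reads <- paste0(ins, substr(rep(linker, ntot), 1L, klen))
      if (error_rate > 0) {
        reads <- vapply(reads, function(r) {
          ch <- strsplit(r, "", fixed = TRUE)[[1L]]
          hit <- which(stats::runif(length(ch)) < error_rate)
          for (h in hit) ch[h] <- sample(setdiff(DNA_BASES, ch[h]), 1L)
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      ids <- sprintf("%s_r%06d", lib, seq_len(ntot))
      out[[lib]] <- list(
        reads = data.frame(id = ids, seq = reads,
                           qual = strrep("I", nchar(reads)),
                           stringsAsFactors = FALSE),
        truth = data.frame(id = ids, locus_id = locus,
                           linker_state = state,
                           trim_position = ifelse(state == "absent",
                                                  NA_integer_,
                                                  nchar(ins) + 1L),
                           stringsAsFactors = FALSE))
    }
  })
  out
}

#' Simulate a transcriptome with planted 21U target sites and 22G reads
#'
#' Target sites are 21-nt antisense footprints: the reverse complement of
#' the source 21U, mutated at exactly the planned number of positions, is
#' written into the transcript. 22G species are 22-nt, 5'-G reads mapping
#' antisense at planned footprint gaps from their site; gap 0 means
#' overlapping/adjacent footprints. A set of background 22G species that
#' also appear in the prg-1-like library (hence not piRNA-dependent) is
#' planted away from all sites.
#'
#' @param loci truth loci (need `locus_id`, `sequence`, `truth_class`).
#' @param n_transcripts number of transcripts.
#' @param transcript_length length of each transcript (nt).
#' @param target_plan data frame with columns `locus_id`, `transcript`
#'   (index), `pos` (1-based site start on the transcript), `mismatches`
#'   (0-3) and `g22_gaps` (comma-separated footprint gaps, `""` for no
#'   22G); `NULL` auto-plans one 0-2-mismatch site with one adjacent 22G
#'   per enriched locus.
#' @param prg1_background number of background 22G species.
#' @param seed random seed.
#' @return list with `transcripts` (named character), `sites` (truth
#'   target table), `g22` (truth 22G table with `counts_wt`,
#'   `counts_prg1`) and `target_plan`.
#' @export
simulate_transcriptome_and_22g <- function(loci, n_transcripts = 20,
                                           transcript_length = 1500,
                                           target_plan = NULL,
                                           prg1_background = 5, seed = 1) {
  seed <- check_seed(seed)
  withr_seed(seed, {
    tx <- vapply(seq_len(n_transcripts), function(i)
      paste(sample(DNA_BASES, transcript_length, replace = TRUE),
            collapse = ""), character(1))
    names(tx) <- sprintf("tx%03d", seq_len(n_transcripts))
    if (is.null(target_plan)) {
      sel <- which(loci$truth_class %in% c("male", "female"))
      target_plan <- data.frame(
        locus_id = loci$locus_id[sel],
        transcript = rep(seq_len(n_transcripts), length.out = length(sel)),
        pos = sample(200:(transcript_length - 200), length(sel)),
        mismatches = sample(0:2, length(sel), replace = TRUE),
        g22_gaps = "5", stringsAsFactors = FALSE)
    }
    txc <- lapply(tx, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
    sites <- list(); g22 <- list(); gi <- 1L
    for (i in seq_len(nrow(target_plan))) {
      p <- target_plan[i, ]
      u <- loci$sequence[match(p$locus_id, loci$locus_id)]
      cls <- loci$truth_class[match(p$locus_id, loci$locus_id)]
      site <- strsplit(revcomp(u), "", fixed = TRUE)[[1L]]
      if (p$mismatches > 0L) {
        at <- sample(21L, p$mismatches)
        for (a in at) site[a] <- sample(setdiff(DNA_BASES, site[a]), 1L)
      }
      ti <- p$transcript
      txc[[ti]][p$pos:(p$pos + 20L)] <- site
      sites[[i]] <- data.frame(
        transcript_id = names(tx)[ti], start = p$pos, end = p$pos + 20L,
        source_21u = p$locus_id, n_mismatches = p$mismatches,
        truth_class = cls, stringsAsFactors = FALSE)
      gaps <- if (nzchar(p$g22_gaps))
        as.integer(strsplit(p$g22_gaps, ",", fixed = TRUE)[[1L]]) else
          integer(0)
      for (g in gaps) {
        g_start <- p$pos + 21L + g        # downstream of the site
        if (g_start + 21L > transcript_length) next
        txc[[ti]][g_start + 21L] <- "C"   # forces the 22G 5' G
        g22[[gi]] <- data.frame(
          species_22g = sprintf("g22_%04d", gi),
          transcript_id = names(tx)[ti], start = g_start,
          end = g_start + 21L, truth_gap = g, source_21u = p$locus_id,
          truth_class = cls, counts_wt = 5L, counts_prg1 = 0L,
          stringsAsFactors = FALSE)
        gi <- gi + 1L
      }
    }
    # prg-1-independent background 22Gs, planted in the transcript tails
    for (b in seq_len(prg1_background)) {
      ti <- sample(n_transcripts, 1L)
      g_start <- transcript_length - 60L - b * 25L
      txc[[ti]][g_start + 21L] <- "C"
      g22[[gi]] <- data.frame(
        species_22g = sprintf("g22_bg_%02d", b),
        transcript_id = names(tx)[ti], start = g_start,
        end = g_start + 21L, truth_gap = NA_integer_,
        source_21u = NA_character_, truth_class = "background",
        counts_wt = 5L, counts_prg1 = 5L, stringsAsFactors = FALSE)
      gi <- gi + 1L
    }
    tx <- stats::setNames(vapply(txc, paste, character(1), collapse = ""),
                          names(tx))
  })
  g22 <- do.call(rbind, g22)
  if (!is.null(g22))
    g22$sequence <- vapply(seq_len(nrow(g22)), function(j)
      revcomp(substr(tx[[g22$transcript_id[j]]], g22$start[j],
                     g22$end[j])), character(1))
  list(transcripts = tx, sites = do.call(rbind, sites), g22 = g22,
       target_plan = target_plan)
}

#' Simulate a per-nucleotide signal track
#'
#' Signal at each position is `baseline` plus a bump contribution centred
#' at every anchor plus Gaussian noise.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param anchors data frame with `chrom`, `pos`, and optionally `strand`
#'   (bumps for minus-strand anchors are reversed); may be empty.
#' @param bump_shape numeric vector added centred on each anchor (its
#'   middle element lands on the anchor position).
#' @param baseline constant baseline level.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed random seed.
#' @return list of per-chromosome numeric signal vectors (a "track"); use
#'   [track_to_bedgraph()] to serialise.
#' @export
simulate_signal_track <- function(chrom_lengths, anchors = NULL,
                                  bump_shape = numeric(0), baseline = 1,
                                  noise_sd = 0, seed = 1) {
  seed <- check_seed(seed)
  withr_seed(seed, {
    track <- lapply(chrom_lengths, function(L)
      rep(baseline, L) + if (noise_sd > 0) stats::rnorm(L, 0, noise_sd)
      else 0)
  })
  names(track) <- names(chrom_lengths)
  w <- length(bump_shape)
  if (!is.null(anchors) && nrow(anchors) > 0L && w > 0L) {
    half <- (w - 1L) %/% 2L
    for (i in seq_len(nrow(anchors))) {
      ch <- anchors$chrom[i]
      shape <- bump_shape
      if (!is.null(anchors$strand) && anchors$strand[i] == "-")
        shape <- rev(shape)
      at <- anchors$pos[i] + seq_len(w) - 1L - half
      ok <- at >= 1L & at <= length(track[[ch]])
      track[[ch]][at[ok]] <- track[[ch]][at[ok]] + shape[ok]
    }
  }
  track
}

#' Convert a track to / from bedGraph records
#'
#' @param track list of per-chromosome numeric vectors.
#' @return `track_to_bedgraph()`: a bedGraph data frame (1-based inclusive,
#'   one run-length row per constant stretch); `track_from_bedgraph()`: a
#'   track list.
#' @export
track_to_bedgraph <- function(track) {
  out <- lapply(names(track), function(ch) {
    r <- rle(track[[ch]])
    end <- cumsum(r$lengths)
    data.frame(chrom = ch, start = c(1L, head(end, -1L) + 1L),
               end = end, value = r$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname track_to_bedgraph
#' @param bg bedGraph data frame (as from [read_bedgraph()]).
#' @param chrom_lengths named lengths; defaults to the maximum end seen.
#' @export
track_from_bedgraph <- function(bg, chrom_lengths = NULL) {
  chroms <- unique(bg$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch)
      max(bg$end[bg$chrom == ch]), numeric(1))
  track <- lapply(chroms, function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    sel <- bg$chrom == ch
    for (j in which(sel)) v[bg$start[j]:bg$end[j]] <- bg$value[j]
    v
  })
  stats::setNames(track, chroms)
}
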