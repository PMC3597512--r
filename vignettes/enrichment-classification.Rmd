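---
title: "Classifying germline-enriched 21U RNAs and their upstream motifs"
author: "pirna21"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirna21)
```

## The biological problem

*C. elegans* piRNAs (21U RNAs) are 21-nt small RNAs with a 5' uridine,
bound by the Piwi Argonaute PRG-1. Unlike the long piRNA precursor
clusters of fly and mouse, each 21U RNA is expressed from a tiny,
autonomous transcriptional unit: an 8-nt upstream core motif (consensus
`CTGTTTCA`, with `GTTTC` its best-conserved center), an A/T-rich spacer of
roughly 35-42 nt, and the 21-nt locus starting at a genomic thymidine.
Most 21U RNAs are preferentially expressed in either the male or the
female germline, and the 5' nucleotide of the core motif carries part of
that information: motifs with a 5' cytidine are strongly over-represented
upstream of male germline-enriched species.

This package implements the computational side of that analysis as a
reusable pipeline operating on multi-library small RNA sequencing counts,
together with a synthetic-data generator that plants motif/21U cassettes
with known truth so the whole pipeline can be validated without any
external download.

## The Enrichment Score model

Let a study comprise male and female germline libraries, each prepared
with either a 5'-monophosphate-dependent or -independent protocol.
Within each protocol group, every male library is compared with every
female library; the default 17-library design (5 dependent male, 1
dependent female, 9 independent male, 2 independent female) yields
`5*1 + 9*2 = 23` comparisons.

For species $i$ with normalized abundance $m$ in a male library and $f$
in a female library, each comparison contributes

$$ s = -\,\mathbf{1}\{m > \kappa f\} + \mathbf{1}\{f > \kappa m\}, \qquad
   \kappa = 5, $$

and the Enrichment Score is the sum over all comparisons. Species with
score $\le -3$ are called male germline-enriched, $\ge +3$ female, the
rest non-enriched.

**Zero handling.** The comparison is a strict multiplicative inequality.
A zero-vs-positive pair therefore always scores for the positive side
(any positive value exceeds five times zero) and a zero-vs-zero pair
never scores. No pseudocount enters the score. This is the only reading
that requires no unstated constant; it has a practical consequence
discussed under *false discovery* below.

**Filters.** Before thresholding, species with no reads in any germline
library are excluded (`excluded_zero`), as are species with higher
normalized abundance in a *prg-1* mutant young adult library than in the
wild-type reference (`excluded_mutant`; such species do not depend on the
piRNA pathway). After thresholding, a classified species whose *average
fold abundance* does not favor its class is reclassified to non-enriched.
The average fold is the geometric mean over all comparisons of
$(m + c)/(f + c)$ with pseudocount $c = 0.25$ RPM; the pseudocount is
needed here because ratios of zeros are undefined, and the geometric mean
is used for symmetry (swapping the sexes inverts the average exactly).
The mutant-dependence filter compares normalized values by default; this
is configurable because raw-count comparison is equally defensible.

**Normalization.** Raw counts are divided by the number of genomic loci a
species maps to and scaled to reads per million mapped reads (RPM) per
library. Only uniquely interpretable quantities enter downstream motif
analyses: species mapping to more than one locus are excluded there,
since their upstream sequences are ambiguous.

The same engine runs unchanged on 26G RNAs with a reduced 13-library
manifest (16 comparisons); the excluded libraries are a manifest-level
decision, not a code path.

## The false-discovery null

The score has no analytic null, so false discovery is estimated by
randomization: per species, a rate $\lambda$ is set to its count in a
reference library; 17 control libraries of Poisson($\lambda$) counts are
drawn; the control columns are randomly assigned the sex-by-protocol
labels of the real design; and the standard scoring and thresholds are
applied. The fraction of all simulated species classified as enriched,
averaged over 1,000 replicates, is the estimate. The null deliberately
draws *raw* counts — the real analysis normalizes, the null does not.

Because the strict zero rule lets zero-vs-positive pairs score, the
per-species false-classification probability depends sharply on
$\lambda$: it is large below $\lambda \approx 3$ (a Poisson(1) species
produces many 0-vs-1 pairs and random-walks past $\pm 3$ easily) and
collapses to zero above $\lambda \approx 20$, where 5-fold excursions
become impossible. The aggregate false discovery rate is therefore
essentially the fraction of reference-library species with single-digit
counts. With $\lambda$ drawn from a deep reference library, the estimate
lands well below 1%; a hypothetical reference dominated by counts of 1-5
would instead invalidate the threshold, which is worth knowing when
applying the method to shallow libraries. The acceptance script draws
$\lambda$ from a synthetic reference library generated under the default
expression model and verifies the < 2% bound.

## Upstream motif scanning conventions

The scanner searches the 60 nt upstream of each locus (on the locus
strand) for `GTTTC`. Conventions that shift results by one nucleotide are
fixed as follows and used consistently everywhere:

* the **spacer** is the number of nucleotides strictly between the 8-mer's
  3' end and the 21U 5' T;
* the canonical spacer range is 35-42 nt and the abundance optimum is
  39 nt;
* among multiple `GTTTC` occurrences the one whose implied spacer is
  closest to 39 is selected, ties going to the shorter spacer. The
  original analysis does not state its selection rule, so this choice is
  explicit and configurable (`select = "nearest39" | "leftmost" |
  "rightmost"`);
* the 8-mer is 2 nt of context + `GTTTC` + 1 nt; its first base is the 5'
  nucleotide class (C/A/G/T). Loci with no in-window `GTTTC` are class
  `NM`, anchored for alignment by placing the G of the core motif at
  position −44 relative to the 5' T (the most common G position);
* motif matrices align windows on the first of the central three Ts and
  report per-position information content
  $\sum_b f_b \log_2 (f_b / q_b)$ against the genome base composition;
* `GTTTC` genomic density counts overlapping occurrences on both strands
  per kilobase.

Miniclusters are sets of uniquely mapping loci whose motif calls share the
same genomic `GTTTC` (same chromosome, strand and coordinate). For
two-member germline-enriched miniclusters, random assortment of the
members (male fraction $p$, female $q = 1-p$) predicts pair fractions
$p^2 : q^2 : 2pq$. Both this analytic expectation and a permutation
version (random re-pairing of the observed members) are provided because
the original procedure is not stated; they agree within Monte-Carlo error
on every configuration tested. Applied to the published composition of
1,026 pairs (73%/12%/15%), the analytic expectation gives 68.6% matching
(~69%), 31.4% mixed and 3.8% female:female.

## Targets and 22G attribution

A 21U RNA targets a transcript wherever the transcript's reverse
complement is within Hamming distance 3 of the 21U — no gaps, no G:U
wobble, all 21 positions weighted equally, since nothing more specific is
stated. 22G species (22-nt, 5' G) are attributed to the classes of target
sites within 40 nt of their footprint, measured footprint-to-footprint
with overlap counting as distance 0 (a 5'-end-based alternative is
available behind an argument). Species detected in a *prg-1* mutant
library are excluded before attribution. Randomization tests re-draw
disjoint random "male"/"female" 21U sets of the observed sizes and
recompute the both-class count or the shared-target-gene count; planted
disjoint targeting lands below the 2.5th percentile of the randomized
distribution, mirroring the under-overlap observed in real data.

## Signal metaprofiles

`metaprofile()` averages a per-nucleotide track across anchors, each
window oriented 5'→3' on the anchor strand; anchors whose window leaves
the chromosome are skipped rather than zero-padded (zero padding creates
artificial dips). The default half-width of 500 nt covers the −300..−50
interval where the interesting occupancy features sit. Background anchors
come from random non-overlapping 1-kb windows tiled into unannotated
space. The operator is linear and translation-invariant, which the tests
assert exactly, and reproduces the qualitative background-exceeds-signal
configuration on constructed tracks.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* genomes of given GC content with planted cassettes: an A/T-only 62-nt
  upstream flank (guaranteeing no spurious `GTTTC` upstream of the planted
  motif), the 8-mer, an A-filled spacer, thymidines at chosen spacer
  distances within 35-42 (several thymidines yield miniclusters), and the
  21-nt locus bodies, on either strand;
* multi-library counts: per-species log-normal baselines, negative
  binomial sampling, a male fold applied in male libraries to male-truth
  species (and the female analogue), embryo carry-over for female
  species, and depletion in *prg-1* mutant libraries;
* linkered raw reads with full, truncated (3-5 nt) or absent linkers and
  optional substitution errors, with recorded truth trim points;
* transcriptomes with target sites planted at exact mismatch counts and
  22G reads at exact footprint gaps, plus *prg-1*-independent background
  species;
* per-nucleotide signal tracks as baseline + anchored bumps + Gaussian
  noise.

**Default study conditions.** The defaults describe a deep, well-behaved
germline study: 24 libraries (the 17-germline design plus 4 embryo, one
wild-type and one *prg-1* young adult library) of 2 million mapped reads
each (about 50 million reads across the study); per-species baselines
log-normal with median 50 RPM and log-sd 1; negative binomial dispersion
0.1 (between-library CV ≈ 30%); sex folds 8× (male) and 4× (female),
reflecting the asymmetry of observed male vs female enrichment; embryo
carry-over 4× for female species. Under these conditions the classifier
recovers ≥ 95% of male-truth species, ≥ 70% of the more weakly enriched
female-truth species, and classifies ≤ 2% of species when no enrichment
is planted. These parameters were fixed once as the package's study
conditions; noisier regimes are explored by passing a different
`expression_model()`.

What the generator does **not** emulate: sequencing quality variation and
indel errors, PCR duplicates, motif-free (`NM`) loci in quantity,
cross-mapping between near-identical loci at genomic scale, and the
chromosome IV cluster architecture of the real genome. Passing tests
therefore validate the pipeline's logic and calibration, not properties
of any real dataset; published quantities that depend on the real
sequencing libraries (class proportions, observed fold asymmetries, motif
fractions, occ/kb densities) are out of desk reach by construction.

## Numerical and degenerate-input choices

* Strict inequalities throughout the score; exactly 5-fold does not score.
* Classification precedence: zero exclusion, mutant exclusion, threshold,
  fold-consistency reclassification.
* Chi-square tests are Pearson without continuity correction; Fisher's
  exact test is reported alongside where randomization tables are
  compared. Degenerate contingency tables (one class, one motif category,
  or all-one-class pair sets) raise explicit errors or are flagged rather
  than silently tested.
* Single-member abundance classes get `NA` SEM and are excluded from
  Welch tests; Welch tests are two-tailed everywhere.
* Tie-breaks: motif selection ties go to the shorter spacer; abundance
  quartile ties keep stable input order.
* Problem sizes used by the test-suite and acceptance script: genomes of
  20-300 kb, 300-1,000 species, 1,000 null replicates, 10,000 reads for
  the trimmer oracle. These sizes give Monte-Carlo error comfortably
  below every asserted margin.

## Known limitations

* The internal mapper enumerates ungapped alignments with ≤ 2 mismatches
  and is intended for synthetic-scale genomes, not a whole-genome
  replacement for a production aligner.
* The FDR null inherits the paper's design (raw Poisson counts, label
  permutation over 17 control libraries); it does not model biological
  overdispersion, so it measures the score's intrinsic false-call rate,
  not robustness to between-library variability.
* Transcript expression values (FPKM filters) are accepted as inputs;
  transcript quantification is out of scope.
* Gene-category lists for the gene-set randomization are user-supplied.
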