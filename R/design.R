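# Library-design manifests and run configuration.
#
# A manifest describes every sequencing library in the analysis: its sex
# (male, female, embryo, mixed), the 5'-monophosphate protocol used to make
# it (dependent or independent), genotype, stage and sequencing depth.
# Germline libraries (sex male or female) drive the Enrichment Score; the
# within-protocol male x female pairs define the comparisons.

VALID_SEX <- c("male", "female", "embryo", "mixed")
VALID_PROTOCOL <- c("monoP_dependent", "monoP_independent")

#' Validate a library-design manifest
#'
#' @param design data frame with columns `id`, `sex`, `protocol`,
#'   `genotype`, `stage`, `total_mapped_reads`.
#' @param counts optional count table (as from [read_counts()]); when
#'   given, every count column must be a manifest library id.
#' @param require_germline require at least one male and one female
#'   germline library (needed for enrichment analysis).
#' @return `design`, invisibly, or an error.
#' @export
validate_design <- function(design, counts = NULL, require_germline = FALSE) {
  need <- c("id", "sex", "protocol", "genotype", "stage",
            "total_mapped_reads")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$id))
    stop("manifest library ids must be unique (duplicated: ",
         design$id[duplicated(design$id)][1L], ")")
  if (!all(design$sex %in% VALID_SEX))
    stop("invalid sex value(s): ",
         paste(setdiff(design$sex, VALID_SEX), collapse = ", "))
  if (!all(design$protocol %in% VALID_PROTOCOL))
    stop("invalid protocol value(s): ",
         paste(setdiff(design$protocol, VALID_PROTOCOL), collapse = ", "))
  if (any(design$total_mapped_reads < 0))
    stop("total_mapped_reads must be non-negative")
  if (!is.null(counts)) {
    libs <- setdiff(names(counts), "species_id")
    unknown <- setdiff(libs, design$id)
    if (length(unknown))
      stop("count table references libraries absent from the manifest: ",
           paste(unknown, collapse = ", "))
  }
  if (require_germline) {
    g <- germline_libraries(design)
    if (!any(g$sex == "male") || !any(g$sex == "female"))
      stop("enrichment analysis requires at least one male and one ",
           "female germline library")
  }
  invisible(design)
}

#' Germline libraries of a manifest
#'
#' Germline libraries are those with sex `male` or `female`; embryo and
#' mixed-stage libraries never enter the Enrichment Score.
#'
#' @param design a library-design manifest.
#' @return the germline rows of `design`.
#' @export
germline_libraries <- function(design) {
  design[design$sex %in% c("male", "female"), , drop = FALSE]
}

#' Default 24-library study design
#'
#' The default manifest mirrors the composite meta-analysis design this
#' package emulates: 17 germline libraries (5 monoP-dependent male, 1
#' dependent female, 9 independent male, 2 independent female), 4 mixed
#' stage embryo libraries, one wild-type (N2) young adult reference
#' library and one prg-1 mutant young adult library used for the
#' piRNA-dependence filter. Within-protocol male x female pairing of the
#' 17 germline libraries yields 23 comparisons.
#'
#' @param depth total mapped reads assigned to every library (the default
#'   matches a deep small RNA library of ~2 million mapped reads).
#' @return a manifest data frame.
#' @export
#' @examples
#' d <- default_design()
#' count_comparisons(d)  # 23
default_design <- function(depth = 2e6) {
  mk <- function(id, sex, protocol, genotype, stage)
    data.frame(id = id, sex = sex, protocol = protocol,
               genotype = genotype, stage = stage,
               total_mapped_reads = depth, stringsAsFactors = FALSE)
  rbind(
    mk(paste0("dep_male_", 1:5), "male", "monoP_dependent", "N2",
       "germline"),
    mk("dep_female_1", "female", "monoP_dependent", "fem-1", "germline"),
    mk(paste0("indep_male_", 1:9), "male", "monoP_independent", "N2",
       "germline"),
    mk(paste0("indep_female_", 1:2), "female", "monoP_independent",
       "fem-1", "germline"),
    mk(paste0("embryo_", 1:4), "embryo", "monoP_independent", "N2",
       "embryo"),
    mk("n2_ya", "mixed", "monoP_independent", "N2", "young_adult"),
    mk("prg1_ya", "mixed", "monoP_independent", "prg-1", "young_adult")
  )
}

#' Reduced design for 26G RNA classification
#'
#' The 26G RNA analysis re-uses the enrichment engine on a 13-library
#' germline subset (4 dependent male, 1 dependent female, 6 independent
#' male, 2 independent female): four male libraries are dropped because
#' their genotypes lack 26G RNA expression. The within-protocol pairing
#' gives 16 comparisons.
#'
#' @param depth total mapped reads per library.
#' @return a manifest data frame.
#' @export
design_26g <- function(depth = 2e6) {
  d <- default_design(depth)
  d <- d[d$sex %in% c("male", "female"), , drop = FALSE]
  drop <- c("dep_male_5", paste0("indep_male_", 7:9))
  d[!d$id %in% drop, , drop = FALSE]
}

#' Read / write a manifest
#'
#' Manifests are TSV files with a header row and the columns documented in
#' [validate_design()].
#'
#' @param path path to the TSV manifest.
#' @return `read_design()` returns the validated manifest data frame.
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_design(d)
  d
}

#' @rdname read_design
#' @param design manifest data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' A single nested list of every tunable threshold, with the conventions
#' used throughout the package: a 5-fold abundance threshold and |score|
#' >= 3 for enrichment calls, a 60-nt upstream scan window, the canonical
#' spacer range 35-42 nt with optimum 39 nt, a 40-nt proximity rule for
#' 22G attribution, and up to 3 mismatches for target search.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    enrichment = list(fold_threshold = 5, score_threshold = 3L,
                      pseudocount = 0.25),
    motif = list(window = 60L, spacer_min = 35L, spacer_max = 42L,
                 spacer_optimum = 39L, select = "nearest39"),
    trim = list(allow_1mm_short = TRUE),
    mapping = list(max_mismatches = 2L, max_loci = 50L),
    targets = list(max_mismatches = 3L, distance = 40L, n_reps = 1000L),
    fdr = list(n_reps = 1000L),
    paths = list()
  )
}

#' Read / write run configuration (YAML)
#'
#' @param path path to a YAML configuration file.
#' @return `read_config()` returns the configuration merged over
#'   [default_config()] (file values win).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_lists(base[[k]], new[[k]]) else new[[k]]
    }
    base
  }
  merge_lists(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
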