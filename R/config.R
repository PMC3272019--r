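#' Pipeline configuration
#'
#' Collects the tunable thresholds used across the census pipeline. Defaults
#' follow the operational definitions used throughout the package: a +/- 3 nt
#' generic window around annotated miRNA 5' ends, an expression floor of 150
#' weighted tags per miRNA (25 for the permissive comparative mode), 80%/20%
#' arm-fraction thresholds for strand-bias categories, a 20% minimum fraction
#' for extreme-isomiR (e-miR) calls, 24 nt as the long-tag cutoff, the seed at
#' mature positions 2-8, p < 0.01 for composition/enrichment tests, and
#' differential-expression gates of >1000 normalized tags per library with
#' two-fold change in every replicate.
#'
#' @param generic_window Maximum absolute 5' start offset (nt) for a tag to be
#'   called generic relative to an annotated miRNA.
#' @param min_expression Weighted tag threshold per miRNA/hairpin for the
#'   stringent analyses (inclusive).
#' @param low_expression Permissive expression threshold (inclusive).
#' @param bias_hi,bias_lo Arm-fraction thresholds splitting biased (major or
#'   minor) from symmetrically expressed species.
#' @param emir_min_fraction Minimum fraction of a hairpin's tags a non-generic
#'   tag set must reach to be reported as an e-miR.
#' @param long_tag_len Tags longer than this many nt count as "long".
#' @param seed_interval Positions of the seed within the mature sequence.
#' @param alpha Significance threshold for composition and enrichment tests.
#' @param de_min_tags Normalized per-library expression floor for differential
#'   calls (strict inequality).
#' @param de_fold Fold-change that must be exceeded (or met) in every
#'   replicate for a differential call.
#' @param max_mismatches Mismatches tolerated during alignment.
#' @param min_tag_len,max_tag_len Length bounds applied when collapsing reads.
#' @param phase_window Half-width (nt) of the modal 5' start window used by
#'   phasing rules.
#' @param phase_min_fraction Minimum fraction of a tag set's weighted count
#'   that the modal 5' start (+/- `phase_window`) must hold for the set to be
#'   "well phased".
#' @param phase_min_tags Minimum weighted count for a phased set.
#' @param emir_len_range Allowed modal tag length (nt) for credible e-miR and
#'   discovery tag sets.
#' @param star_overhang Canonical duplex 3' overhang (nt).
#' @param star_geom_tol Tolerance (nt) around the canonical overhang when
#'   deciding whether a novel miR* is "directly juxtaposed" to a known miRNA.
#' @param multimap_cap Genome placements above this count mark a tag as
#'   repetitive and discard it.
#' @param cluster_window Window (nt) for grouping genome tags into clusters.
#' @param cluster_min_count Minimum weighted count for a genomic tag cluster.
#' @param fold_window_lengths Genomic window lengths (nt) folded around a
#'   cluster during discovery.
#' @param distortion_window Number of nt examined on each strand around a
#'   cleavage boundary when classifying structural distortions.
#' @param cand_min_paired_frac Minimum fraction of candidate bases paired.
#' @param cand_loop_range Allowed terminal loop length (nt) for candidates.
#' @param cand_min_stem Minimum number of base pairs spanning the loop.
#' @param cand_len_range Allowed modal length (nt) of a candidate miRNA.
#' @param fold_backend Secondary-structure prediction backend: the bundled
#'   base-pair maximization folder (`"nussinov"`) or ViennaRNA's `RNAfold`
#'   executable if present on the PATH (`"rnafold"`).
#' @param rng_seed Optional integer seed recorded in outputs.
#'
#' @return An object of class `census_config` (a validated named list).
#' @export
#' @examples
#' cfg <- census_config()
#' cfg$generic_window
census_config <- function(generic_window = 3L,
                          min_expression = 150,
                          low_expression = 25,
                          bias_hi = 0.80,
                          bias_lo = 0.20,
                          emir_min_fraction = 0.20,
                          long_tag_len = 24L,
                          seed_interval = c(2L, 8L),
                          alpha = 0.01,
                          de_min_tags = 1000,
                          de_fold = 2.0,
                          max_mismatches = 1L,
                          min_tag_len = 15L,
                          max_tag_len = 35L,
                          phase_window = 1L,
                          phase_min_fraction = 0.5,
                          phase_min_tags = 10,
                          emir_len_range = c(18L, 26L),
                          star_overhang = 2L,
                          star_geom_tol = 1L,
                          multimap_cap = 10L,
                          cluster_window = 30L,
                          cluster_min_count = 50,
                          fold_window_lengths = c(100L, 160L),
                          distortion_window = 4L,
                          cand_min_paired_frac = 0.6,
                          cand_loop_range = c(3L, 30L),
                          cand_min_stem = 16L,
                          cand_len_range = c(20L, 24L),
                          fold_backend = c("nussinov", "rnafold"),
                          rng_seed = NULL) {
  cfg <- list(
    generic_window = as.integer(generic_window),
    min_expression = min_expression,
    low_expression = low_expression,
    bias_hi = bias_hi,
    bias_lo = bias_lo,
    emir_min_fraction = emir_min_fraction,
    long_tag_len = as.integer(long_tag_len),
    seed_interval = as.integer(seed_interval),
    alpha = alpha,
    de_min_tags = de_min_tags,
    de_fold = de_fold,
    max_mismatches = as.integer(max_mismatches),
    min_tag_len = as.integer(min_tag_len),
    max_tag_len = as.integer(max_tag_len),
    phase_window = as.integer(phase_window),
    phase_min_fraction = phase_min_fraction,
    phase_min_tags = phase_min_tags,
    emir_len_range = as.integer(emir_len_range),
    star_overhang = as.integer(star_overhang),
    star_geom_tol = as.integer(star_geom_tol),
    multimap_cap = as.integer(multimap_cap),
    cluster_window = as.integer(cluster_window),
    cluster_min_count = cluster_min_count,
    fold_window_lengths = as.integer(fold_window_lengths),
    distortion_window = as.integer(distortion_window),
    cand_min_paired_frac = cand_min_paired_frac,
    cand_loop_range = as.integer(cand_loop_range),
    cand_min_stem = as.integer(cand_min_stem),
    cand_len_range = as.integer(cand_len_range),
    fold_backend = match.arg(fold_backend),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  stopifnot(
    cfg$generic_window >= 0L,
    cfg$min_expression >= 0, cfg$low_expression >= 0,
    cfg$bias_lo > 0, cfg$bias_lo < cfg$bias_hi, cfg$bias_hi < 1,
    cfg$emir_min_fraction > 0, cfg$emir_min_fraction <= 1,
    cfg$max_mismatches >= 0L,
    cfg$min_tag_len > 0L, cfg$min_tag_len <= cfg$max_tag_len,
    cfg$phase_min_fraction > 0, cfg$phase_min_fraction <= 1,
    length(cfg$seed_interval) == 2L,
    cfg$seed_interval[1] >= 1L, cfg$seed_interval[1] < cfg$seed_interval[2]
  )
  structure(cfg, class = "census_config")
}

#' @export
print.census_config <- function(x, ...) {
  cat("miRNA census configuration\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  for (nm in names(flat)) cat(sprintf("  %-22s %s\n", nm, flat[[nm]]))
  invisible(x)
}
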