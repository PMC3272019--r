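# Hairpin arm strand bias, expression filters, and the replicate-based
# differential expression screen.

#' Compute per-hairpin arm bias and categorize it
#'
#' Arm fractions are computed on weighted generic tags only, so that bias
#' reflects competition between annotated species. Hairpins below the
#' stringent expression threshold are `not_assessed`. Categories follow the
#' annotation pattern: for mature/star hairpins a star-arm fraction above
#' `bias_hi` is a `strand_reversal`, a fraction in (`bias_lo`, `bias_hi`] is
#' `biased_to_symmetrical`, anything else `concordant`; for -5p/-3p pairs
#' either arm above `bias_hi` is `symmetrical_to_biased`; single-annotation
#' hairpins are concordant by default and flagged.
#'
#' @param summary A [summarize_hairpins()] result.
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return data.frame of class `arm_bias` with one row per hairpin; the
#'   attribute `global` holds the cohort-level 5'/3' weighted tag shares.
#' @export
compute_arm_bias <- function(summary, reference, config = census_config()) {
  h <- summary$hairpin
  ann <- reference$annotations
  n <- nrow(h)
  pattern <- character(n); category <- character(n); flags <- character(n)
  star_arm <- character(n)
  for (i in seq_len(n)) {
    a <- ann[ann$hairpin_id == h$hairpin_id[i], , drop = FALSE]
    cls <- sort(unique(a$class))
    pattern[i] <- if (all(c("mature", "star") %in% cls)) "mature_star"
      else if (all(c("p5", "p3") %in% cls)) "p5_p3"
      else "single"
    star_arm[i] <- if (pattern[i] == "mature_star")
      a$arm[a$class == "star"][1] else NA_character_
  }
  total <- h$count_5p + h$count_3p
  p5_fraction <- ifelse(total > 0, h$count_5p / total, NA_real_)
  for (i in seq_len(n)) {
    if (total[i] < config$min_expression || total[i] == 0) {
      category[i] <- "not_assessed"
      next
    }
    if (pattern[i] == "mature_star") {
      sf <- if (identical(star_arm[i], "five_prime")) p5_fraction[i]
            else 1 - p5_fraction[i]
      category[i] <- if (sf > config$bias_hi) "strand_reversal"
        else if (sf > config$bias_lo) "biased_to_symmetrical"
        else "concordant"
    } else if (pattern[i] == "p5_p3") {
      category[i] <- if (p5_fraction[i] > config$bias_hi ||
                         (1 - p5_fraction[i]) > config$bias_hi)
        "symmetrical_to_biased" else "concordant"
    } else {
      category[i] <- "concordant"
      flags[i] <- "single_annotation"
    }
  }
  out <- data.frame(hairpin_id = h$hairpin_id,
                    count_5p = h$count_5p, count_3p = h$count_3p,
                    p5_fraction = p5_fraction,
                    annotation_pattern = pattern,
                    category = category, flags = flags,
                    stringsAsFactors = FALSE)
  class(out) <- c("arm_bias", "data.frame")
  tot5 <- sum(h$count_5p); tot3 <- sum(h$count_3p)
  attr(out, "global") <- c(p5 = 100 * tot5 / (tot5 + tot3),
                           p3 = 100 * tot3 / (tot5 + tot3))
  out
}

#' Filter miRNAs by expression
#'
#' Retains miRNAs whose weighted total meets the threshold (inclusive
#' boundary: a miRNA at exactly the threshold is kept).
#'
#' @param mirna Per-miRNA data.frame with a `total` column (e.g.
#'   `summary$mirna`).
#' @param threshold Weighted tag threshold.
#' @return The retained subset.
#' @export
expression_filter <- function(mirna, threshold = 150) {
  out <- mirna[mirna$total >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicated two-condition differential expression screen
#'
#' Counts are normalized to counts per million mapped tags per library. A
#' miRNA is significant when its fold change (treatment over reference,
#' normalized) meets `de_fold` in the same direction in every replicate and
#' its normalized count exceeds `de_min_tags` in every library. M is the
#' log2 fold of replicate-averaged normalized counts and A the mean log2
#' abundance. miRNAs with a missing replicate are flagged unevaluable.
#'
#' @param counts Matrix of raw counts, miRNAs x libraries.
#' @param condition Factor/character of length ncol(counts) with two levels;
#'   the first level (or `ref`) is the reference condition.
#' @param replicate Replicate labels pairing libraries across conditions.
#' @param config A [census_config()].
#' @param ref Optional reference condition name.
#' @return data.frame with per-miRNA M, A, per-replicate folds, and
#'   `significant`/`flags` columns; normalization recorded in the
#'   `normalization` attribute.
#' @export
differential_expression <- function(counts, condition, replicate,
                                    config = census_config(), ref = NULL) {
  condition <- as.character(condition)
  lev <- unique(condition)
  stopifnot(length(lev) == 2L, ncol(counts) == length(condition),
            length(replicate) == length(condition))
  if (is.null(ref)) ref <- lev[1]
  trt <- setdiff(lev, ref)
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  reps <- unique(replicate)
  folds <- matrix(NA_real_, nrow(counts), length(reps),
                  dimnames = list(rownames(counts), paste0("fold_", reps)))
  for (j in seq_along(reps)) {
    rsel <- replicate == reps[j] & condition == ref
    tsel <- replicate == reps[j] & condition == trt
    if (sum(rsel) == 1L && sum(tsel) == 1L) {
      folds[, j] <- cpm[, tsel] / cpm[, rsel]
    }
  }
  mean_ref <- rowMeans(cpm[, condition == ref, drop = FALSE])
  mean_trt <- rowMeans(cpm[, condition == trt, drop = FALSE])
  M <- log2(mean_trt / mean_ref)
  A <- 0.5 * (log2(mean_trt) + log2(mean_ref))
  unevaluable <- apply(folds, 1L, function(f) any(is.na(f)))
  expressed <- apply(cpm, 1L, function(x) all(x > config$de_min_tags))
  up <- apply(folds, 1L, function(f) all(!is.na(f) & f >= config$de_fold))
  down <- apply(folds, 1L, function(f) all(!is.na(f) & f <= 1 / config$de_fold))
  significant <- !unevaluable & expressed & (up | down)
  out <- data.frame(name = rownames(counts), M = M, A = A,
                    folds, significant = significant,
                    flags = ifelse(unevaluable, "unevaluable", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "normalization") <- "counts per million mapped tags"
  out
}

#' Non-canonical remainder of a class split
#'
#' Bookkeeping helper for census report tables: the percentage of tags not
#' accounted for by the canonical annotation classes (mature, star, -5p/-3p).
#'
#' @param percents Numeric vector of canonical class percentages.
#' @return 100 minus their sum.
#' @export
class_split_remainder <- function(percents) 100 - sum(percents)

#' Mapping rate
#'
#' Percentage of usable tags that found a placement.
#'
#' @param mapped,usable Tag totals.
#' @return Percentage mapped.
#' @export
mapping_rate <- function(mapped, usable) 100 * mapped / usable

#' Class split of feature calls
#'
#' Weighted percentage of generic tags per annotation class plus the
#' non-canonical remainder (e-miR candidates, novel-star candidates and
#' unassigned tags).
#'
#' @param calls Output of [assign_features()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
class_split <- function(calls) {
  w <- calls$weighted_count
  total <- sum(w)
  pct <- function(sel) 100 * sum(w[sel]) / total
  c(mature = pct(calls$label == "generic_mature"),
    star = pct(calls$label == "generic_star"),
    p5_p3 = pct(calls$label %in% c("generic_p5", "generic_p3")),
    noncanonical = pct(!startsWith(calls$label, "generic_")))
}
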