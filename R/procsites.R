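# Terminal nucleoside composition around cleavage sites, duplex
# reconstruction and structural distortion classes.

# estimated duplex partner of a position, moving inward by `dir` to the
# nearest paired position when the anchor itself is unpaired; the gap is
# added back so the estimate stays on the anchor's diagonal
partner_est <- function(pt, pos, dir) {
  p <- pos
  while (p >= 1L && p <= pt$n && pt$partner[p] == 0L) p <- p + dir
  if (p < 1L || p > pt$n || pt$partner[p] == 0L) {
    return(list(partner = NA_integer_, gap = NA_integer_))
  }
  list(partner = pt$partner[p] + (p - pos), gap = abs(p - pos))
}

# core overhang arithmetic shared by duplex reconstruction and novel-miR*
# geometry checks: positive values are 3' overhangs
duplex_overhangs <- function(s5, e5, s3, e3, pt) {
  dro <- partner_est(pt, s5, +1L)
  dic <- partner_est(pt, s3, +1L)
  list(drosha = if (is.na(dro$partner)) NA_real_ else unname(e3 - dro$partner),
       dicer = if (is.na(dic$partner)) NA_real_ else unname(e5 - dic$partner),
       anchored_unpaired = (isTRUE(dro$gap > 0L) || isTRUE(dic$gap > 0L)))
}

#' Terminal-position nucleotide profiles
#'
#' For every sufficiently expressed miRNA, builds isomiR-weighted frequency
#' vectors over A/C/G/U at four positions: the first and last tag positions
#' (from the tag's own bases) and the positions one nt outside the observed
#' 5' start and 3' end (from the hairpin). Each vector is renormalized to 1
#' per miRNA. The background is the unweighted mean over all available
#' position vectors of all included miRNAs.
#'
#' @param calls Output of [assign_features()].
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return Object of class `position_profiles`: list with `profiles` (long
#'   data.frame: name, hairpin_id, arm, position, A, C, G, U), `background`
#'   (length-4 frequency vector), and `mirna_background` (per-miRNA mean
#'   frequency per base, the background sample for composition tests).
#' @export
build_position_profiles <- function(calls, reference, config = census_config()) {
  gen <- calls[startsWith(calls$label, "generic_"), , drop = FALSE]
  keys <- unique(gen[, c("target_id", "anchor_name", "arm")])
  bases <- c("A", "C", "G", "U")
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(keys))) {
    g <- gen[gen$anchor_name == keys$anchor_name[i] &
               gen$target_id == keys$target_id[i], , drop = FALSE]
    if (sum(g$weighted_count) < config$min_expression) next
    hp_seq <- reference$seq[[keys$target_id[i]]]
    n <- nchar(hp_seq)
    for (pos in c("ext5", "first", "last", "ext3")) {
      b <- switch(pos,
        first = substr(g$tag_seq, 1L, 1L),
        last = substr(g$tag_seq, nchar(g$tag_seq), nchar(g$tag_seq)),
        ext5 = ifelse(g$start - 1L >= 1L,
                      substr(hp_seq, g$start - 1L, g$start - 1L), NA),
        ext3 = ifelse(g$end + 1L <= n,
                      substr(hp_seq, g$end + 1L, g$end + 1L), NA))
      ok <- !is.na(b)
      if (!any(ok)) { dropped <- dropped + 1L; next }
      v <- vapply(DNA_BASES, function(x)
        sum(g$weighted_count[ok][b[ok] == x]), numeric(1))
      if (sum(v) == 0) { dropped <- dropped + 1L; next }
      v <- v / sum(v)
      rows[[length(rows) + 1L]] <- data.frame(
        name = keys$anchor_name[i], hairpin_id = keys$target_id[i],
        arm = keys$arm[i], position = pos,
        A = v[1], C = v[2], G = v[3], U = v[4], stringsAsFactors = FALSE)
    }
  }
  profiles <- if (length(rows)) do.call(rbind, rows) else
    empty_df(list(name = character, hairpin_id = character, arm = character,
                  position = character, A = numeric, C = numeric,
                  G = numeric, U = numeric))
  rownames(profiles) <- NULL
  mat <- as.matrix(profiles[, bases, drop = FALSE])
  background <- if (nrow(mat)) colMeans(mat) else stats::setNames(rep(NA_real_, 4), bases)
  mirna_bg <- if (nrow(profiles)) {
    do.call(rbind, lapply(split(profiles, profiles$name), function(d) {
      data.frame(name = d$name[1], arm = d$arm[1],
                 t(colMeans(as.matrix(d[, bases]))), stringsAsFactors = FALSE)
    }))
  } else empty_df(list(name = character, arm = character, A = numeric,
                       C = numeric, G = numeric, U = numeric))
  rownames(mirna_bg) <- NULL
  structure(list(profiles = profiles, background = background,
                 mirna_background = mirna_bg, dropped_positions = dropped),
            class = "position_profiles")
}

#' Test terminal composition against background
#'
#' Groups miRNAs by arm-fraction of their hairpin into major (fraction of
#' hairpin tags from the miRNA's arm >= `bias_hi`), minor (<= `bias_lo`) and
#' symmetric species, plus a "total" group, and for every (arm, group,
#' position, base) runs a two-sided Welch (unequal-variance) t-test of the
#' per-miRNA frequencies at that position against the per-miRNA background
#' frequencies of that base. Status is `enriched`/`depleted` by the sign of
#' the mean difference when p < `alpha`; groups with fewer than 3 miRNAs are
#' reported `ns` with a `small_group` flag.
#'
#' @param profiles A [build_position_profiles()] result.
#' @param arm_fractions data.frame with columns `name` and `arm_fraction`
#'   (fraction of its hairpin's generic tags on the miRNA's own arm); see
#'   [mirna_arm_fractions()].
#' @param config A [census_config()].
#' @return data.frame of class `composition_result`.
#' @export
composition_test <- function(profiles, arm_fractions, config = census_config()) {
  bases <- c("A", "C", "G", "U")
  pr <- profiles$profiles
  pr$arm_fraction <- arm_fractions$arm_fraction[match(pr$name, arm_fractions$name)]
  pr$group <- ifelse(pr$arm_fraction >= config$bias_hi, "major",
              ifelse(pr$arm_fraction <= config$bias_lo, "minor", "symmetric"))
  bg <- profiles$mirna_background
  res <- list()
  for (arm in unique(pr$arm)) {
    for (grp in c("major", "minor", "symmetric", "total")) {
      sel <- pr$arm == arm & (grp == "total" | (!is.na(pr$group) & pr$group == grp))
      for (pos in c("ext5", "first", "last", "ext3")) {
        d <- pr[sel & pr$position == pos, , drop = FALSE]
        for (b in bases) {
          x <- d[[b]]
          y <- bg[[b]]
          small <- length(x) < 3L
          if (small || stats::var(x) + stats::var(y) == 0) {
            p <- NA_real_
            status <- "ns"
          } else {
            p <- stats::t.test(x, y, var.equal = FALSE)$p.value
            status <- if (!is.na(p) && p < config$alpha) {
              if (mean(x) > mean(y)) "enriched" else "depleted"
            } else "ns"
          }
          res[[length(res) + 1L]] <- data.frame(
            arm = arm, group = grp, position = pos, base = b,
            n = length(x), mean_freq = if (length(x)) mean(x) else NA_real_,
            background_freq = mean(y), p_value = p, status = status,
            flags = if (small) "small_group" else "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("composition_result", "data.frame")
  out
}

#' Per-miRNA own-arm fractions
#'
#' Helper producing, for every miRNA in a summary, the fraction of its
#' hairpin's generic tags that derive from the miRNA's own arm — the grouping
#' variable for [composition_test()].
#'
#' @param summary A [summarize_hairpins()] result.
#' @return data.frame with `name`, `arm`, `arm_fraction`.
#' @export
mirna_arm_fractions <- function(summary) {
  m <- summary$mirna
  h <- summary$hairpin
  tot <- h$count_5p + h$count_3p
  f5 <- ifelse(tot > 0, h$count_5p / tot, NA_real_)
  idx <- match(m$hairpin_id, h$hairpin_id)
  data.frame(name = m$name, arm = m$arm,
             arm_fraction = ifelse(m$arm == "five_prime", f5[idx], 1 - f5[idx]),
             stringsAsFactors = FALSE)
}

#' Reconstruct the miRNA:miR* duplex of a hairpin
#'
#' Given the dominant isomiR interval on each arm, computes the 3' overhangs
#' left at the Drosha end (3' end of the 3p species past the pairing partner
#' of the 5p 5' start) and the Dicer end (3' end of the 5p species past the
#' partner of the 3p 5' start). When an anchor position is unpaired the
#' nearest paired position inward is used and the gap added back; such
#' duplexes carry the `anchored_unpaired` flag. Positive overhangs are 3'
#' overhangs; canonical Drosha/Dicer processing leaves 2 nt at both ends.
#'
#' @param interval_5p,interval_3p Integer c(start, end) of the dominant
#'   species on each arm.
#' @param pt The hairpin's [pair_table()].
#' @return Object of class `duplex_model`: list with `overhang_drosha`,
#'   `overhang_dicer`, `first_nt_paired_5p`, `first_nt_paired_3p`,
#'   `anchored_unpaired`, and the two intervals.
#' @export
reconstruct_duplex <- function(interval_5p, interval_3p, pt) {
  s5 <- interval_5p[1]; e5 <- interval_5p[2]
  s3 <- interval_3p[1]; e3 <- interval_3p[2]
  ov <- duplex_overhangs(s5, e5, s3, e3, pt)
  structure(list(
    interval_5p = c(s5, e5), interval_3p = c(s3, e3),
    overhang_drosha = ov$drosha, overhang_dicer = ov$dicer,
    first_nt_paired_5p = pt$partner[s5] > 0L,
    first_nt_paired_3p = pt$partner[s3] > 0L,
    anchored_unpaired = ov$anchored_unpaired), class = "duplex_model")
}

#' @export
print.duplex_model <- function(x, ...) {
  cat(sprintf("duplex 5p (%d,%d) : 3p (%d,%d) | overhangs drosha %s nt, dicer %s nt\n",
              x$interval_5p[1], x$interval_5p[2], x$interval_3p[1],
              x$interval_3p[2], format(x$overhang_drosha),
              format(x$overhang_dicer)))
  invisible(x)
}

# count unpaired positions of a window clipped to the hairpin
unpaired_in <- function(pt, win) {
  win <- win[win >= 1L & win <= pt$n]
  sum(pt$partner[win] == 0L)
}

#' Classify structural distortions around cleavage boundaries
#'
#' Examines the `window` nt straddling each cleavage boundary on both strands
#' of the reconstructed duplex. All positions paired gives `fully_paired`;
#' equal unpaired counts on both strands give a symmetrical internal loop
#' (`sym_internal_loop_2`, `_4`, or `_other` by total loop size); an unpaired
#' run on one strand only is a `bulge`; otherwise `other`. The Dicer boundary
#' is first checked for terminal-loop adjacency: a duplex end 0 or 1 nt from
#' the terminal loop is `terminal_loop_adjacent(offset)`.
#'
#' @param duplex A [reconstruct_duplex()] result.
#' @param pt The hairpin's [pair_table()].
#' @param window Total straddling window size per strand (default 4: two
#'   positions on each side of the boundary).
#' @return list with `drosha` and `dicer` entries, each
#'   `list(kind = <class>, offset = <loop offset or NA>)`.
#' @export
classify_distortions <- function(duplex, pt, window = 4L) {
  half <- window %/% 2L
  s5 <- duplex$interval_5p[1]; e5 <- duplex$interval_5p[2]
  s3 <- duplex$interval_3p[1]; e3 <- duplex$interval_3p[2]

  site_class <- function(w_guide, w_opp) {
    u1 <- unpaired_in(pt, w_guide)
    u2 <- unpaired_in(pt, w_opp)
    if (u1 == 0L && u2 == 0L) return("fully_paired")
    if (u1 > 0L && u2 > 0L) {
      if (u1 == u2) {
        total <- u1 + u2
        if (total == 2L) return("sym_internal_loop_2")
        if (total == 4L) return("sym_internal_loop_4")
        return("sym_internal_loop_other")
      }
      return("other")
    }
    "bulge"
  }

  # Drosha boundary: 5' strand cut before s5; opposing strand cut after e3
  drosha <- list(
    kind = site_class((s5 - half):(s5 + half - 1L),
                      (e3 - half + 1L):(e3 + half)),
    offset = NA_integer_)

  # Dicer boundary: loop adjacency takes precedence
  off5 <- if (!is.null(pt$loop)) pt$loop[1] - e5 - 1L else NA_integer_
  off3 <- if (!is.null(pt$loop)) s3 - pt$loop[2] - 1L else NA_integer_
  loop_off <- suppressWarnings(min(off5, off3, na.rm = TRUE))
  if (is.finite(loop_off) && loop_off >= 0L && loop_off <= 1L) {
    dicer <- list(kind = "terminal_loop_adjacent", offset = as.integer(loop_off))
  } else {
    dicer <- list(
      kind = site_class((e5 - half + 1L):(e5 + half),
                        (s3 - half):(s3 + half - 1L)),
      offset = NA_integer_)
  }
  list(drosha = drosha, dicer = dicer)
}

#' Duplex models and distortion classes for a whole summary
#'
#' Applies [reconstruct_duplex()] and [classify_distortions()] to every
#' hairpin expressing both arms (taking the dominant isomiR interval per
#' arm); single-arm hairpins are counted separately.
#'
#' @param summary A [summarize_hairpins()] result.
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return list with `duplexes` (data.frame: hairpin, intervals, overhangs,
#'   pairing flags, distortion kinds) and `single_arm` (hairpin ids).
#' @export
duplex_models <- function(summary, reference, config = census_config()) {
  m <- summary$mirna
  rows <- list()
  single <- character(0)
  for (hp in unique(m$hairpin_id)) {
    d <- m[m$hairpin_id == hp, , drop = FALSE]
    arms <- split(d, d$arm)
    if (is.null(arms$five_prime) || is.null(arms$three_prime)) {
      single <- c(single, hp)
      next
    }
    top5 <- arms$five_prime[which.max(arms$five_prime$total), ]
    top3 <- arms$three_prime[which.max(arms$three_prime$total), ]
    pt <- reference$pair_tables[[hp]]
    dup <- reconstruct_duplex(c(top5$dom_start, top5$dom_end),
                              c(top3$dom_start, top3$dom_end), pt)
    dist <- classify_distortions(dup, pt, config$distortion_window)
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = hp,
      start_5p = top5$dom_start, end_5p = top5$dom_end,
      start_3p = top3$dom_start, end_3p = top3$dom_end,
      overhang_drosha = dup$overhang_drosha,
      overhang_dicer = dup$overhang_dicer,
      first_nt_paired_5p = dup$first_nt_paired_5p,
      first_nt_paired_3p = dup$first_nt_paired_3p,
      anchored_unpaired = dup$anchored_unpaired,
      drosha_class = dist$drosha$kind,
      dicer_class = dist$dicer$kind,
      dicer_loop_offset = dist$dicer$offset,
      stringsAsFactors = FALSE)
  }
  duplexes <- if (length(rows)) do.call(rbind, rows) else
    empty_df(list(hairpin_id = character, start_5p = integer, end_5p = integer,
                  start_3p = integer, end_3p = integer,
                  overhang_drosha = numeric, overhang_dicer = numeric,
                  first_nt_paired_5p = logical, first_nt_paired_3p = logical,
                  anchored_unpaired = logical, drosha_class = character,
                  dicer_class = character, dicer_loop_offset = integer))
  rownames(duplexes) <- NULL
  list(duplexes = duplexes, single_arm = single)
}
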