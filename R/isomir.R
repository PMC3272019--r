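# Operational taxonomy of miRNA variants: generic calls with 5'/3' offsets,
# novel miR*, extreme isomiRs (e-miRs), and per-hairpin summaries.

CLASS_PRIORITY <- c(mature = 1L, star = 2L, p5 = 3L, p3 = 4L, none = 5L)

#' Assign the variant taxonomy label to resolved sense placements
#'
#' A tag whose 5' start lies within +/- `generic_window` nt of a same-arm
#' annotated miRNA 5' end is a generic call anchored on that annotation (ties
#' go to the smaller absolute 5' offset, then mature over star over -5p/-3p).
#' Non-generic tags on an arm that carries an annotation become e-miR
#' candidates; tags on an arm without any annotation become novel-miR*
#' candidates; loop-spanning tags are left unassigned and flagged as
#' AGO2-processing candidates. Offsets are signed: `five_prime_offset` =
#' tag start - annotated start (negative = 5'-extended), `three_prime_offset`
#' = tag end - annotated end, both measured along the hairpin 5'-to-3' axis
#' against the anchor annotation.
#'
#' @param placements Resolved placements (sense hairpin rows are used).
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return data.frame of feature calls: placement columns plus `arm`, `label`,
#'   `anchor_name`, `anchor_class`, `five_prime_offset`, `three_prime_offset`,
#'   `weighted_count`.
#' @export
assign_features <- function(placements, reference, config = census_config()) {
  pl <- placements[placements$target_type == "hairpin" &
                     placements$strand == "sense", , drop = FALSE]
  n <- nrow(pl)
  arm <- character(n); label <- character(n)
  anchor_name <- character(n); anchor_class <- character(n)
  off5 <- rep(NA_integer_, n); off3 <- rep(NA_integer_, n)
  ann_all <- reference$annotations
  for (i in seq_len(n)) {
    hp <- pl$target_id[i]
    pt <- reference$pair_tables[[hp]]
    ann <- ann_all[ann_all$hairpin_id == hp, , drop = FALSE]
    # generic membership is decided by 5' start proximity alone, so a tag
    # whose 3' extension dips into the loop still anchors on its annotation
    d5 <- pl$start[i] - ann$start
    gen <- abs(d5) <= config$generic_window
    if (nrow(ann) && any(gen)) {
      cand <- which(gen)
      ord <- order(abs(d5[cand]), CLASS_PRIORITY[ann$class[cand]])
      j <- cand[ord[1]]
      arm[i] <- ann$arm[j]
      label[i] <- paste0("generic_", ann$class[j])
      anchor_name[i] <- ann$name[j]
      anchor_class[i] <- ann$class[j]
      off5[i] <- d5[j]
      off3[i] <- pl$end[i] - ann$end[j]
      next
    }
    a <- arm_of(pl$start[i], pl$end[i], pt)
    arm[i] <- a
    anchor_name[i] <- ""; anchor_class[i] <- ""
    if (a == "loop_spanning") {
      label[i] <- "unassigned"
    } else if (nrow(ann[ann$arm == a, ]) > 0L) {
      label[i] <- "emir_candidate"
    } else if (nrow(ann[ann$arm != a, ]) > 0L) {
      label[i] <- "novel_star_candidate"
    } else {
      label[i] <- "unassigned"
    }
  }
  out <- pl
  out$arm <- arm
  out$label <- label
  out$anchor_name <- anchor_name
  out$anchor_class <- anchor_class
  out$five_prime_offset <- off5
  out$three_prime_offset <- off3
  out$weighted_count <- out$weight * out$count
  out$flags <- ifelse(out$label == "unassigned" & out$arm == "loop_spanning",
                      ifelse(out$flags == "", "loop_spanning",
                             paste(out$flags, "loop_spanning", sep = ",")),
                      out$flags)
  rownames(out) <- NULL
  out
}

#' Summarize feature calls per miRNA and per hairpin
#'
#' For each anchor miRNA: total weighted count, 5'- and 3'-isomiR proportions
#' among its generic tags (fraction of weighted tags with a non-zero offset),
#' weighted length histogram, long-tag proportion (> `long_tag_len` nt),
#' dominant isomiR interval, and flags: `high_5p_isomir` / `high_3p_isomir`
#' above 20%, `extreme_*` above 80%, `long_mirna` when the long-tag
#' proportion exceeds 20%. Per-hairpin arm totals (generic tags only) are
#' returned alongside.
#'
#' @param calls Output of [assign_features()].
#' @param config A [census_config()].
#' @return Object of class `hairpin_summary`: list with `mirna` (per-miRNA
#'   data.frame), `hairpin` (per-hairpin arm totals), `length_hist` (named
#'   list of weighted length tables).
#' @export
summarize_hairpins <- function(calls, config = census_config()) {
  gen <- calls[startsWith(calls$label, "generic_"), , drop = FALSE]
  mirnas <- unique(gen[, c("target_id", "anchor_name", "anchor_class", "arm")])
  rows <- list()
  hists <- list()
  for (i in seq_len(nrow(mirnas))) {
    g <- gen[gen$anchor_name == mirnas$anchor_name[i] &
               gen$target_id == mirnas$target_id[i], , drop = FALSE]
    w <- g$weighted_count
    tot <- sum(w)
    p5iso <- sum(w[g$five_prime_offset != 0]) / tot
    p3iso <- sum(w[g$three_prime_offset != 0]) / tot
    len <- nchar(g$tag_seq)
    hist <- tapply(w, len, sum)
    long_prop <- sum(w[len > config$long_tag_len]) / tot
    ikey <- paste(g$start, g$end)
    dom <- names(which.max(tapply(w, ikey, sum)))
    dom_se <- as.integer(strsplit(dom, " ")[[1]])
    flags <- c(
      if (p5iso > 0.20) "high_5p_isomir",
      if (p5iso > 0.80) "extreme_5p_isomir",
      if (p3iso > 0.20) "high_3p_isomir",
      if (p3iso > 0.80) "extreme_3p_isomir",
      if (long_prop > 0.20) "long_mirna")
    rows[[i]] <- data.frame(
      hairpin_id = mirnas$target_id[i], name = mirnas$anchor_name[i],
      class = mirnas$anchor_class[i], arm = mirnas$arm[i],
      total = tot, p5_isomir_prop = p5iso, p3_isomir_prop = p3iso,
      modal_length = weighted_mode(len, w), long_prop = long_prop,
      dom_start = dom_se[1], dom_end = dom_se[2],
      flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
    hists[[mirnas$anchor_name[i]]] <- hist
  }
  mirna <- if (length(rows)) do.call(rbind, rows) else
    empty_df(list(hairpin_id = character, name = character, class = character,
                  arm = character, total = numeric, p5_isomir_prop = numeric,
                  p3_isomir_prop = numeric, modal_length = numeric,
                  long_prop = numeric, dom_start = integer, dom_end = integer,
                  flags = character))
  mirna <- mirna[order(-mirna$total, mirna$name), , drop = FALSE]
  rownames(mirna) <- NULL

  # per-hairpin arm totals over generic tags
  hp_ids <- unique(calls$target_id)
  hairpin <- data.frame(
    hairpin_id = hp_ids,
    count_5p = vapply(hp_ids, function(h)
      sum(gen$weighted_count[gen$target_id == h & gen$arm == "five_prime"]),
      numeric(1)),
    count_3p = vapply(hp_ids, function(h)
      sum(gen$weighted_count[gen$target_id == h & gen$arm == "three_prime"]),
      numeric(1)),
    total_all = vapply(hp_ids, function(h)
      sum(calls$weighted_count[calls$target_id == h]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(hairpin) <- NULL
  structure(list(mirna = mirna, hairpin = hairpin, length_hist = hists),
            class = "hairpin_summary")
}

#' @export
print.hairpin_summary <- function(x, ...) {
  cat(sprintf("hairpin_summary: %d miRNAs on %d hairpins, %.0f weighted generic tags\n",
              nrow(x$mirna), nrow(x$hairpin), sum(x$mirna$total)))
  invisible(x)
}

# phasing of a tag set: modal 5' start (+/- window) share of weighted count
phase_stats <- function(starts, weights, window = 1L) {
  m <- weighted_mode(starts, weights)
  frac <- sum(weights[abs(starts - m) <= window]) / sum(weights)
  list(modal_start = m, phase_fraction = frac)
}

# dominant exact interval of a tag set
dominant_interval <- function(starts, ends, weights) {
  key <- paste(starts, ends)
  dom <- names(which.max(tapply(weights, key, sum)))
  as.integer(strsplit(dom, " ")[[1]])
}

#' Detect novel miR* species
#'
#' On hairpin arms without any annotation but whose opposite arm carries a
#' known miRNA, a well-phased tag set (modal 5' start +/- 1 nt holding at
#' least half the weighted count, minimum 10 weighted tags) is called a novel
#' miR*. If its dominant interval forms a duplex with the opposite-arm
#' annotation consistent with canonical 2-nt 3' overhangs it is upgraded to a
#' novel generic miR* ("directly juxtaposed" to the known miRNA).
#'
#' @param calls Output of [assign_features()].
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return data.frame of novel miR* calls with geometry and phasing columns.
#' @export
detect_novel_star <- function(calls, reference, config = census_config()) {
  cand <- calls[calls$label == "novel_star_candidate", , drop = FALSE]
  proto <- list(hairpin_id = character, name = character, arm = character,
                start = integer, end = integer, weighted_count = numeric,
                phase_fraction = numeric, overhang_drosha = numeric,
                overhang_dicer = numeric, label = character)
  if (nrow(cand) == 0L) return(empty_df(proto))
  out <- list()
  for (hp in unique(cand$target_id)) {
    for (a in unique(cand$arm[cand$target_id == hp])) {
      g <- cand[cand$target_id == hp & cand$arm == a, , drop = FALSE]
      w <- g$weighted_count
      if (sum(w) < config$phase_min_tags) next
      ph <- phase_stats(g$start, w, config$phase_window)
      if (ph$phase_fraction < config$phase_min_fraction) next
      dom <- dominant_interval(g$start, g$end, w)
      ann <- reference$annotations
      opp <- ann[ann$hairpin_id == hp & ann$arm != a, , drop = FALSE]
      if (nrow(opp) == 0L) next
      opp <- opp[order(CLASS_PRIORITY[opp$class]), , drop = FALSE][1, ]
      pt <- reference$pair_tables[[hp]]
      if (a == "five_prime") {
        dx <- duplex_overhangs(dom[1], dom[2], opp$start, opp$end, pt)
      } else {
        dx <- duplex_overhangs(opp$start, opp$end, dom[1], dom[2], pt)
      }
      canonical <- !is.na(dx$drosha) && !is.na(dx$dicer) &&
        abs(dx$drosha - config$star_overhang) <= config$star_geom_tol &&
        abs(dx$dicer - config$star_overhang) <= config$star_geom_tol
      out[[length(out) + 1L]] <- data.frame(
        hairpin_id = hp, name = paste0(opp$name, "*"), arm = a,
        start = dom[1], end = dom[2], weighted_count = sum(w),
        phase_fraction = ph$phase_fraction,
        overhang_drosha = dx$drosha, overhang_dicer = dx$dicer,
        label = if (canonical) "novel_generic_star" else "novel_star",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_df(proto))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

emir_name <- function(hairpin_id) {
  core <- sub("^[A-Za-z]{2,4}-", "", hairpin_id)
  core <- sub("^mir-?", "", core, ignore.case = TRUE)
  paste0("e-miR-", core)
}

#' Detect extreme isomiRs (e-miRs)
#'
#' On hairpins passing the stringent expression threshold, non-generic tag
#' sets (tags outside the generic window of every annotation, grouped per
#' hairpin region: 5' arm, 3' arm or loop) are reported as e-miRs when they
#' reach `emir_min_fraction` of the hairpin's weighted tags and pass the
#' credibility filters: modal length within `emir_len_range` and phase
#' fraction at least `phase_min_fraction`. Loop-overlapping e-miRs are
#' flagged as AGO2-processing candidates.
#'
#' @param calls Output of [assign_features()].
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return data.frame of e-miR calls.
#' @export
detect_emir <- function(calls, reference, config = census_config()) {
  proto <- list(hairpin_id = character, name = character, region = character,
                start = integer, end = integer, weighted_count = numeric,
                fraction = numeric, phase_fraction = numeric,
                modal_length = numeric, flags = character)
  res <- list()
  for (hp in unique(calls$target_id)) {
    hp_calls <- calls[calls$target_id == hp, , drop = FALSE]
    total <- sum(hp_calls$weighted_count)
    if (total < config$min_expression) next
    cand <- hp_calls[hp_calls$label %in% c("emir_candidate", "unassigned"), ,
                     drop = FALSE]
    if (nrow(cand) == 0L) next
    for (region in unique(cand$arm)) {
      g <- cand[cand$arm == region, , drop = FALSE]
      w <- g$weighted_count
      frac <- sum(w) / total
      if (frac < config$emir_min_fraction) next
      ph <- phase_stats(g$start, w, config$phase_window)
      if (ph$phase_fraction < config$phase_min_fraction) next
      mlen <- weighted_mode(nchar(g$tag_seq), w)
      if (mlen < config$emir_len_range[1] || mlen > config$emir_len_range[2]) next
      dom <- dominant_interval(g$start, g$end, w)
      pt <- reference$pair_tables[[hp]]
      on_loop <- !is.null(pt$loop) &&
        dom[1] <= pt$loop[2] && dom[2] >= pt$loop[1]
      res[[length(res) + 1L]] <- data.frame(
        hairpin_id = hp, name = emir_name(hp), region = region,
        start = dom[1], end = dom[2], weighted_count = sum(w),
        fraction = frac, phase_fraction = ph$phase_fraction,
        modal_length = mlen,
        flags = if (on_loop) "AGO2-candidate" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_df(proto))
  out <- do.call(rbind, res)
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a plain-text hairpin alignment block
#'
#' Shows the hairpin sequence and structure with tags stacked underneath at
#' their aligned columns, sorted by decreasing weighted count. Mismatched tag
#' bases (including non-templated additions) are lowercased.
#'
#' @param reference A `hairpin_set`.
#' @param hairpin_id Hairpin to render.
#' @param calls Feature calls (any subset containing this hairpin).
#' @param max_tags Maximum tag lines.
#' @return Character vector of lines (also of class `hairpin_alignment` with
#'   a cat-based print method).
#' @export
render_hairpin_alignment <- function(reference, hairpin_id, calls,
                                     max_tags = 50L) {
  g <- calls[calls$target_id == hairpin_id, , drop = FALSE]
  g <- g[order(-g$weighted_count, g$start), , drop = FALSE]
  if (nrow(g) > max_tags) g <- g[seq_len(max_tags), , drop = FALSE]
  lines <- c(paste0(">", hairpin_id),
             reference$seq[[hairpin_id]],
             reference$structure[[hairpin_id]])
  for (i in seq_len(nrow(g))) {
    tag <- g$tag_seq[i]
    mm <- decode_mismatches(g$mismatches[i])
    if (nrow(mm)) {
      chars <- strsplit(tag, "")[[1]]
      chars[mm$pos] <- tolower(chars[mm$pos])
      tag <- paste(chars, collapse = "")
    }
    lines <- c(lines, paste0(strrep(" ", g$start[i] - 1L), tag,
                             sprintf("  x%.6g [%s]", g$weighted_count[i],
                                     g$label[i])))
  }
  structure(lines, class = c("hairpin_alignment", "character"))
}

#' @export
print.hairpin_alignment <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
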