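# Novel miRNA discovery from phased genomic tag clusters, and antisense
# miRNA detection over known hairpin loci.

#' Cluster genome-mapped tags
#'
#' Size-selects placements to 18-26 nt, then groups them per (chromosome,
#' strand) into windows of `cluster_window` nt around modal 5' starts
#' (greedy, most abundant start first). The 5' anchor of an antisense
#' placement is its genomic end. Clusters below `cluster_min_count` weighted
#' tags or with phase fraction below `phase_min_fraction` are discarded.
#'
#' @param placements Genome placements from [align_to_genome()], MMR-resolved.
#' @param config A [census_config()].
#' @return data.frame of clusters: chrom, strand, modal_start (5' anchor),
#'   span_start/span_end, dominant interval, weighted_count, phase_fraction.
#' @export
cluster_genome_tags <- function(placements, config = census_config()) {
  proto <- list(cluster_id = character, chrom = character, strand = character,
                modal_start = integer, span_start = integer, span_end = integer,
                dom_start = integer, dom_end = integer,
                weighted_count = numeric, phase_fraction = numeric,
                modal_length = numeric)
  pl <- placements[placements$target_type == "genome", , drop = FALSE]
  len <- nchar(pl$tag_seq)
  pl <- pl[len >= 18L & len <= 26L, , drop = FALSE]
  if (nrow(pl) == 0L) return(empty_df(proto))
  pl$w <- pl$weight * pl$count
  pl$anchor <- ifelse(pl$strand == "sense", pl$start, pl$end)
  out <- list()
  for (key in unique(paste(pl$target_id, pl$strand))) {
    part <- strsplit(key, " ")[[1]]
    g <- pl[pl$target_id == part[1] & pl$strand == part[2], , drop = FALSE]
    while (nrow(g) > 0L) {
      m <- weighted_mode(g$anchor, g$w)
      member <- abs(g$anchor - m) <= config$cluster_window
      cl <- g[member, , drop = FALSE]
      g <- g[!member, , drop = FALSE]
      tot <- sum(cl$w)
      frac <- sum(cl$w[abs(cl$anchor - m) <= config$phase_window]) / tot
      dom <- dominant_interval(cl$start, cl$end, cl$w)
      if (tot >= config$cluster_min_count && frac >= config$phase_min_fraction) {
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = "", chrom = part[1], strand = part[2],
          modal_start = as.integer(m),
          span_start = min(cl$start), span_end = max(cl$end),
          dom_start = dom[1], dom_end = dom[2],
          weighted_count = tot, phase_fraction = frac,
          modal_length = weighted_mode(nchar(cl$tag_seq), cl$w),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_df(proto))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$span_start, res$strand), , drop = FALSE]
  res$cluster_id <- sprintf("cl%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Fold genomic windows around a tag cluster
#'
#' Extracts windows of the configured lengths placed so that the cluster sits
#' first on the 5' arm, then on the 3' arm of a putative hairpin, in the
#' cluster's strand orientation (antisense windows are reverse-complemented),
#' folds each with the configured backend, and retains the best-scoring fold.
#' Windows truncated at a chromosome end are flagged.
#'
#' @param genome Named character vector of chromosomes.
#' @param cluster One row of [cluster_genome_tags()] output.
#' @param config A [census_config()].
#' @return list of class `folded_window`: window genomic coordinates, strand,
#'   `sequence`, `structure`, `score`, `cand_start`/`cand_end` (the cluster's
#'   dominant interval in window coordinates) and a `truncated` flag.
#' @export
fold_window <- function(genome, cluster, config = census_config()) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  genome <- normalize_seq(genome)
  chrom <- genome[[cluster$chrom]]
  n <- nchar(chrom)
  pad <- 15L
  best <- NULL
  for (L in config$fold_window_lengths) {
    for (side in c("five_prime", "three_prime")) {
      if (cluster$strand == "sense") {
        if (side == "five_prime") {
          ws <- cluster$dom_start - pad
        } else {
          ws <- cluster$dom_end + pad - L + 1L
        }
      } else {
        # in tag orientation the 5' side is the genomic right
        if (side == "five_prime") {
          ws <- cluster$dom_end + pad - L + 1L
        } else {
          ws <- cluster$dom_start - pad
        }
      }
      we <- ws + L - 1L
      truncated <- ws < 1L || we > n
      ws_c <- max(1L, ws); we_c <- min(n, we)
      if (we_c - ws_c + 1L < 40L) next
      seq <- substr(chrom, ws_c, we_c)
      if (cluster$strand == "antisense") seq <- revcomp(seq)
      fold <- fold_sequence(seq, backend = config$fold_backend)
      if (is.null(best) || fold$score > best$score) {
        if (cluster$strand == "sense") {
          cs <- cluster$dom_start - ws_c + 1L
          ce <- cluster$dom_end - ws_c + 1L
        } else {
          cs <- we_c - cluster$dom_end + 1L
          ce <- we_c - cluster$dom_start + 1L
        }
        best <- list(chrom = cluster$chrom, window_start = ws_c,
                     window_end = we_c, strand = cluster$strand,
                     sequence = seq, structure = fold$structure,
                     score = fold$score, cand_start = cs, cand_end = ce,
                     truncated = truncated)
      }
    }
  }
  if (!is.null(best)) class(best) <- "folded_window"
  best
}

# longest contiguous helix (consecutive stacked pairs) spanning a given
# hairpin loop: the operational "stem length" criterion
stem_length <- function(pt, loop = pt$loop) {
  if (is.null(loop)) return(0L)
  pairs <- which(pt$partner > seq_len(pt$n) &
                   seq_len(pt$n) < loop[1] & pt$partner > loop[2])
  if (!length(pairs)) return(0L)
  best <- run <- 1L
  for (k in seq_along(pairs)[-1]) {
    stacked <- pairs[k] == pairs[k - 1L] + 1L &&
      pt$partner[pairs[k]] == pt$partner[pairs[k - 1L]] - 1L
    run <- if (stacked) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Evaluate a folded window as a miRNA hairpin candidate
#'
#' Mandatory criteria (each individually reported): the candidate interval
#' lies entirely on one arm of the fold; at least `cand_min_paired_frac` of
#' candidate bases are paired; the terminal loop length is within
#' `cand_loop_range`; the stem holds at least `cand_min_stem` contiguous base
#' pairs spanning the loop; and the cluster's modal tag length is within
#' `cand_len_range`. Support by a second cluster at the canonical 2-nt
#' 3'-overhang duplex position is recorded as a confidence bonus, not a
#' requirement.
#'
#' @param cluster One cluster row.
#' @param folded A [fold_window()] result (NULL rejects with `no_stem`).
#' @param config A [census_config()].
#' @param star_clusters Optional data.frame of other clusters searched for
#'   miR* support.
#' @return list of class `hairpin_candidate` with `verdict` (`accepted` or
#'   `rejected`), `reason`, per-criterion flags and the candidate geometry.
#' @export
evaluate_candidate <- function(cluster, folded, config = census_config(),
                               star_clusters = NULL) {
  fail <- function(reason, flags = list()) {
    structure(list(cluster_id = cluster$cluster_id, verdict = "rejected",
                   reason = reason, flags = flags, folded = folded,
                   star_support = FALSE), class = "hairpin_candidate")
  }
  if (is.null(folded)) return(fail("no_stem"))
  pt <- suppressWarnings(pair_table(folded$structure))
  if (length(pt$loops) == 0L) return(fail("no_stem"))
  cs <- folded$cand_start; ce <- folded$cand_end
  # a window fold can hold several hairpin loops; judge the candidate
  # against the one with the strongest spanning helix
  stems <- vapply(pt$loops, function(l) stem_length(pt, l), integer(1))
  loop <- pt$loops[[which.max(stems)]]
  arm <- if (min(pt$n, ce) < loop[1]) "five_prime"
    else if (max(1L, cs) > loop[2]) "three_prime"
    else "loop_spanning"
  flags <- list(
    on_one_arm = arm %in% c("five_prime", "three_prime"),
    paired_frac = sum(pt$partner[max(1L, cs):min(pt$n, ce)] > 0L) /
      (ce - cs + 1L),
    loop_len = loop[2] - loop[1] + 1L,
    stem_pairs = max(stems),
    modal_length = cluster$modal_length)
  if (!flags$on_one_arm) return(fail("loop_overlap", flags))
  if (flags$paired_frac < config$cand_min_paired_frac)
    return(fail("low_pairing", flags))
  if (flags$loop_len < config$cand_loop_range[1] ||
      flags$loop_len > config$cand_loop_range[2])
    return(fail("loop_size", flags))
  if (flags$stem_pairs < config$cand_min_stem) return(fail("short_stem", flags))
  if (flags$modal_length < config$cand_len_range[1] ||
      flags$modal_length > config$cand_len_range[2])
    return(fail("length", flags))

  star <- FALSE
  if (!is.null(star_clusters) && nrow(star_clusters)) {
    # expected star interval: duplex position with canonical 2-nt overhangs
    # (star_start = partner(cand_end - 2), star_end = partner(cand_start) + 2)
    exp5 <- partner_est(pt, ce - config$star_overhang, +1L)$partner
    exp3 <- partner_est(pt, cs, +1L)$partner + config$star_overhang
    for (k in seq_len(nrow(star_clusters))) {
      sc <- star_clusters[k, ]
      if (sc$chrom != cluster$chrom || sc$strand != cluster$strand) next
      if (cluster$strand == "sense") {
        scs <- sc$dom_start - folded$window_start + 1L
        sce <- sc$dom_end - folded$window_start + 1L
      } else {
        scs <- folded$window_end - sc$dom_end + 1L
        sce <- folded$window_end - sc$dom_start + 1L
      }
      if (!is.na(exp5) && !is.na(exp3) &&
          abs(scs - exp5) <= 2L && abs(sce - exp3) <= 2L) {
        star <- TRUE
        break
      }
    }
  }
  structure(list(cluster_id = cluster$cluster_id, verdict = "accepted",
                 reason = "", flags = flags, folded = folded,
                 star_support = star, arm = arm),
            class = "hairpin_candidate")
}

#' Discover novel miRNA candidates genome-wide
#'
#' Clusters genome placements, folds windows around each cluster, evaluates
#' candidates, and names accepted loci miR-N1, miR-N2, ... in coordinate
#' order (stable under re-runs).
#'
#' @param placements Genome placements (MMR-resolved).
#' @param genome Named character vector of chromosomes.
#' @param config A [census_config()].
#' @return list with `candidates` (data.frame report, one row per cluster
#'   with verdict and criteria), `accepted` (accepted subset) and `details`
#'   (list of `hairpin_candidate` objects).
#' @export
discover_novel <- function(placements, genome, config = census_config()) {
  clusters <- cluster_genome_tags(placements, config)
  details <- list()
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    folded <- fold_window(genome, cl, config)
    cand <- evaluate_candidate(cl, folded, config,
                               star_clusters = clusters[-i, , drop = FALSE])
    details[[cl$cluster_id]] <- cand
    rows[[i]] <- data.frame(
      cluster_id = cl$cluster_id, chrom = cl$chrom, strand = cl$strand,
      dom_start = cl$dom_start, dom_end = cl$dom_end,
      weighted_count = cl$weighted_count,
      phase_fraction = cl$phase_fraction,
      verdict = cand$verdict, reason = cand$reason,
      star_support = isTRUE(cand$star_support),
      stem_pairs = if (length(cand$flags)) cand$flags$stem_pairs else NA_integer_,
      name = NA_character_, stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    empty_df(list(cluster_id = character, chrom = character, strand = character,
                  dom_start = integer, dom_end = integer,
                  weighted_count = numeric, phase_fraction = numeric,
                  verdict = character, reason = character,
                  star_support = logical, stem_pairs = integer,
                  name = character))
  # link accepted clusters from the two arms of one hairpin into one locus:
  # clusters within 120 nt on the same chromosome and strand are grouped,
  # the most abundant is the named candidate, the other its miR* partner
  candidates$is_star <- FALSE
  acc_idx <- which(candidates$verdict == "accepted")
  if (length(acc_idx)) {
    acc_idx <- acc_idx[order(-candidates$weighted_count[acc_idx])]
    primaries <- integer(0)
    for (i in acc_idx) {
      near <- primaries[candidates$chrom[primaries] == candidates$chrom[i] &
                          candidates$strand[primaries] == candidates$strand[i] &
                          abs(candidates$dom_start[primaries] -
                                candidates$dom_start[i]) <= 120L]
      if (length(near)) {
        candidates$is_star[i] <- TRUE
        candidates$name[i] <- paste0(candidates$name[near[1]], "*")
        candidates$star_support[near[1]] <- TRUE
      } else {
        primaries <- c(primaries, i)
      }
    }
    ord <- order(candidates$chrom[primaries], candidates$dom_start[primaries])
    candidates$name[primaries[ord]] <- sprintf("miR-N%d", seq_along(primaries))
    # star partners inherit their primary's final name
    for (i in which(candidates$is_star)) {
      near <- primaries[candidates$chrom[primaries] == candidates$chrom[i] &
                          candidates$strand[primaries] == candidates$strand[i] &
                          abs(candidates$dom_start[primaries] -
                                candidates$dom_start[i]) <= 120L]
      if (length(near)) candidates$name[i] <- paste0(candidates$name[near[1]], "*")
    }
  }
  rownames(candidates) <- NULL
  acc <- candidates$verdict == "accepted" & !candidates$is_star
  list(candidates = candidates,
       accepted = candidates[acc, , drop = FALSE],
       details = details)
}

#' Detect antisense miRNAs over known hairpin loci
#'
#' For each hairpin with antisense placements, the reverse complement of the
#' hairpin is folded and evaluated with the discovery criteria against the
#' dominant phased antisense tag set; at least one tag must map to the
#' opposing arm of the antisense hairpin. Accepted candidates are named
#' `<hairpin>-as`.
#'
#' @param placements Hairpin placements (MMR-resolved; antisense rows used).
#' @param reference A `hairpin_set`.
#' @param config A [census_config()].
#' @return data.frame of antisense candidates with verdicts.
#' @export
detect_antisense <- function(placements, reference, config = census_config()) {
  proto <- list(hairpin_id = character, name = character,
                weighted_count = numeric, phase_fraction = numeric,
                verdict = character, reason = character)
  as_pl <- placements[placements$target_type == "hairpin" &
                        placements$strand == "antisense", , drop = FALSE]
  if (nrow(as_pl) == 0L) return(empty_df(proto))
  as_pl$w <- as_pl$weight * as_pl$count
  rows <- list()
  for (hp in unique(as_pl$target_id)) {
    g <- as_pl[as_pl$target_id == hp, , drop = FALSE]
    n <- nchar(reference$seq[[hp]])
    # map into antisense-hairpin coordinates (revcomp of the locus)
    g$as_start <- n - g$end + 1L
    g$as_end <- n - g$start + 1L
    # the antisense screen uses the stringent expression threshold, so that
    # low-level mismapped tags (e.g. error tags resolving antisense) do not
    # nominate loci
    if (sum(g$w) < config$min_expression) next
    fold <- fold_sequence(revcomp(reference$seq[[hp]]),
                          backend = config$fold_backend)
    pt <- suppressWarnings(pair_table(fold$structure))
    arm <- if (is.null(pt$loop)) rep("loop_spanning", nrow(g)) else
      vapply(seq_len(nrow(g)), function(i)
        arm_of(g$as_start[i], g$as_end[i], pt), character(1))
    dom_arm <- names(which.max(tapply(g$w, arm, sum)))
    opposing <- setdiff(c("five_prime", "three_prime"), dom_arm)
    has_opposing <- length(opposing) == 1L && any(arm == opposing)
    d <- g[arm == dom_arm, , drop = FALSE]
    ph <- phase_stats(d$as_start, d$w, config$phase_window)
    dom <- dominant_interval(d$as_start, d$as_end, d$w)
    verdict <- "accepted"; reason <- ""
    if (!has_opposing) {
      verdict <- "rejected"; reason <- "no_opposing_tag"
    } else if (ph$phase_fraction < config$phase_min_fraction) {
      verdict <- "rejected"; reason <- "poor_phasing"
    } else {
      pseudo <- data.frame(cluster_id = paste0(hp, "-as"), chrom = hp,
                           strand = "sense", modal_start = ph$modal_start,
                           span_start = min(d$as_start),
                           span_end = max(d$as_end),
                           dom_start = dom[1], dom_end = dom[2],
                           weighted_count = sum(d$w),
                           phase_fraction = ph$phase_fraction,
                           modal_length = weighted_mode(nchar(d$tag_seq), d$w),
                           stringsAsFactors = FALSE)
      folded <- list(chrom = hp, window_start = 1L, window_end = n,
                     strand = "sense", sequence = revcomp(reference$seq[[hp]]),
                     structure = fold$structure, score = fold$score,
                     cand_start = dom[1], cand_end = dom[2],
                     truncated = FALSE)
      class(folded) <- "folded_window"
      cand <- evaluate_candidate(pseudo, folded, config)
      verdict <- cand$verdict; reason <- cand$reason
    }
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = hp, name = paste0(hp, "-as"),
      weighted_count = sum(g$w), phase_fraction = ph$phase_fraction,
      verdict = verdict, reason = reason, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_df(proto))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write discovery outputs
#'
#' Writes a BED file of candidate loci, a TSV criteria report, and FASTA plus
#' dot-bracket files of the candidate hairpins.
#'
#' @param discovery A [discover_novel()] result.
#' @param dir Output directory (created if needed).
#' @export
write_discovery <- function(discovery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cand <- discovery$candidates
  utils::write.table(cand, file.path(dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  acc <- discovery$accepted
  if (nrow(acc)) {
    bed <- data.frame(chrom = acc$chrom, start = acc$dom_start - 1L,
                      end = acc$dom_end, name = acc$name,
                      score = round(acc$weighted_count),
                      strand = ifelse(acc$strand == "sense", "+", "-"))
    utils::write.table(bed, file.path(dir, "candidates.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    fa <- character(0); db <- character(0)
    for (id in acc$cluster_id) {
      f <- discovery$details[[id]]$folded
      nm <- acc$name[acc$cluster_id == id]
      fa <- c(fa, paste0(">", nm), f$sequence)
      db <- c(db, paste0(">", nm), f$structure)
    }
    writeLines(fa, file.path(dir, "candidates.fa"))
    writeLines(db, file.path(dir, "candidates.dot"))
  }
  invisible(dir)
}
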