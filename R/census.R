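#' Run the full miRNA variant census
#'
#' End-to-end pipeline: collapse reads to tags, align them to the hairpin
#' reference (both strands), resolve mismatches and multimapping, classify
#' mismatch types, apply the variant taxonomy, summarize per miRNA and per
#' hairpin, categorize arm strand bias, build terminal-composition profiles
#' and tests, reconstruct duplexes with distortion classes, call novel miR*
#' and e-miRs, and — when a genome is supplied — map leftover tags to it and
#' run novel-locus discovery and the antisense screen.
#'
#' @param reads Path to a FASTA/FASTQ file or a character vector of
#'   adapter-trimmed reads.
#' @param reference A `hairpin_set` (see [read_hairpin_reference()]).
#' @param config A [census_config()].
#' @param genome Optional named character vector (or DNAStringSet) of
#'   chromosomes for discovery.
#' @param library_id Library label.
#' @return Object of class `mir_census` with components `tags`, `placements`,
#'   `calls`, `summary`, `arm_bias`, `profiles`, `composition`, `duplexes`,
#'   `novel_star`, `emir`, `antisense`, `discovery`, `class_split`, `config`
#'   and `stats`.
#' @export
#' @examples
#' spec <- sim_spec(n_hairpins = 4, n_reads = 2000, novel = NULL,
#'                  antisense = NULL, emir = NULL, seed = 3)
#' ref <- sim_reference(spec)
#' lib <- simulate_library(ref)
#' cen <- mir_census(lib$reads, ref$hairpins)
#' cen
mir_census <- function(reads, reference, config = census_config(),
                       genome = NULL, library_id = "lib1") {
  tags <- collapse_reads(reads, config$min_tag_len, config$max_tag_len,
                         library_id)
  pl_hp <- align_to_hairpins(tags, reference, config$max_mismatches)
  placed <- unique(pl_hp$tag_seq)
  unplaced <- tags[!(tags$sequence %in% placed), , drop = FALSE]
  pl_gen <- NULL
  if (!is.null(genome) && nrow(unplaced)) {
    pl_gen <- align_to_genome(unplaced, genome, config$max_mismatches,
                              config$multimap_cap)
  }
  placements <- if (!is.null(pl_gen) && nrow(pl_gen)) rbind(pl_hp, pl_gen)
    else pl_hp
  placements <- mmr_resolve(placements)
  placements <- classify_mismatches(placements)

  calls <- assign_features(placements, reference, config)
  summary <- summarize_hairpins(calls, config)
  arm_bias <- compute_arm_bias(summary, reference, config)
  profiles <- build_position_profiles(calls, reference, config)
  composition <- if (nrow(profiles$profiles)) {
    composition_test(profiles, mirna_arm_fractions(summary), config)
  } else NULL
  duplexes <- duplex_models(summary, reference, config)
  novel_star <- detect_novel_star(calls, reference, config)
  emir <- detect_emir(calls, reference, config)
  antisense <- detect_antisense(placements, reference, config)
  discovery <- if (!is.null(genome)) {
    discover_novel(placements, genome, config)
  } else NULL

  placed_counts <- tags$count[tags$sequence %in% unique(placements$tag_seq)]
  stats <- list(
    n_reads = sum(tags$count) + attr(tags, "dropped"),
    n_tags = nrow(tags),
    dropped_short_long = attr(tags, "dropped"),
    usable = sum(tags$count),
    mapped = sum(placed_counts),
    mapping_rate = mapping_rate(sum(placed_counts), sum(tags$count)))

  structure(list(tags = tags, placements = placements, calls = calls,
                 summary = summary, arm_bias = arm_bias,
                 profiles = profiles, composition = composition,
                 duplexes = duplexes, novel_star = novel_star, emir = emir,
                 antisense = antisense, discovery = discovery,
                 class_split = class_split(calls),
                 reference = reference, config = config, stats = stats),
            class = "mir_census")
}

#' @export
print.mir_census <- function(x, ...) {
  cat("miRNA variant census\n")
  cat(sprintf("  reads: %d usable, %.1f%% mapped; %d unique tags\n",
              x$stats$usable, x$stats$mapping_rate, x$stats$n_tags))
  cat(sprintf("  miRNAs: %d called (%d at >= %g weighted tags)\n",
              nrow(x$summary$mirna),
              nrow(expression_filter(x$summary$mirna, x$config$min_expression)),
              x$config$min_expression))
  cs <- x$class_split
  cat(sprintf("  class split: %.2f%% mature, %.2f%% star, %.2f%% -5p/-3p, %.2f%% non-canonical\n",
              cs["mature"], cs["star"], cs["p5_p3"], cs["noncanonical"]))
  cat(sprintf("  variants: %d novel miR*, %d e-miRs, %d antisense, %d novel loci\n",
              nrow(x$novel_star), nrow(x$emir),
              sum(x$antisense$verdict == "accepted"),
              if (is.null(x$discovery)) 0L else nrow(x$discovery$accepted)))
  invisible(x)
}

#' @method summary mir_census
#' @export
summary.mir_census <- function(object, ...) {
  g <- attr(object$arm_bias, "global")
  m <- object$summary$mirna
  kept <- expression_filter(m, object$config$min_expression)
  w <- kept$total
  out <- list(
    class_split = object$class_split,
    arm_split = g,
    n_mirna = nrow(kept),
    modal_length = weighted_mode(kept$modal_length, w),
    p5_isomir_global = 100 * sum(kept$p5_isomir_prop * w) / sum(w),
    p3_isomir_global = 100 * sum(kept$p3_isomir_prop * w) / sum(w),
    p5_isomir_mean = 100 * mean(kept$p5_isomir_prop),
    p3_isomir_mean = 100 * mean(kept$p3_isomir_prop),
    bias_categories = table(object$arm_bias$category))
  class(out) <- "summary.mir_census"
  out
}

#' @export
print.summary.mir_census <- function(x, ...) {
  cat(sprintf("%d miRNAs above threshold; modal tag length %g nt\n",
              x$n_mirna, x$modal_length))
  cat(sprintf("arm split: %.1f%% 5' / %.1f%% 3'\n", x$arm_split["p5"],
              x$arm_split["p3"]))
  cat(sprintf("5' isomiRs: %.1f%% of tags (per-miRNA mean %.1f%%)\n",
              x$p5_isomir_global, x$p5_isomir_mean))
  cat(sprintf("3' isomiRs: %.1f%% of tags (per-miRNA mean %.1f%%)\n",
              x$p3_isomir_global, x$p3_isomir_mean))
  print(x$bias_categories)
  invisible(x)
}

#' Plot a census overview
#'
#' Two base-graphics panels: the weighted tag length distribution of generic
#' calls, and per-miRNA 5'-arm fraction against hairpin abundance (the
#' strand-bias scatter).
#'
#' @param x A `mir_census`.
#' @param ... Unused.
#' @method plot mir_census
#' @export
plot.mir_census <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  gen <- x$calls[startsWith(x$calls$label, "generic_"), , drop = FALSE]
  lens <- tapply(gen$weighted_count, nchar(gen$tag_seq), sum)
  graphics::barplot(lens, xlab = "tag length (nt)", ylab = "weighted tags",
                    main = "generic tag lengths", col = "steelblue")
  b <- x$arm_bias
  tot <- b$count_5p + b$count_3p
  ok <- tot > 0
  graphics::plot(tot[ok], b$p5_fraction[ok], log = "x",
                 xlab = "tags per hairpin", ylab = "5' arm fraction",
                 main = "arm strand bias", pch = 19,
                 col = grDevices::adjustcolor("darkred", 0.6))
  graphics::abline(h = c(0.2, 0.8), lty = 2, col = "grey40")
  invisible(x)
}

#' Write the census tables to a directory
#'
#' Emits the per-tag placement/feature table, per-miRNA summary, arm-bias
#' table, composition results, duplex table, variant calls and per-hairpin
#' text alignments.
#'
#' @param census A `mir_census`.
#' @param dir Output directory (created if needed).
#' @export
write_census <- function(census, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_placements(census$placements, file.path(dir, "placements.tsv"),
                   census$config)
  wt(census$calls, "feature_calls.tsv")
  wt(census$summary$mirna, "mirna_summary.tsv")
  wt(as.data.frame(census$arm_bias), "arm_bias.tsv")
  if (!is.null(census$composition)) wt(census$composition, "composition.tsv")
  wt(census$duplexes$duplexes, "duplexes.tsv")
  if (nrow(census$novel_star)) wt(census$novel_star, "novel_star.tsv")
  if (nrow(census$emir)) wt(census$emir, "emir.tsv")
  if (nrow(census$antisense)) wt(census$antisense, "antisense.tsv")
  if (!is.null(census$discovery)) write_discovery(census$discovery, dir)
  aln <- file.path(dir, "alignments.txt")
  con <- file(aln, "w")
  for (hpid in unique(census$calls$target_id)) {
    writeLines(render_hairpin_alignment(
      census$reference, hpid, census$calls), con)
    writeLines("", con)
  }
  close(con)
  invisible(dir)
}
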