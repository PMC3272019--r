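# Tag collapsing, alignment to hairpins/genome, and mismatch/multimapping
# resolution (MMR). Placements are plain data.frames with one row per
# (tag, target, position, strand); mismatches are encoded "pos:REF>ALT"
# (positions in tag coordinates, bases in tag orientation), ";"-separated.

placement_proto <- list(
  tag_seq = character, count = integer, library_id = character,
  target_id = character, target_type = character,
  start = integer, end = integer, strand = character,
  n_mismatch = integer, mismatches = character, weight = numeric,
  flags = character
)

#' Collapse reads into unique tags
#'
#' A tag is a unique read sequence; its count is the number of reads sharing
#' it. Reads outside the configured length bounds are dropped and tallied in
#' the `dropped` attribute.
#'
#' @param reads Path to a FASTA/FASTQ file, or a character vector of reads.
#' @param min_len,max_len Inclusive length bounds.
#' @param library_id Library label carried through to placements.
#' @return data.frame with columns `sequence`, `count`, `library_id`, ordered
#'   by decreasing count; attribute `dropped` counts length-filtered reads.
#' @export
collapse_reads <- function(reads, min_len = 15L, max_len = 35L,
                           library_id = "lib1") {
  if (length(reads) == 1L && file.exists(reads[1])) reads <- read_reads(reads)
  reads <- normalize_seq(reads)
  if (length(reads) == 0L) {
    warning("no reads supplied")
    out <- data.frame(sequence = character(0), count = integer(0),
                      library_id = character(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  len <- nchar(reads)
  keep <- len >= min_len & len <= max_len
  dropped <- sum(!keep)
  tab <- table(reads[keep])
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    library_id = library_id, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# mismatch encoding helpers ---------------------------------------------------

encode_mismatches <- function(pos, ref, alt) {
  if (length(pos) == 0L) return("")
  paste(sprintf("%d:%s>%s", pos, ref, alt), collapse = ";")
}

#' Decode a placement mismatch string
#' @param mm ";"-separated "pos:REF>ALT" string.
#' @return data.frame with columns `pos`, `ref`, `alt`.
#' @export
decode_mismatches <- function(mm) {
  if (is.na(mm) || mm == "") {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0)))
  }
  parts <- strsplit(strsplit(mm, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(pos = as.integer(vapply(parts, `[`, character(1), 1L)),
             ref = vapply(parts, `[`, character(1), 2L),
             alt = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

align_tags <- function(tags, ref_seqs, max_mismatches, target_type) {
  if (nrow(tags) == 0L || length(ref_seqs) == 0L) {
    return(empty_df(placement_proto))
  }
  hits <- .scan_align(tags$sequence, unname(ref_seqs), max_mismatches)
  if (length(hits$tag_idx) == 0L) return(empty_df(placement_proto))
  out <- data.frame(
    tag_seq = tags$sequence[hits$tag_idx],
    count = tags$count[hits$tag_idx],
    library_id = tags$library_id[hits$tag_idx],
    target_id = names(ref_seqs)[hits$ref_idx],
    target_type = target_type,
    start = hits$start, end = hits$end,
    strand = ifelse(hits$antisense == 1L, "antisense", "sense"),
    n_mismatch = hits$n_mismatch, mismatches = hits$mismatches,
    weight = NA_real_, flags = "", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Align tags to hairpin precursors
#'
#' Reports every placement with at most `max_mismatches` substitutions on
#' either strand of each hairpin. Sense placements feed the variant taxonomy;
#' antisense placements are retained for the antisense screen.
#'
#' @param tags data.frame from [collapse_reads()].
#' @param reference A `hairpin_set`.
#' @param max_mismatches Substitutions tolerated.
#' @return Placement data.frame (see package overview); weights are filled by
#'   [mmr_resolve()].
#' @export
align_to_hairpins <- function(tags, reference, max_mismatches = 1L) {
  align_tags(tags, reference$seq, max_mismatches, "hairpin")
}

#' Align hairpin-unmapped tags to a genome
#'
#' Tags are matched on both strands of every chromosome; a tag with more than
#' `multimap_cap` placements is treated as repetitive and discarded (its
#' sequences are listed in the `discarded` attribute).
#'
#' @param tags data.frame of tags with no hairpin placement.
#' @param genome Named character vector (or DNAStringSet) of chromosomes.
#' @param max_mismatches Substitutions tolerated.
#' @param multimap_cap Placement-count cap.
#' @return Placement data.frame with `target_type = "genome"`.
#' @export
align_to_genome <- function(tags, genome, max_mismatches = 1L,
                            multimap_cap = 10L) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  pl <- align_tags(tags, normalize_seq(genome), max_mismatches, "genome")
  if (nrow(pl) == 0L) {
    attr(pl, "discarded") <- character(0)
    return(pl)
  }
  nplace <- table(pl$tag_seq)
  repetitive <- names(nplace)[nplace > multimap_cap]
  out <- pl[!(pl$tag_seq %in% repetitive), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- repetitive
  out
}

#' Resolve mismatch and multimapping placements (MMR)
#'
#' Per tag: if any perfect (0-mismatch) placement exists, all placements with
#' mismatches are dropped; surviving placements share the tag's count with
#' equal weights 1/k. Surviving placements whose aligned reference sequence is
#' identical across different hairpins are flagged `identical-locus` so that
#' per-family reports can aggregate them. The operation is deterministic and
#' idempotent, and conserves counts: sum(weight * count) over placements
#' equals the summed count of placed tags.
#'
#' @param placements Placement data.frame.
#' @return The resolved placement data.frame with `weight` filled in.
#' @export
mmr_resolve <- function(placements) {
  if (nrow(placements) == 0L) return(placements)
  key <- paste(placements$tag_seq, placements$library_id, sep = "\r")
  parts <- split(seq_len(nrow(placements)), key)
  keep_idx <- integer(0)
  weights <- numeric(0)
  flags <- character(0)
  for (idx in parts) {
    nm <- placements$n_mismatch[idx]
    surv <- if (any(nm == 0L)) idx[nm == 0L] else idx
    k <- length(surv)
    w <- rep(1 / k, k)
    fl <- placements$flags[surv]
    # identical-locus: same aligned reference content on >1 hairpin
    if (k > 1L) {
      refkey <- paste(placements$target_type[surv], placements$strand[surv],
                      placements$mismatches[surv], sep = "|")
      dupgrp <- ave(seq_along(surv), refkey, FUN = length)
      multi_target <- ave(as.integer(factor(placements$target_id[surv])),
                          refkey, FUN = function(z) length(unique(z)))
      tag_it <- dupgrp > 1L & multi_target > 1L
      fl <- ifelse(tag_it,
                   ifelse(fl == "", "identical-locus",
                          paste(fl, "identical-locus", sep = ",")), fl)
    }
    keep_idx <- c(keep_idx, surv)
    weights <- c(weights, w)
    flags <- c(flags, fl)
  }
  out <- placements[keep_idx, , drop = FALSE]
  out$weight <- weights
  out$flags <- flags
  out <- out[order(out$tag_seq, out$target_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify placement mismatches
#'
#' Adds `mismatch_class` (`clean`, `internal`, `nta`) and `mismatch_subtype`
#' columns. A mismatch at the tag's final position is a non-templated 3'
#' addition (NTA), subtyped by the added base (RNA alphabet); internal
#' substitutions are subtyped by the 12-way ref-to-alt split (e.g. `A-to-G`,
#' the signature an A-to-I editing event would leave).
#'
#' @param placements Resolved placement data.frame.
#' @return The data.frame with classification columns appended.
#' @export
classify_mismatches <- function(placements) {
  n <- nrow(placements)
  cls <- character(n); sub <- character(n)
  for (i in seq_len(n)) {
    mm <- decode_mismatches(placements$mismatches[i])
    if (nrow(mm) == 0L) {
      cls[i] <- "clean"; sub[i] <- ""
      next
    }
    taglen <- nchar(placements$tag_seq[i])
    at_end <- mm$pos == taglen
    if (all(at_end)) {
      cls[i] <- "nta"
      sub[i] <- to_rna(mm$alt[which(at_end)[1]])
    } else {
      cls[i] <- "internal"
      j <- which(!at_end)[1]
      sub[i] <- paste0(to_rna(mm$ref[j]), "-to-", to_rna(mm$alt[j]))
    }
  }
  placements$mismatch_class <- cls
  placements$mismatch_subtype <- sub
  placements
}

#' Write a placement table to TSV
#'
#' @param placements Placement data.frame.
#' @param path Output file.
#' @param config Optional `census_config` echoed into `#` header lines,
#'   including the multimapping-resolution policy.
#' @export
write_placements <- function(placements, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mircensus placement table", con)
  writeLines("# MMR policy: perfect-beats-mismatch, equal 1/k weights, identical-locus flagging", con)
  if (!is.null(config)) {
    writeLines(sprintf("# config: max_mismatches=%d generic_window=%d",
                       config$max_mismatches, config$generic_window), con)
  }
  utils::write.table(placements, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
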