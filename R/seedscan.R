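# Seed extraction, simplified 7-mer seed-match scanning of 3' UTRs, and
# set-overlap reports with term enrichment.

#' Extract the seed of a miRNA variant
#'
#' The seed is nucleotides 2-8 of the variant's own sequence. For a 5'
#' isomiR, the variant start is shifted by `variant_offset` relative to the
#' canonical sequence, so the seed equals canonical positions (2+k)-(8+k).
#' The input alphabet (RNA or DNA) is preserved.
#'
#' @param mature_sequence Canonical mature sequence (>= 8 nt).
#' @param variant_offset Signed 5' offset of the variant (0 = canonical).
#' @return 7-nt seed string.
#' @export
#' @examples
#' extract_seed("UGGUCCCCUUCAACCAGCUGU")      # "GGUCCCC"
#' extract_seed("UGGUCCCCUUCAACCAGCUGU", 1L)  # "GUCCCCU"
extract_seed <- function(mature_sequence, variant_offset = 0L) {
  s <- toupper(mature_sequence)
  from <- 2L + variant_offset
  to <- 8L + variant_offset
  if (from < 1L || to > nchar(s)) {
    stop("seed positions ", from, "-", to, " fall outside the sequence")
  }
  substr(s, from, to)
}

#' Scan 3' UTR sequences for exact seed matches
#'
#' Reports the ids of UTRs containing at least one exact reverse-complement
#' match to the seed (a 7-mer site). This is a deliberate simplification:
#' it is exact 7-mer matching, not TargetScan context scoring, and is
#' labelled as such in outputs.
#'
#' @param seed 7-nt seed (RNA or DNA alphabet).
#' @param utrs Path to a UTR FASTA, or a named character vector/XStringSet.
#' @return Character vector of hit ids; attribute `method` records the
#'   simplification.
#' @export
scan_utrs <- function(seed, utrs) {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs)) {
    utrs <- Biostrings::readBStringSet(utrs)
  }
  if (methods::is(utrs, "XStringSet")) utrs <- as.character(utrs)
  utrs <- normalize_seq(utrs)
  if (length(utrs) == 0L) {
    out <- character(0)
    attr(out, "method") <- "exact 7-mer seed match (not TargetScan)"
    return(out)
  }
  site <- revcomp(normalize_seq(seed))
  counts <- Biostrings::vcountPattern(site, Biostrings::DNAStringSet(utrs),
                                      fixed = TRUE)
  out <- names(utrs)[counts >= 1L]
  attr(out, "method") <- "exact 7-mer seed match (not TargetScan)"
  out
}

#' Overlap (Venn) report for two target sets with term enrichment
#'
#' Computes A-only/B-only/shared counts and, when a term annotation is
#' supplied, per-term hypergeometric enrichment of each subset against the
#' id universe, Benjamini-Hochberg corrected within each subset and called
#' significant at `alpha`.
#'
#' @param setA,setB Character vectors of target ids.
#' @param annotation Optional data.frame with columns `id` and `term` (or a
#'   2-column TSV path).
#' @param universe Character vector of all ids (defaults to the union of the
#'   annotation ids and both sets).
#' @param config A [census_config()].
#' @return list of class `overlap_report`: `counts` (a_only, b_only, shared),
#'   the member ids, and `enrichment` (data.frame: subset, term, overlap,
#'   subset size, term size, p_value, p_adjusted, significant).
#' @export
overlap_report <- function(setA, setB, annotation = NULL, universe = NULL,
                           config = census_config()) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- intersect(setA, setB)
  a_only <- setdiff(setA, setB)
  b_only <- setdiff(setB, setA)
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- utils::read.table(annotation, sep = "\t", header = FALSE,
                                    col.names = c("id", "term"),
                                    stringsAsFactors = FALSE)
  }
  enr <- NULL
  if (!is.null(annotation)) {
    if (is.null(universe)) universe <- unique(c(annotation$id, setA, setB))
    if (length(universe) == 0L) stop("empty id universe")
    annotation <- annotation[annotation$id %in% universe, , drop = FALSE]
    rows <- list()
    for (subset in c("a_only", "b_only", "shared")) {
      ids <- switch(subset, a_only = a_only, b_only = b_only, shared = shared)
      terms <- unique(annotation$term)
      pvals <- numeric(0); meta <- list()
      for (tm in terms) {
        with_term <- unique(annotation$id[annotation$term == tm])
        q <- length(intersect(ids, with_term))
        m <- length(with_term)
        k <- length(ids)
        p <- stats::phyper(q - 1, m, length(universe) - m, k,
                           lower.tail = FALSE)
        pvals <- c(pvals, p)
        meta[[length(meta) + 1L]] <- data.frame(
          subset = subset, term = tm, overlap = q, subset_size = k,
          term_size = m, p_value = p, stringsAsFactors = FALSE)
      }
      if (length(meta)) {
        d <- do.call(rbind, meta)
        d$p_adjusted <- stats::p.adjust(d$p_value, method = "BH")
        d$significant <- d$p_adjusted < config$alpha
        rows[[length(rows) + 1L]] <- d
      }
    }
    enr <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(enr)) rownames(enr) <- NULL
  }
  structure(list(counts = c(a_only = length(a_only), b_only = length(b_only),
                            shared = length(shared)),
                 a_only = a_only, b_only = b_only, shared = shared,
                 enrichment = enr),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: %d A-only, %d B-only, %d shared\n",
              x$counts["a_only"], x$counts["b_only"], x$counts["shared"]))
  if (!is.null(x$enrichment)) {
    sig <- x$enrichment[x$enrichment$significant, , drop = FALSE]
    cat(sprintf("%d significantly enriched subset/term pairs\n", nrow(sig)))
  }
  invisible(x)
}
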