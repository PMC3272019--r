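# Synthetic reference and small-RNA library generator with planted ground
# truth, emulating a deeply sequenced small-RNA library: modal tag length
# 22 nt, rare 5' offsets and frequent 3' offsets, arm-biased hairpin
# expression, occasional internal mismatches and non-templated 3' additions,
# plus planted e-miRs, antisense loci and novel genomic hairpins.

#' Specification for synthetic data generation
#'
#' Defaults describe the emulated library: 20 stem-loop hairpins (30-bp stem,
#' 10-nt loop) with log-normal abundances; 22-nt mature species starting at
#' hairpin position 8 with canonical 2-nt 3'-overhang duplex geometry; the
#' mature arm on the 5' arm with probability 0.55; mature/star hairpins
#' biased to the mature arm (fraction drawn in 0.75-0.95) and -5p/-3p
#' hairpins near-symmetric (0.35-0.65); 5' start offsets concentrated at 0
#' (95% of reads) over -3..+3 and 3' end offsets with 48% mass at 0 over
#' -4..+4 (so roughly half of tags vary at the 3' end and the modal tag
#' length stays 22 nt); 5% non-templated 3' additions (A- and U-biased);
#' 0.5% internal substitution errors. One e-miR, one antisense locus and two
#' novel genomic loci are planted by default, and two hairpins are annotated
#' on one arm only so that novel miR* detection can be exercised.
#'
#' @param n_hairpins,n_reads Cohort and library size.
#' @param arm_len,loop_len,mature_len,mature_start Hairpin geometry (nt).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @param p_mature_5p Probability the mature species sits on the 5' arm.
#' @param p_pattern_mature_star Probability a hairpin is annotated
#'   mature/star rather than -5p/-3p.
#' @param n_single_arm Number of hairpins annotated on the mature arm only.
#' @param arm_fraction_range,arm_fraction_sym_range Uniform ranges for the
#'   dominant-arm read fraction of biased and symmetric hairpins.
#' @param arm_fractions Optional explicit per-hairpin dominant-arm fractions.
#' @param offset5_probs Named probabilities over 5' offsets -3..+3.
#' @param offset3_probs Named probabilities over 3' offsets -4..+4.
#' @param nta_rate,nta_base_probs Non-templated 3' addition rate and base
#'   distribution (DNA alphabet).
#' @param error_rate Per-read internal substitution probability.
#' @param emir NULL or list(hairpin = index, offset = 5' offset of the
#'   planted set beyond the generic window, length = tag length, fraction =
#'   share of that hairpin's reads).
#' @param antisense NULL or list(hairpin = index, fraction = share of all
#'   reads drawn antisense to that hairpin locus).
#' @param novel NULL or list(n = loci, fraction = share of all reads per
#'   locus, star_fraction = share of a locus' reads from the star arm).
#' @param distortions Optional data.frame(hairpin, site, kind) planting
#'   symmetric internal loops (`sym2`, `sym4`) at the Drosha site.
#' @param identical_loci If TRUE, hairpin 2 is made sequence-identical to
#'   hairpin 1 (a two-locus family such as miR-133a-1/-2).
#' @param genome_len Length of the random genome carrying novel loci.
#' @param seed Integer seed; the reference uses `seed`, the library `seed+1`.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_hairpins = 20L, n_reads = 50000L,
                     arm_len = 30L, loop_len = 10L,
                     mature_len = 22L, mature_start = 8L,
                     abundance_meanlog = log(1000), abundance_sdlog = 1,
                     p_mature_5p = 0.55,
                     p_pattern_mature_star = 0.7,
                     n_single_arm = 2L,
                     arm_fraction_range = c(0.75, 0.95),
                     arm_fraction_sym_range = c(0.35, 0.65),
                     arm_fractions = NULL,
                     offset5_probs = c(`-3` = 0.002, `-2` = 0.005,
                                       `-1` = 0.018, `0` = 0.95,
                                       `1` = 0.018, `2` = 0.005, `3` = 0.002),
                     offset3_probs = c(`-4` = 0.01, `-3` = 0.04, `-2` = 0.10,
                                       `-1` = 0.15, `0` = 0.48, `1` = 0.12,
                                       `2` = 0.06, `3` = 0.03, `4` = 0.01),
                     nta_rate = 0.05,
                     nta_base_probs = c(A = 0.5, C = 0.1, G = 0.05, T = 0.35),
                     error_rate = 0.005,
                     emir = list(hairpin = 1L, offset = 4L, length = 19L,
                                 fraction = 0.25),
                     antisense = list(hairpin = 2L, fraction = 0.02),
                     novel = list(n = 2L, fraction = 0.02,
                                  star_fraction = 0.2),
                     distortions = NULL,
                     identical_loci = FALSE,
                     genome_len = 1000000L,
                     seed = 1L) {
  stopifnot(abs(sum(offset5_probs) - 1) < 1e-8,
            abs(sum(offset3_probs) - 1) < 1e-8,
            nta_rate >= 0, nta_rate <= 1, error_rate >= 0, error_rate <= 1,
            mature_start + mature_len - 1L < arm_len,
            mature_start - 4L >= 1L)
  spec <- list(n_hairpins = as.integer(n_hairpins),
               n_reads = as.integer(n_reads),
               arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
               mature_len = as.integer(mature_len),
               mature_start = as.integer(mature_start),
               abundance_meanlog = abundance_meanlog,
               abundance_sdlog = abundance_sdlog,
               p_mature_5p = p_mature_5p,
               p_pattern_mature_star = p_pattern_mature_star,
               n_single_arm = as.integer(n_single_arm),
               arm_fraction_range = arm_fraction_range,
               arm_fraction_sym_range = arm_fraction_sym_range,
               arm_fractions = arm_fractions,
               offset5_probs = offset5_probs,
               offset3_probs = offset3_probs,
               nta_rate = nta_rate, nta_base_probs = nta_base_probs,
               error_rate = error_rate,
               emir = emir, antisense = antisense, novel = novel,
               distortions = distortions,
               identical_loci = identical_loci,
               genome_len = as.integer(genome_len),
               seed = as.integer(seed))
  class(spec) <- "sim_spec"
  spec
}

# One synthetic stem-loop: fully paired stem, unpaired loop. A single G-U
# wobble is planted mid-stem so the two arms are not exact reverse
# complements of each other (as in real precursors); without it every arm
# tag would also match the opposite arm antisense.
make_stem_loop <- function(arm_len, loop_len, wobble_at = 18L) {
  arm <- strsplit(random_dna(arm_len), "")[[1]]
  w <- min(max(2L, wobble_at), arm_len - 1L)
  if (!(arm[w] %in% c("G", "T"))) arm[w] <- sample(c("G", "T"), 1L)
  arm3 <- strsplit(revcomp(paste(arm, collapse = "")), "")[[1]]
  arm3[arm_len - w + 1L] <- if (arm[w] == "G") "T" else "G"
  loop <- random_dna(loop_len)
  seq <- paste0(paste(arm, collapse = ""), loop, paste(arm3, collapse = ""))
  struct <- paste0(strrep("(", arm_len), strrep(".", loop_len),
                   strrep(")", arm_len))
  list(seq = seq, struct = struct)
}

#' Build a synthetic reference with planted truth
#'
#' Constructs the hairpin cohort (sequences, dot-bracket structures,
#' annotations with canonical 2-nt 3'-overhang Drosha/Dicer geometry), plants
#' any requested structural distortions, and embeds the novel loci in a
#' random genome at recorded coordinates.
#'
#' @param spec A [sim_spec()].
#' @return list of class `sim_reference`: `hairpins` (a `hairpin_set`),
#'   `genome` (named character vector), `truth` (per-hairpin planted
#'   parameters and planted locus coordinates).
#' @export
sim_reference <- function(spec = sim_spec()) {
  set.seed(spec$seed)
  n <- spec$n_hairpins
  hp_len <- 2L * spec$arm_len + spec$loop_len
  ids <- sprintf("syn-mir-%d", seq_len(n))
  seqs <- character(n); structs <- character(n)
  for (i in seq_len(n)) {
    sl <- make_stem_loop(spec$arm_len, spec$loop_len)
    seqs[i] <- sl$seq; structs[i] <- sl$struct
  }
  if (isTRUE(spec$identical_loci) && n >= 2L) {
    seqs[2] <- seqs[1]; structs[2] <- structs[1]
  }
  names(seqs) <- ids; names(structs) <- ids

  # planted distortions: symmetric internal loops just outside the Drosha
  # cleavage site (positions mature_start-1[,-2] and their partners)
  if (!is.null(spec$distortions)) {
    for (k in seq_len(nrow(spec$distortions))) {
      d <- spec$distortions[k, ]
      width <- if (d$kind == "sym4") 2L else 1L
      pos <- (spec$mature_start - width):(spec$mature_start - 1L)
      pos <- c(pos, hp_len + 1L - pos)
      st <- strsplit(structs[d$hairpin], "")[[1]]
      st[pos] <- "."
      structs[d$hairpin] <- paste(st, collapse = "")
    }
  }

  s5 <- spec$mature_start
  e5 <- s5 + spec$mature_len - 1L
  s3 <- hp_len + 3L - e5   # canonical duplex: 2-nt 3' overhangs
  e3 <- hp_len + 3L - s5
  mature_arm <- ifelse(stats::runif(n) < spec$p_mature_5p,
                       "five_prime", "three_prime")
  pattern <- ifelse(stats::runif(n) < spec$p_pattern_mature_star,
                    "mature_star", "p5_p3")
  if (!is.null(spec$emir)) pattern[spec$emir$hairpin] <- "mature_star"
  single <- rep(FALSE, n)
  if (spec$n_single_arm > 0L) {
    cand <- setdiff(seq_len(n), c(spec$emir$hairpin, spec$antisense$hairpin))
    single[utils::tail(cand, spec$n_single_arm)] <- TRUE
  }
  pattern[single] <- "mature_star"
  if (isTRUE(spec$identical_loci)) {
    mature_arm[2] <- mature_arm[1]; pattern[2] <- pattern[1]
  }

  ann <- list()
  for (i in seq_len(n)) {
    iv5 <- c(s5, e5); iv3 <- c(s3, e3)
    base <- sub("mir", "miR", ids[i])
    if (pattern[i] == "mature_star") {
      m_iv <- if (mature_arm[i] == "five_prime") iv5 else iv3
      st_iv <- if (mature_arm[i] == "five_prime") iv3 else iv5
      ann[[length(ann) + 1L]] <- data.frame(
        hairpin_id = ids[i], name = base, start = m_iv[1], end = m_iv[2],
        class = "mature", stringsAsFactors = FALSE)
      if (!single[i]) {
        ann[[length(ann) + 1L]] <- data.frame(
          hairpin_id = ids[i], name = paste0(base, "*"),
          start = st_iv[1], end = st_iv[2], class = "star",
          stringsAsFactors = FALSE)
      }
    } else {
      ann[[length(ann) + 1L]] <- data.frame(
        hairpin_id = ids[i], name = paste0(base, "-5p"),
        start = iv5[1], end = iv5[2], class = "p5", stringsAsFactors = FALSE)
      if (!single[i]) {
        ann[[length(ann) + 1L]] <- data.frame(
          hairpin_id = ids[i], name = paste0(base, "-3p"),
          start = iv3[1], end = iv3[2], class = "p3", stringsAsFactors = FALSE)
      }
    }
  }
  annotations <- do.call(rbind, ann)
  hairpins <- hairpin_set(seqs, structs, annotations)

  abundance <- stats::rlnorm(n, spec$abundance_meanlog, spec$abundance_sdlog)
  if (is.null(spec$arm_fractions)) {
    arm_fraction <- ifelse(
      pattern == "mature_star",
      stats::runif(n, spec$arm_fraction_range[1], spec$arm_fraction_range[2]),
      stats::runif(n, spec$arm_fraction_sym_range[1],
                   spec$arm_fraction_sym_range[2]))
  } else {
    arm_fraction <- rep_len(spec$arm_fractions, n)
  }
  if (isTRUE(spec$identical_loci)) {
    abundance[2] <- abundance[1]; arm_fraction[2] <- arm_fraction[1]
  }

  genome <- c(chr1 = random_dna(spec$genome_len))
  novel_truth <- NULL
  if (!is.null(spec$novel) && spec$novel$n > 0L) {
    rows <- list()
    gseq <- genome[["chr1"]]
    used <- integer(0)
    for (k in seq_len(spec$novel$n)) {
      sl <- make_stem_loop(spec$arm_len, spec$loop_len)
      repeat {   # keep planted loci well separated
        pos <- sample.int(spec$genome_len - hp_len - 400L, 1L) + 200L
        if (!length(used) || min(abs(used - pos)) > hp_len + 300L) break
      }
      used <- c(used, pos)
      substr(gseq, pos, pos + hp_len - 1L) <- sl$seq
      rows[[k]] <- data.frame(
        locus = sprintf("novel-%d", k), chrom = "chr1",
        start = pos, end = pos + hp_len - 1L,
        mature_start = pos + s5 - 1L, mature_end = pos + e5 - 1L,
        star_start = pos + s3 - 1L, star_end = pos + e3 - 1L,
        sequence = sl$seq, structure = sl$struct, stringsAsFactors = FALSE)
    }
    genome[["chr1"]] <- gseq
    novel_truth <- do.call(rbind, rows)
  }

  truth <- list(
    hairpins = data.frame(hairpin_id = ids, abundance = abundance,
                          pattern = pattern, mature_arm = mature_arm,
                          arm_fraction = arm_fraction, single_arm = single,
                          stringsAsFactors = FALSE),
    mature_interval = c(s5, e5), star_interval = c(s3, e3),
    offset5_probs = spec$offset5_probs, offset3_probs = spec$offset3_probs,
    nta_rate = spec$nta_rate, error_rate = spec$error_rate,
    emir = spec$emir, antisense = spec$antisense, novel = novel_truth)
  structure(list(hairpins = hairpins, genome = genome, truth = truth,
                 spec = spec), class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("sim_reference: %d hairpins, genome %d nt, %d novel loci\n",
              length(x$hairpins$seq), nchar(x$genome[[1]]),
              if (is.null(x$truth$novel)) 0L else nrow(x$truth$novel)))
  invisible(x)
}

sample_offset <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

mutate_base <- function(base) {
  sample(setdiff(DNA_BASES, base), 1L)
}

#' Simulate a small-RNA library from a synthetic reference
#'
#' Draws reads according to the planted abundances, arm fractions and offset
#' distributions; applies non-templated 3' additions (a 3'-terminal base
#' guaranteed to differ from the templated next hairpin base) and internal
#' substitution errors; and emits planted e-miR, antisense and novel-locus
#' reads at their configured fractions. Deterministic given the spec seed.
#'
#' @param reference A [sim_reference()].
#' @param spec The same [sim_spec()] (defaults to the one in the reference).
#' @param fastq Optional path: write the reads as FASTQ.
#' @return list of class `sim_library`: `reads` (character vector), `truth`
#'   (per-read provenance data.frame plus the reference truth), and
#'   `fastq` (the path, if written).
#' @export
simulate_library <- function(reference, spec = reference$spec, fastq = NULL) {
  set.seed(spec$seed + 1L)
  hp <- reference$hairpins
  tr <- reference$truth
  n_reads <- spec$n_reads
  hp_len <- nchar(hp$seq[[1]])

  p_novel <- if (!is.null(spec$novel)) spec$novel$n * spec$novel$fraction else 0
  p_as <- if (!is.null(spec$antisense)) spec$antisense$fraction else 0
  src <- sample(c("hairpin", "antisense", "novel"), n_reads, replace = TRUE,
                prob = c(1 - p_novel - p_as, p_as, p_novel))

  reads <- character(n_reads)
  prov <- data.frame(source = src, origin = NA_character_,
                     arm = NA_character_, start = NA_integer_,
                     end = NA_integer_, off5 = NA_integer_,
                     off3 = NA_integer_, nta = NA_character_,
                     error = FALSE, stringsAsFactors = FALSE)

  hp_idx <- which(src == "hairpin")
  if (length(hp_idx)) {
    hsel <- sample.int(spec$n_hairpins, length(hp_idx), replace = TRUE,
                       prob = tr$hairpins$abundance)
    is_emir <- rep(FALSE, length(hp_idx))
    if (!is.null(spec$emir)) {
      is_emir <- hsel == spec$emir$hairpin &
        stats::runif(length(hp_idx)) < spec$emir$fraction
    }
    on_dom <- stats::runif(length(hp_idx)) < tr$hairpins$arm_fraction[hsel]
    # dominant arm carries the mature (or -5p) species
    dom_arm <- tr$hairpins$mature_arm[hsel]
    arm <- ifelse(on_dom, dom_arm,
                  ifelse(dom_arm == "five_prime", "three_prime", "five_prime"))
    iv_s <- ifelse(arm == "five_prime", tr$mature_interval[1],
                   tr$star_interval[1])
    iv_e <- ifelse(arm == "five_prime", tr$mature_interval[2],
                   tr$star_interval[2])
    off5 <- sample_offset(length(hp_idx), spec$offset5_probs)
    off3 <- sample_offset(length(hp_idx), spec$offset3_probs)
    start <- iv_s + off5
    end <- iv_e + off3
    # planted e-miR set: fixed non-generic interval, 90% exactly phased
    if (any(is_emir)) {
      es <- tr$mature_interval[1] + spec$emir$offset
      jit <- ifelse(stats::runif(sum(is_emir)) < 0.9, 0L, 1L)
      start[is_emir] <- es + jit
      end[is_emir] <- start[is_emir] + spec$emir$length - 1L
      arm[is_emir] <- "emir"
      off5[is_emir] <- NA_integer_; off3[is_emir] <- NA_integer_
    }
    hseqs <- unname(hp$seq[hsel])
    s <- pmax(1L, start); e <- pmin(hp_len, end)
    rd <- substr(hseqs, s, e)
    nta <- rep(NA_character_, length(hp_idx))
    err <- rep(FALSE, length(hp_idx))
    u <- stats::runif(length(hp_idx))
    nta_sel <- arm != "emir" & u < spec$nta_rate & e < hp_len
    if (any(nta_sel)) {
      b <- sample(names(spec$nta_base_probs), sum(nta_sel), replace = TRUE,
                  prob = spec$nta_base_probs)
      templ <- substr(hseqs[nta_sel], e[nta_sel] + 1L, e[nta_sel] + 1L)
      clash <- which(b == templ)
      for (k in clash) b[k] <- mutate_base(templ[k])
      rd[nta_sel] <- paste0(rd[nta_sel], b)
      nta[nta_sel] <- b
    }
    err_sel <- which(!nta_sel & stats::runif(length(hp_idx)) < spec$error_rate &
                       nchar(rd) > 3L)
    for (k in err_sel) {
      p <- sample(2L:(nchar(rd[k]) - 1L), 1L)
      substr(rd[k], p, p) <- mutate_base(substr(rd[k], p, p))
      err[k] <- TRUE
    }
    reads[hp_idx] <- rd
    prov$origin[hp_idx] <- names(hp$seq)[hsel]
    prov$arm[hp_idx] <- arm
    prov$start[hp_idx] <- s; prov$end[hp_idx] <- e
    prov$off5[hp_idx] <- off5; prov$off3[hp_idx] <- off3
    prov$nta[hp_idx] <- nta; prov$error[hp_idx] <- err
  }

  as_idx <- which(src == "antisense")
  if (length(as_idx) && !is.null(spec$antisense)) {
    hseq <- hp$seq[[spec$antisense$hairpin]]
    m_arm <- tr$hairpins$mature_arm[spec$antisense$hairpin]
    o_arm <- setdiff(c("five_prime", "three_prime"), m_arm)
    ivs <- list(five_prime = tr$mature_interval,
                three_prime = tr$star_interval)
    rc <- vapply(ivs, function(iv) revcomp(substr(hseq, iv[1], iv[2])),
                 character(1))
    on_mature <- stats::runif(length(as_idx)) < 0.7
    a <- ifelse(on_mature, m_arm, o_arm)
    reads[as_idx] <- rc[a]
    prov$origin[as_idx] <- names(hp$seq)[spec$antisense$hairpin]
    prov$arm[as_idx] <- paste0("antisense_", a)
    prov$start[as_idx] <- vapply(a, function(x) ivs[[x]][1], integer(1))
    prov$end[as_idx] <- vapply(a, function(x) ivs[[x]][2], integer(1))
  }

  nv_idx <- which(src == "novel")
  if (length(nv_idx) && !is.null(tr$novel)) {
    lsel <- sample.int(nrow(tr$novel), length(nv_idx), replace = TRUE)
    for (j in seq_along(nv_idx)) {
      i <- nv_idx[j]
      loc <- tr$novel[lsel[j], ]
      on_star <- stats::runif(1) < spec$novel$star_fraction
      gs <- if (on_star) loc$star_start else loc$mature_start
      ge <- if (on_star) loc$star_end else loc$mature_end
      ge <- ge + sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.7, 0.15))
      reads[i] <- substr(reference$genome[["chr1"]], gs, ge)
      prov$origin[i] <- loc$locus
      prov$arm[i] <- if (on_star) "novel_star" else "novel_mature"
      prov$start[i] <- gs; prov$end[i] <- ge
    }
  }

  out <- list(reads = reads,
              truth = c(list(reads = prov), tr),
              fastq = NULL)
  if (!is.null(fastq)) {
    write_fastq(reads, fastq)
    out$fastq <- fastq
  }
  class(out) <- "sim_library"
  out
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("sim_library: %d reads (%s)\n", length(x$reads),
              paste(sprintf("%s=%d", names(table(x$truth$reads$source)),
                            table(x$truth$reads$source)), collapse = ", ")))
  invisible(x)
}

#' Write a simulated reference to files
#'
#' Emits the hairpin FASTA, dot-bracket structure file, annotation TSV and
#' genome FASTA so that the file-based loaders can round-trip the reference.
#'
#' @param reference A [sim_reference()].
#' @param dir Output directory.
#' @return Named list of the written paths.
#' @export
write_sim_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp <- reference$hairpins
  paths <- list(
    hairpin_fasta = file.path(dir, "hairpins.fa"),
    structure = file.path(dir, "hairpins.dot"),
    annotations = file.path(dir, "annotations.tsv"),
    genome = file.path(dir, "genome.fa"))
  write_fasta(hp$seq, paths$hairpin_fasta)
  writeLines(as.vector(rbind(paste0(">", names(hp$structure)),
                             unname(hp$structure))), paths$structure)
  utils::write.table(hp$annotations[, c("hairpin_id", "name", "start",
                                        "end", "class")],
                     paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(reference$genome, paths$genome)
  paths
}

#' Write / read a simulation specification file
#'
#' Serializes a [sim_spec()] to a documented key-value (YAML) file and reads
#' it back, so that the exact study conditions of a simulated cohort can be
#' stored alongside its outputs.
#'
#' @param spec A [sim_spec()].
#' @param path File path.
#' @return `write_sim_spec` returns the path invisibly; `read_sim_spec`
#'   returns a validated [sim_spec()].
#' @export
write_sim_spec <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("sim-spec files require the yaml package")
  }
  x <- unclass(spec)
  if (!is.null(x$distortions)) x$distortions <- as.list(x$distortions)
  for (f in c("offset5_probs", "offset3_probs", "nta_base_probs")) {
    x[[f]] <- as.list(x[[f]])   # keep names (YAML map, not sequence)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("sim-spec files require the yaml package")
  }
  y <- yaml::read_yaml(path)
  for (f in c("offset5_probs", "offset3_probs", "nta_base_probs")) {
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  }
  if (!is.null(y$distortions)) y$distortions <- as.data.frame(y$distortions)
  for (f in c("arm_fraction_range", "arm_fraction_sym_range",
              "arm_fractions")) {
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  }
  y <- y[names(y) %in% names(formals(sim_spec))]
  do.call(sim_spec, y)
}
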