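# Shared fixtures and independent oracles. All fixtures are built in code;
# the toy hairpin is the 70-nt stem-loop with pair table i <-> 71-i for
# i = 1..30 and terminal loop 31-40, carrying a 22-nt miRNA on each arm with
# canonical 2-nt 3' overhangs: 5' arm 8-29, 3' arm 44-65.

TOY_ARM <- "TCGCTAGGTCACAGCTTAGGATCAGGTCCA"  # 30 nt
TOY_LOOP <- "ATCGAACTTG"                     # 10 nt

toy_seq <- function() {
  paste0(TOY_ARM, TOY_LOOP,
         as.character(Biostrings::reverseComplement(Biostrings::DNAString(TOY_ARM))))
}

toy_structure <- function() {
  paste0(strrep("(", 30), strrep(".", 10), strrep(")", 30))
}

toy_annotations <- function() {
  data.frame(hairpin_id = "toy-mir-1",
             name = c("toy-miR-1", "toy-miR-1*"),
             start = c(8L, 44L), end = c(29L, 65L),
             class = c("mature", "star"),
             stringsAsFactors = FALSE)
}

toy_reference <- function() {
  mircensus:::hairpin_set(c(`toy-mir-1` = toy_seq()),
                          c(`toy-mir-1` = toy_structure()),
                          toy_annotations())
}

# build a placement row without running the aligner
mk_placement <- function(tag_seq, count, target, start, end,
                         strand = "sense", n_mm = 0L, mm = "",
                         weight = 1, target_type = "hairpin",
                         library_id = "lib1") {
  data.frame(tag_seq = tag_seq, count = as.integer(count),
             library_id = library_id, target_id = target,
             target_type = target_type, start = as.integer(start),
             end = as.integer(end), strand = strand,
             n_mismatch = as.integer(n_mm), mismatches = mm,
             weight = weight, flags = "", stringsAsFactors = FALSE)
}

# independent pair-table oracle: iterative innermost-pair elimination
oracle_pair_table <- function(db) {
  s <- strsplit(db, "")[[1]]
  partner <- integer(length(s))
  repeat {
    done <- TRUE
    i <- 1L
    while (i < length(s)) {
      if (s[i] == "(") {
        j <- i + 1L
        while (j <= length(s) && s[j] == ".") j <- j + 1L
        if (j <= length(s) && s[j] == ")") {
          partner[i] <- j; partner[j] <- i
          s[i] <- "."; s[j] <- "."
          done <- FALSE
        }
      }
      i <- i + 1L
    }
    if (done) break
  }
  if (any(s != ".")) stop("unbalanced")
  partner
}

# random valid dot-bracket generator
random_db <- function(n) {
  if (n <= 1L) return(strrep(".", n))
  r <- stats::runif(1)
  if (r < 0.35 || n < 4L) {
    paste0(".", random_db(n - 1L))
  } else if (r < 0.75) {
    paste0("(", random_db(n - 2L), ")")
  } else {
    k <- sample(seq_len(n - 1L), 1L)
    paste0(random_db(k), random_db(n - k))
  }
}

# brute-force sliding-window aligner oracle (substitutions only)
brute_force_align <- function(tag, ref, max_mm) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  L <- nchar(tag); n <- nchar(ref)
  out <- list()
  for (strand in c("sense", "antisense")) {
    q <- if (strand == "sense") tag else rc
    qs <- strsplit(q, "")[[1]]
    for (s in seq_len(max(0L, n - L + 1L))) {
      w <- strsplit(substr(ref, s, s + L - 1L), "")[[1]]
      mm <- sum(qs != w)
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + L - 1L, strand = strand, n_mm = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_mm = integer(0)))
  }
  do.call(rbind, out)
}

# Welch two-sample t-test oracle (two-sided p-value from first principles)
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

# Benjamini-Hochberg oracle
bh_adjust <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# small simulated cohort shared by round-trip tests
small_sim <- function(seed, n_hairpins = 6L, n_reads = 4000L, ...) {
  spec <- sim_spec(n_hairpins = n_hairpins, n_reads = n_reads,
                   genome_len = 50000L, seed = seed, ...)
  ref <- sim_reference(spec)
  lib <- simulate_library(ref)
  list(spec = spec, ref = ref, lib = lib)
}
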