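# shared low-level helpers (DNA alphabet internally; RNA only in reports)

DNA_BASES <- c("A", "C", "G", "T")

normalize_seq <- function(x) {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  gsub("U", "T", x, fixed = TRUE)
}

to_rna <- function(x) gsub("T", "U", toupper(as.character(x)), fixed = TRUE)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# weighted mode; ties broken by the smaller value for determinism
weighted_mode <- function(values, weights) {
  if (length(values) == 0L) return(NA)
  tab <- tapply(weights, values, sum)
  keys <- names(tab)[tab == max(tab)]
  keys <- sort(as.numeric(keys))
  keys[1]
}

# read FASTA or FASTQ into a plain character vector of (DNA-normalized) reads
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  normalize_seq(as.character(x))
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

write_fastq <- function(seqs, path, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  qual <- vapply(nchar(seqs), function(k) strrep("I", k), character(1))
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(out, path)
  invisible(path)
}

# empty data.frame constructor with typed columns
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(f) f(0)), stringsAsFactors = FALSE)
}
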