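# Secondary-structure prediction backends behind a common contract:
# sequence in, dot-bracket + score out.

#' Predict a secondary structure for a sequence
#'
#' Backends: `"nussinov"`, the bundled deterministic base-pair maximization
#' dynamic program (score = number of base pairs; allows Watson-Crick and
#' G-U wobble pairs, minimum hairpin loop 3 nt); or `"rnafold"`, ViennaRNA's
#' minimum-free-energy folder when the `RNAfold` executable is on the PATH
#' (score = -MFE in kcal/mol). Both satisfy the same contract, so candidate
#' evaluation is backend-agnostic.
#'
#' @param seq Nucleotide sequence (DNA or RNA alphabet).
#' @param backend `"nussinov"` or `"rnafold"`.
#' @param min_loop Minimum hairpin loop size (nussinov backend).
#' @return list with `structure` (dot-bracket) and `score` (higher = more
#'   stable).
#' @export
fold_sequence <- function(seq, backend = c("nussinov", "rnafold"),
                          min_loop = 3L) {
  backend <- match.arg(backend)
  seq <- normalize_seq(seq)
  if (backend == "rnafold") {
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe)) stop("RNAfold executable not found on PATH")
    out <- system2(exe, args = "--noPS", input = seq, stdout = TRUE)
    line <- out[2]
    db <- sub("\\s+\\(.*$", "", line)
    mfe <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
    return(list(structure = db, score = -mfe))
  }
  .nussinov_fold(seq, min_loop = as.integer(min_loop))
}
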