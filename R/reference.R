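#' Parse a dot-bracket secondary structure into a pair table
#'
#' Matches brackets with a stack and locates the terminal loop: the unpaired
#' span enclosed by an innermost base pair. Structures containing several
#' hairpin loops (multiloop folds) are tolerated with a warning; the longest
#' enclosed unpaired span is taken as the terminal loop.
#'
#' @param structure Dot-bracket string (characters `(`, `)`, `.`).
#' @return An object of class `pair_table`: list with `partner` (integer
#'   vector, 0 = unpaired), `loop` (c(first, last) of the terminal loop or
#'   NULL), `multi_loop` flag and `n` (length).
#' @export
#' @examples
#' pt <- pair_table("((((....))))")
#' pt$partner[1]  # 12
#' pt$loop        # c(5, 8)
pair_table <- function(structure) {
  s <- strsplit(structure, "")[[1]]
  n <- length(s)
  bad <- setdiff(unique(s), c("(", ")", "."))
  if (length(bad)) stop("invalid dot-bracket characters: ", paste(bad, collapse = " "))
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (s[i] == "(") {
      stack <- c(stack, i)
    } else if (s[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at ", stack[1])

  # hairpin loops = maximal unpaired spans directly enclosed by a pair
  loops <- list()
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i + 1L && all(partner[(i + 1L):(j - 1L)] == 0L)) {
      loops[[length(loops) + 1L]] <- c(i + 1L, j - 1L)
    }
  }
  multi <- length(loops) > 1L
  loop <- NULL
  if (length(loops)) {
    spans <- vapply(loops, function(l) l[2] - l[1] + 1L, integer(1))
    loop <- loops[[which.max(spans)]]
    if (multi) warning("structure contains ", length(loops),
                       " hairpin loops; using the longest span as terminal loop")
  } else if (any(partner > 0L)) {
    # paired but no enclosed unpaired span (e.g. "()"): no terminal loop
    warning("no terminal loop found in structure")
  } else if (n > 0L) {
    warning("structure has no base pairs; terminal loop undefined")
  }
  structure(list(partner = partner, loop = loop, loops = loops,
                 multi_loop = multi, n = n),
            class = "pair_table")
}

#' Assign a hairpin interval to an arm
#'
#' An interval lying entirely 5' of the terminal loop is on the `five_prime`
#' arm, entirely 3' of it on the `three_prime` arm; anything overlapping the
#' loop is `loop_spanning` (the AGO2-processed miR-451 configuration).
#'
#' @param start,end 1-based inclusive interval on the hairpin.
#' @param pt A [pair_table()].
#' @return One of `"five_prime"`, `"three_prime"`, `"loop_spanning"`.
#' @export
arm_of <- function(start, end, pt) {
  stopifnot(start >= 1, end <= pt$n, start <= end)
  if (is.null(pt$loop)) return("loop_spanning")
  if (end < pt$loop[1]) "five_prime"
  else if (start > pt$loop[2]) "three_prime"
  else "loop_spanning"
}

read_dot_brackets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L) stop("structure file must have id/structure line pairs")
  ids <- sub("^>", "", trimws(lines[seq(1L, length(lines), by = 2L)]))
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  st <- trimws(lines[seq(2L, length(lines), by = 2L)])
  stats::setNames(st, ids)
}

read_annotation_table <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), "##gff")
  if (is_gff) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 annotations requires the rtracklayer package")
    }
    g <- as.data.frame(rtracklayer::import(path))
    g <- g[as.character(g$type) == "miRNA", , drop = FALSE]
    nm <- as.character(g$Name)
    cls <- rep("mature", nrow(g))
    cls[grepl("\\*$", nm)] <- "star"
    cls[grepl("-5p$", nm)] <- "p5"
    cls[grepl("-3p$", nm)] <- "p3"
    data.frame(hairpin_id = as.character(g$seqnames),
               name = nm,
               start = g$start,
               end = g$end,
               class = cls,
               stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("hairpin_id", "name", "start", "end", "class")
    if (!all(need %in% names(ann))) {
      # headerless 5-column form
      ann <- utils::read.table(path, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE, comment.char = "#")
      if (ncol(ann) != 5L) stop("annotation TSV must have columns ",
                                paste(need, collapse = ", "))
      names(ann) <- need
    }
    ann[need]
  }
}

#' Load and validate a hairpin reference
#'
#' Reads precursor sequences (FASTA), their secondary structures (two lines
#' per record: id then dot-bracket) and mature/star/-5p/-3p annotations (GFF3
#' with `type=miRNA`, or a 5-column TSV: hairpin_id, name, start, end, class).
#' Sequences are stored uppercase in the DNA alphabet (U and T equivalent).
#' Records whose structure length disagrees with the sequence, or whose
#' brackets are unbalanced, are rejected and reported; annotations outside
#' their hairpin are rejected likewise.
#'
#' @param hairpin_fasta Path to the precursor FASTA.
#' @param structure_file Path to the dot-bracket file.
#' @param annotation_file Path to the annotation GFF3/TSV.
#' @return An object of class `hairpin_set`: list with `seq` and `structure`
#'   (named character vectors), `pair_tables` (named list of [pair_table()]),
#'   `annotations` (data.frame with an `arm` column), and `rejected`
#'   (data.frame of ids and reasons).
#' @export
read_hairpin_reference <- function(hairpin_fasta, structure_file, annotation_file) {
  seqs <- normalize_seq(as.character(Biostrings::readBStringSet(hairpin_fasta)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  structs <- read_dot_brackets(structure_file)
  missing <- setdiff(names(structs), names(seqs))
  if (length(missing)) stop("structure ids without FASTA record: ",
                            paste(missing, collapse = ", "))
  nostruct <- setdiff(names(seqs), names(structs))

  rejected <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(nostruct)) {
    rejected <- rbind(rejected, data.frame(id = nostruct, reason = "missing structure"))
    seqs <- seqs[setdiff(names(seqs), nostruct)]
  }

  pts <- list()
  keep <- character(0)
  for (id in names(seqs)) {
    st <- structs[[id]]
    if (nchar(st) != nchar(seqs[[id]])) {
      rejected <- rbind(rejected,
                        data.frame(id = id, reason = "structure/sequence length mismatch"))
      next
    }
    pt <- tryCatch(pair_table(st), error = function(e) e)
    if (inherits(pt, "error")) {
      rejected <- rbind(rejected, data.frame(id = id, reason = conditionMessage(pt)))
      next
    }
    pts[[id]] <- pt
    keep <- c(keep, id)
  }
  seqs <- seqs[keep]
  structs <- structs[keep]

  ann <- read_annotation_table(annotation_file)
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ok <- ann$hairpin_id %in% keep
  bad_hp <- ann[!ok, , drop = FALSE]
  ann <- ann[ok, , drop = FALSE]
  inb <- ann$start >= 1L & ann$start <= ann$end &
    ann$end <= nchar(seqs[ann$hairpin_id])
  if (any(!inb)) {
    rejected <- rbind(rejected,
                      data.frame(id = ann$name[!inb], reason = "annotation outside hairpin"))
  }
  if (nrow(bad_hp)) {
    rejected <- rbind(rejected,
                      data.frame(id = bad_hp$name, reason = "annotation on unknown hairpin"))
  }
  ann <- ann[inb, , drop = FALSE]
  ann$arm <- vapply(seq_len(nrow(ann)), function(i) {
    arm_of(ann$start[i], ann$end[i], pts[[ann$hairpin_id[i]]])
  }, character(1))
  rownames(ann) <- NULL

  structure(list(seq = seqs, structure = structs, pair_tables = pts,
                 annotations = ann, rejected = rejected),
            class = "hairpin_set")
}

# assemble a hairpin_set directly from in-memory vectors (used by the
# simulator and by tests)
hairpin_set <- function(seqs, structures, annotations) {
  seqs <- normalize_seq(seqs)
  stopifnot(!is.null(names(seqs)), all(names(seqs) == names(structures)),
            all(nchar(seqs) == nchar(structures)))
  pts <- lapply(structures, pair_table)
  annotations$start <- as.integer(annotations$start)
  annotations$end <- as.integer(annotations$end)
  annotations$arm <- vapply(seq_len(nrow(annotations)), function(i) {
    arm_of(annotations$start[i], annotations$end[i],
           pts[[annotations$hairpin_id[i]]])
  }, character(1))
  structure(list(seq = seqs, structure = structures, pair_tables = pts,
                 annotations = annotations,
                 rejected = data.frame(id = character(0), reason = character(0))),
            class = "hairpin_set")
}

#' @export
print.hairpin_set <- function(x, ...) {
  cat(sprintf("hairpin_set: %d hairpins, %d annotations (%d records rejected)\n",
              length(x$seq), nrow(x$annotations), nrow(x$rejected)))
  invisible(x)
}
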