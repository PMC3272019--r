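# Read collapsing, alignment, MMR and mismatch classification.

test_that("collapse_reads counts unique tags and drops out-of-range reads", {
  r22 <- strrep("ACGT", 5)          # 20 nt
  other <- strrep("GTCA", 5)
  tags <- collapse_reads(c(rep(r22, 5), rep(other, 3), "ACGTACGTAC"))
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$count[tags$sequence == r22], 5L)
  expect_equal(tags$count[tags$sequence == other], 3L)
  expect_equal(attr(tags, "dropped"), 1L)   # the 10-nt read
  expect_warning(empty <- collapse_reads(character(0)), "no reads")
  expect_equal(nrow(empty), 0L)
})

test_that("collapse_reads conserves read counts", {
  set.seed(11)
  reads <- vapply(sample(15:35, 2000, replace = TRUE),
                  mircensus:::random_dna, character(1))
  tags <- collapse_reads(reads)
  expect_equal(sum(tags$count) + attr(tags, "dropped"), 2000L)
  expect_equal(attr(tags, "dropped"), 0L)
})

test_that("hairpin alignment finds exact, mismatched and multi-locus hits", {
  ref <- toy_reference()
  exact <- substr(toy_seq(), 8, 29)
  tg <- data.frame(sequence = exact, count = 10L, library_id = "lib1")
  pl <- align_to_hairpins(tg, ref)
  sense <- pl[pl$strand == "sense" & pl$n_mismatch == 0L, ]
  expect_equal(nrow(sense), 1L)
  expect_equal(c(sense$start, sense$end), c(8L, 29L))

  sub10 <- exact
  substr(sub10, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(exact, 10, 10))[1]
  pl2 <- align_to_hairpins(
    data.frame(sequence = sub10, count = 1L, library_id = "l"), ref)
  hit <- pl2[pl2$strand == "sense" & pl2$start == 8L, ]
  expect_equal(hit$n_mismatch, 1L)
  mm <- decode_mismatches(hit$mismatches)
  expect_equal(mm$pos, 10L)
  expect_equal(mm$ref, substr(exact, 10, 10))
  expect_equal(mm$alt, substr(sub10, 10, 10))

  # two identical hairpins -> two placements before MMR
  twin <- mircensus:::hairpin_set(
    c(a = toy_seq(), b = toy_seq()),
    c(a = toy_structure(), b = toy_structure()),
    data.frame(hairpin_id = c("a", "b"), name = c("mA", "mB"),
               start = 8L, end = 29L, class = "mature"))
  pl3 <- align_to_hairpins(
    data.frame(sequence = exact, count = 4L, library_id = "l"), twin)
  expect_equal(sum(pl3$strand == "sense" & pl3$n_mismatch == 0L), 2L)
})

test_that("tags longer than the hairpin get no placement", {
  ref <- toy_reference()
  long <- mircensus:::random_dna(80)
  pl <- align_to_hairpins(
    data.frame(sequence = long, count = 1L, library_id = "l"), ref)
  expect_equal(nrow(pl), 0L)
})

test_that("genome alignment places both strands and discards repeats", {
  set.seed(5)
  tag <- mircensus:::random_dna(22)
  left <- mircensus:::random_dna(1000)
  right <- mircensus:::random_dna(978)
  genome <- c(chr1 = paste0(left, tag, right))
  tg <- data.frame(sequence = tag, count = 3L, library_id = "l")
  pl <- align_to_genome(tg, genome, max_mismatches = 0L)
  expect_equal(pl$start, 1001L)
  expect_equal(pl$end, 1022L)
  expect_equal(pl$strand, "sense")

  rc <- mircensus:::revcomp(tag)
  pl2 <- align_to_genome(
    data.frame(sequence = rc, count = 1L, library_id = "l"), genome,
    max_mismatches = 0L)
  expect_equal(pl2$strand, "antisense")
  expect_equal(c(pl2$start, pl2$end), c(1001L, 1022L))

  # a tag planted 12 times exceeds the default cap of 10 and is discarded
  rep_tag <- mircensus:::random_dna(20)
  genome2 <- c(chr1 = paste0(paste(rep(paste0(rep_tag,
                                              mircensus:::random_dna(30)), 12),
                                   collapse = ""),
                             mircensus:::random_dna(200)))
  pl3 <- align_to_genome(
    data.frame(sequence = rep_tag, count = 1L, library_id = "l"), genome2,
    max_mismatches = 0L)
  expect_equal(nrow(pl3), 0L)
  expect_equal(attr(pl3, "discarded"), rep_tag)
})

test_that("aligner agrees with a brute-force comparator", {
  set.seed(202)
  for (i in seq_len(120)) {
    ref_seq <- mircensus:::random_dna(sample(40:90, 1))
    # half the cases plant the tag inside the reference
    if (i %% 2 == 0) {
      s <- sample(1:(nchar(ref_seq) - 24), 1)
      tag <- substr(ref_seq, s, s + sample(15:22, 1))
      if (i %% 4 == 0) {
        p <- sample(nchar(tag), 1)
        substr(tag, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    } else {
      tag <- mircensus:::random_dna(sample(15:25, 1))
    }
    got <- align_to_hairpins(
      data.frame(sequence = tag, count = 1L, library_id = "l"),
      list(seq = c(r = ref_seq)), max_mismatches = 1L)
    want <- brute_force_align(tag, ref_seq, 1L)
    got_key <- sort(paste(got$start, got$end, got$strand, got$n_mismatch))
    want_key <- sort(paste(want$start, want$end, want$strand, want$n_mm))
    expect_identical(got_key, want_key)
  }
})

test_that("MMR keeps perfect placements and splits weights evenly", {
  p <- rbind(mk_placement("T1", 10, "hpA", 8, 29, n_mm = 0),
             mk_placement("T1", 10, "hpB", 8, 29, n_mm = 1, mm = "3:A>G"))
  r <- mmr_resolve(p)
  expect_equal(nrow(r), 1L)
  expect_equal(r$target_id, "hpA")
  expect_equal(r$weight, 1)

  # perfect ties on identical loci share the count and are flagged
  p2 <- rbind(mk_placement("T2", 9, "hpA", 8, 29),
              mk_placement("T2", 9, "hpB", 8, 29))
  r2 <- mmr_resolve(p2)
  expect_equal(r2$weight, c(0.5, 0.5))
  expect_true(all(grepl("identical-locus", r2$flags)))
  expect_equal(sum(r2$weight * r2$count), 9)

  # only mismatched placements: equal thirds
  p3 <- rbind(mk_placement("T3", 6, "hpA", 5, 26, n_mm = 1, mm = "1:A>G"),
              mk_placement("T3", 6, "hpB", 9, 30, n_mm = 1, mm = "2:C>T"),
              mk_placement("T3", 6, "hpC", 2, 23, n_mm = 1, mm = "4:G>A"))
  r3 <- mmr_resolve(p3)
  expect_equal(r3$weight, rep(1 / 3, 3))
})

test_that("MMR is idempotent and conserves counts on simulated data", {
  sim <- small_sim(seed = 21)
  tags <- collapse_reads(sim$lib$reads)
  pl <- align_to_hairpins(tags, sim$ref$hairpins)
  r1 <- mmr_resolve(pl)
  r2 <- mmr_resolve(r1)
  expect_equal(r1, r2)
  placed <- tags$count[tags$sequence %in% unique(r1$tag_seq)]
  expect_equal(sum(r1$weight * r1$count), sum(placed), tolerance = 1e-9)
})

test_that("mismatch classes separate NTA from internal substitutions", {
  p <- rbind(
    mk_placement("ACGTACGTACGTACGTACGTAT", 1, "h", 1, 22, n_mm = 1,
                 mm = "22:C>T"),            # last position, added U (T)
    mk_placement("ACGTACGTGCGTACGTACGTAC", 1, "h", 1, 22, n_mm = 1,
                 mm = "9:A>G"),             # internal A-to-G (editing-like)
    mk_placement("ACGTACGTACGTACGTACGTAC", 1, "h", 1, 22))
  cl <- classify_mismatches(p)
  expect_equal(cl$mismatch_class, c("nta", "internal", "clean"))
  expect_equal(cl$mismatch_subtype, c("U", "A-to-G", ""))
})
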