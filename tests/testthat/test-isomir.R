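# Variant taxonomy: generic calls and offsets, novel miR*, e-miRs,
# summaries and text rendering.

toy_tag <- function(s, e, count = 1, n_mm = 0L, mm = "") {
  mk_placement(substr(toy_seq(), s, e), count, "toy-mir-1", s, e,
               n_mm = n_mm, mm = mm)
}

test_that("generic window is +/- 3 nt around the annotated 5' start", {
  ref <- toy_reference()
  cfg <- census_config()
  sweep <- do.call(rbind, lapply(-5:5, function(d) toy_tag(8 + d, 29)))
  calls <- assign_features(sweep, ref, cfg)
  gen <- startsWith(calls$label, "generic_")
  expect_equal(calls$five_prime_offset[gen], (-5:5)[abs(-5:5) <= 3])
  expect_equal(max(abs(calls$five_prime_offset[gen])), 3L)
  expect_true(all(calls$label[!gen] == "emir_candidate"))

  # offsets measured against the anchor: +1 start keeps the annotated 3' end
  one <- assign_features(toy_tag(9, 29), ref, cfg)
  expect_equal(one$label, "generic_mature")
  expect_equal(one$five_prime_offset, 1L)
  expect_equal(one$three_prime_offset, 0L)
})

test_that("loop-spanning tags are unassigned and flagged", {
  calls <- assign_features(toy_tag(25, 46), toy_reference())
  expect_equal(calls$label, "unassigned")
  expect_true(grepl("loop_spanning", calls$flags))
})

test_that("taxonomy is a partition and offsets shift under re-annotation", {
  sim <- small_sim(seed = 31)
  cen <- suppressWarnings(mir_census(sim$lib$reads, sim$ref$hairpins))
  calls <- cen$calls
  expect_true(all(calls$label %in% c("generic_mature", "generic_star",
                                     "generic_p5", "generic_p3",
                                     "novel_star_candidate", "emir_candidate",
                                     "unassigned")))
  # weighted label counts partition the weighted hairpin tags exactly
  expect_equal(sum(calls$weighted_count),
               sum(tapply(calls$weighted_count, calls$label, sum)),
               tolerance = 1e-9)

  # shifting every annotated start by +1 shifts 5' offsets by -1
  ref2 <- sim$ref$hairpins
  ref2$annotations$start <- ref2$annotations$start + 1L
  pl <- cen$placements
  c1 <- assign_features(pl, sim$ref$hairpins)
  c2 <- assign_features(pl, ref2)
  both <- startsWith(c1$label, "generic_") & startsWith(c2$label, "generic_") &
    c1$anchor_name == c2$anchor_name
  expect_gt(sum(both), 0)
  expect_equal(c2$five_prime_offset[both], c1$five_prime_offset[both] - 1L)
})

test_that("summaries report isomiR proportions and flags", {
  ref <- toy_reference()
  p <- rbind(toy_tag(8, 29, count = 60), toy_tag(9, 29, count = 40))
  s <- summarize_hairpins(assign_features(p, ref))
  m <- s$mirna[s$mirna$name == "toy-miR-1", ]
  expect_equal(m$p5_isomir_prop, 0.4)
  expect_true(grepl("high_5p_isomir", m$flags))
  expect_equal(m$p3_isomir_prop, 0)
  expect_equal(m$total, 100)
  expect_equal(m$modal_length, 22)
  expect_equal(c(m$dom_start, m$dom_end), c(8L, 29L))
})

test_that("planted 5' isomiR mixture is recovered within the binomial CI", {
  spec <- sim_spec(n_hairpins = 2, n_reads = 10000, identical_loci = TRUE,
                   p_pattern_mature_star = 1, n_single_arm = 0,
                   arm_fractions = 1,
                   offset5_probs = c(`0` = 0.499, `1` = 0.501),
                   emir = NULL, antisense = NULL, novel = NULL,
                   genome_len = 1000L, seed = 7)
  ref <- sim_reference(spec)
  lib <- simulate_library(ref)
  cen <- suppressWarnings(mir_census(lib$reads, ref$hairpins))
  m <- cen$summary$mirna[1, ]
  se <- sqrt(0.501 * 0.499 / m$total)
  expect_lt(abs(m$p5_isomir_prop - 0.501), 3 * se)
  # the two identical loci carry identical-locus flags after MMR
  expect_true(any(grepl("identical-locus", cen$placements$flags)))
})

test_that("novel miR* calls require phasing and canonical geometry", {
  # single-arm annotation: mature on 5' arm only
  ref <- mircensus:::hairpin_set(
    c(h = toy_seq()), c(h = toy_structure()),
    data.frame(hairpin_id = "h", name = "miR-x", start = 8L, end = 29L,
               class = "mature"))
  star_exact <- mk_placement(substr(toy_seq(), 44, 65), 50, "h", 44, 65)
  calls <- assign_features(star_exact, ref)
  expect_equal(calls$label, "novel_star_candidate")
  ns <- detect_novel_star(calls, ref)
  expect_equal(nrow(ns), 1L)
  expect_equal(ns$label, "novel_generic_star")
  expect_equal(ns$overhang_drosha, 2)
  expect_equal(ns$overhang_dicer, 2)
  expect_equal(ns$name, "miR-x*")

  # displaced 6 nt from the canonical duplex position: non-generic star
  disp <- mk_placement(substr(toy_seq(), 50, 69), 50, "h", 50, 69)
  ns2 <- detect_novel_star(assign_features(disp, ref), ref)
  expect_equal(ns2$label, "novel_star")

  # diffuse starts (max phase fraction well below 0.5): no call
  diffuse <- do.call(rbind, lapply(c(42, 45, 48, 51), function(s)
    mk_placement(substr(toy_seq(), s, s + 19), 10, "h", s, s + 19)))
  ns3 <- detect_novel_star(assign_features(diffuse, ref), ref)
  expect_equal(nrow(ns3), 0L)
})

test_that("e-miR calls honour fraction, phasing and length filters", {
  ref <- toy_reference()
  cfg <- census_config()
  # dominant non-generic set (99.7% of hairpin tags), e-miR-721*-like
  p <- rbind(toy_tag(12, 30, count = 997), toy_tag(8, 29, count = 3))
  em <- detect_emir(assign_features(p, ref), ref, cfg)
  expect_equal(nrow(em), 1L)
  expect_equal(em$fraction, 0.997)
  expect_equal(em$name, "e-miR-1")
  expect_equal(c(em$start, em$end), c(12L, 30L))

  # below the 20% threshold: no call
  p2 <- rbind(toy_tag(12, 30, count = 100), toy_tag(8, 29, count = 900))
  expect_equal(nrow(detect_emir(assign_features(p2, ref), ref, cfg)), 0L)

  # 30-nt tags fail the credible-length filter despite fraction 0.4
  p3 <- rbind(toy_tag(1, 30, count = 400), toy_tag(8, 29, count = 600))
  em3 <- detect_emir(assign_features(p3, ref), ref, cfg)
  expect_equal(nrow(em3), 0L)

  # loop-overlapping e-miR set is flagged as an AGO2 candidate
  p4 <- rbind(toy_tag(25, 46, count = 500), toy_tag(8, 29, count = 500))
  em4 <- detect_emir(assign_features(p4, ref), ref, cfg)
  expect_equal(nrow(em4), 1L)
  expect_equal(em4$flags, "AGO2-candidate")

  # below the hairpin expression threshold nothing is screened
  p5 <- rbind(toy_tag(12, 30, count = 99), toy_tag(8, 29, count = 3))
  expect_equal(nrow(detect_emir(assign_features(p5, ref), ref, cfg)), 0L)
})

test_that("text alignments stack tags at their columns, mismatches lowercased", {
  ref <- toy_reference()
  p <- rbind(toy_tag(8, 29, count = 5),
             mk_placement(paste0(substr(toy_seq(), 8, 28), "A"), 9,
                          "toy-mir-1", 8, 29, n_mm = 1, mm = "22:C>A"))
  calls <- assign_features(p, ref)
  txt <- render_hairpin_alignment(ref, "toy-mir-1", calls)
  expect_equal(txt[1], ">toy-mir-1")
  expect_equal(txt[2], toy_seq())
  expect_equal(txt[3], toy_structure())
  # most abundant tag first; indented by start - 1 columns
  expect_match(txt[4], paste0("^", strrep(" ", 7), "[ACGTacgt]"))
  # the NTA tag line ends its sequence with a lowercase base
  nta_line <- txt[grepl("a  x", txt)]
  expect_equal(length(nta_line), 1L)
  # descending weighted count
  counts <- as.numeric(sub(".*x([0-9.]+) .*", "\\1", txt[-(1:3)]))
  expect_true(all(diff(counts) <= 0))
})
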