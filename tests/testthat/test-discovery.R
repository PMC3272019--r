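# Genomic tag clustering, window folding, candidate evaluation and the
# antisense screen.

mk_genome_placement <- function(tag_seq, count, start, strand = "sense",
                                chrom = "chr1", weight = 1) {
  mk_placement(tag_seq, count, chrom, start, start + nchar(tag_seq) - 1L,
               strand = strand, weight = weight, target_type = "genome")
}

test_that("clustering groups phased tags and applies the thresholds", {
  tag <- mircensus:::random_dna(22)
  p <- mk_genome_placement(tag, 100, 5000)
  cl <- cluster_genome_tags(p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$phase_fraction, 1)
  expect_equal(cl$modal_start, 5000L)

  # 40/30/30 split over starts 10 nt apart: phase fraction 0.4, discarded
  p2 <- rbind(mk_genome_placement(mircensus:::random_dna(22), 40, 5000),
              mk_genome_placement(mircensus:::random_dna(22), 30, 5010),
              mk_genome_placement(mircensus:::random_dna(22), 30, 5020))
  expect_equal(nrow(cluster_genome_tags(p2)), 0L)

  # two phased clusters 60 nt apart both survive
  p3 <- rbind(mk_genome_placement(mircensus:::random_dna(22), 80, 5000),
              mk_genome_placement(mircensus:::random_dna(22), 80, 5060))
  expect_equal(nrow(cluster_genome_tags(p3)), 2L)

  # below the minimum weighted count: discarded
  p4 <- mk_genome_placement(mircensus:::random_dna(22), 49, 5000)
  expect_equal(nrow(cluster_genome_tags(p4)), 0L)

  # size selection drops 30-nt tags
  p5 <- mk_genome_placement(mircensus:::random_dna(30), 500, 5000)
  expect_equal(nrow(cluster_genome_tags(p5)), 0L)
})

test_that("folding is deterministic and recovers a planted stem", {
  set.seed(61)
  sl <- mircensus:::make_stem_loop(24, 8)
  genome <- c(chr1 = paste0(mircensus:::random_dna(60), sl$seq,
                            mircensus:::random_dna(60)))
  f1 <- fold_sequence(sl$seq)
  f2 <- fold_sequence(sl$seq)
  expect_identical(f1, f2)
  pt_pred <- pair_table(f1$structure)
  pt_true <- pair_table(sl$struct)
  planted <- which(pt_true$partner > seq_along(pt_true$partner))
  recovered <- sum(pt_pred$partner[planted] == pt_true$partner[planted])
  expect_gte(recovered, 20)
})

test_that("candidate evaluation applies each mandatory criterion", {
  set.seed(62)
  sl <- mircensus:::make_stem_loop(30, 10)
  genome <- c(chr1 = paste0(mircensus:::random_dna(300), sl$seq,
                            mircensus:::random_dna(300)))
  mature <- substr(sl$seq, 8, 29)
  star <- substr(sl$seq, 44, 65)
  p <- rbind(mk_genome_placement(mature, 400, 308),
             mk_genome_placement(star, 100, 344))
  clusters <- cluster_genome_tags(p)
  expect_equal(nrow(clusters), 2L)
  disc <- discover_novel(p, genome)
  expect_equal(nrow(disc$accepted), 1L)
  expect_equal(disc$accepted$name, "miR-N1")
  expect_true(disc$accepted$star_support)
  expect_true(any(disc$candidates$is_star))

  # cluster spanning the loop is rejected
  loop_tag <- substr(sl$seq, 25, 46)
  cl_loop <- cluster_genome_tags(mk_genome_placement(loop_tag, 400, 325))
  fw <- fold_window(genome, cl_loop[1, ], census_config())
  cand <- evaluate_candidate(cl_loop[1, ], fw)
  expect_equal(cand$verdict, "rejected")
  expect_equal(cand$reason, "loop_overlap")

  # a 14-bp stem fails the stem criterion
  sl14 <- mircensus:::make_stem_loop(14, 8)
  genome2 <- c(chr1 = paste0(mircensus:::random_dna(200), sl14$seq,
                             mircensus:::random_dna(200)))
  tag14 <- substr(sl14$seq, 1, 14)
  p14 <- mk_genome_placement(paste0(tag14, substr(sl14$seq, 15, 22)), 400, 201)
  cl14 <- cluster_genome_tags(p14)
  cand14 <- evaluate_candidate(cl14[1, ],
                               fold_window(genome2, cl14[1, ], census_config()))
  expect_equal(cand14$verdict, "rejected")
})

test_that("discovery recall is complete on easy loci with no false positives", {
  # four planted loci, clean reads at count 500 (plus star support)
  spec <- sim_spec(n_hairpins = 2, n_reads = 8000,
                   nta_rate = 0, error_rate = 0,
                   emir = NULL, antisense = NULL,
                   novel = list(n = 4, fraction = 0.125, star_fraction = 0.2),
                   genome_len = 60000, seed = 71)
  ref <- sim_reference(spec)
  lib <- simulate_library(ref)
  cen <- suppressWarnings(mir_census(lib$reads, ref$hairpins,
                                     genome = ref$genome))
  expect_equal(nrow(cen$discovery$accepted), 4L)
  # accepted intervals sit inside the planted loci (round-trip coordinates)
  for (i in seq_len(4)) {
    acc <- cen$discovery$accepted[i, ]
    truth <- ref$truth$novel
    hit <- truth[truth$start <= acc$dom_start & truth$end >= acc$dom_end, ]
    expect_equal(nrow(hit), 1L)
    # the candidate window sequence round-trips from the genome coordinates
    det <- cen$discovery$details[[acc$cluster_id]]$folded
    expect_equal(det$sequence,
                 substr(ref$genome[["chr1"]], det$window_start, det$window_end))
  }

  # shuffled-genome controls: pseudo-clusters on random sequence, 0 accepted
  set.seed(72)
  shuffled <- c(chr1 = mircensus:::random_dna(60000))
  accepted <- 0L
  for (k in seq_len(100)) {
    pos <- sample(200:59000, 1)
    cl <- data.frame(cluster_id = sprintf("ctl%03d", k), chrom = "chr1",
                     strand = "sense", modal_start = pos,
                     span_start = pos, span_end = pos + 21L,
                     dom_start = pos, dom_end = pos + 21L,
                     weighted_count = 500, phase_fraction = 1,
                     modal_length = 22, stringsAsFactors = FALSE)
    cand <- evaluate_candidate(cl, fold_window(shuffled, cl, census_config()))
    accepted <- accepted + (cand$verdict == "accepted")
  }
  expect_equal(accepted, 0L)
})

test_that("antisense screen needs both arms and enough expression", {
  spec <- sim_spec(n_hairpins = 4, n_reads = 6000, genome_len = 5000,
                   emir = NULL, novel = NULL,
                   antisense = list(hairpin = 3, fraction = 0.1),
                   seed = 81)
  ref <- sim_reference(spec)
  lib <- simulate_library(ref)
  cen <- suppressWarnings(mir_census(lib$reads, ref$hairpins))
  acc <- cen$antisense[cen$antisense$verdict == "accepted", ]
  expect_equal(acc$hairpin_id, "syn-mir-3")
  expect_equal(acc$name, "syn-mir-3-as")

  # one-arm antisense tags only: rejected for lack of an opposing tag
  hp <- ref$hairpins
  one_arm <- mk_placement(
    mircensus:::revcomp(substr(hp$seq[["syn-mir-1"]], 8, 29)),
    500, "syn-mir-1", 8, 29, strand = "antisense")
  res <- detect_antisense(one_arm, hp)
  expect_equal(res$verdict, "rejected")
  expect_equal(res$reason, "no_opposing_tag")

  # sense-only placements yield no antisense candidates
  sense_only <- mk_placement(substr(hp$seq[["syn-mir-1"]], 8, 29), 500,
                             "syn-mir-1", 8, 29)
  expect_equal(nrow(detect_antisense(sense_only, hp)), 0L)
})
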