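# Terminal composition profiles and tests, duplex geometry, distortions.

test_that("position profiles weight isomiRs and renormalize per miRNA", {
  ref <- toy_reference()
  cfg <- census_config(min_expression = 10)
  # two isomiRs 70:30 with different first bases: 8 starts with G, 9 with T
  # (toy arm: ...GGT at 7-9); check against the actual bases
  b8 <- substr(toy_seq(), 8, 8); b9 <- substr(toy_seq(), 9, 9)
  expect_true(b8 != b9)
  p <- rbind(mk_placement(substr(toy_seq(), 8, 29), 70, "toy-mir-1", 8, 29),
             mk_placement(substr(toy_seq(), 9, 29), 30, "toy-mir-1", 9, 29))
  pr <- build_position_profiles(assign_features(p, ref, cfg), ref, cfg)
  first <- pr$profiles[pr$profiles$position == "first", ]
  rna <- function(b) chartr("T", "U", b)
  expect_equal(first[[rna(b8)]], 0.7)
  expect_equal(first[[rna(b9)]], 0.3)
  # every frequency vector sums to 1
  mat <- as.matrix(pr$profiles[, c("A", "C", "G", "U")])
  expect_equal(unname(rowSums(mat)), rep(1, nrow(mat)), tolerance = 1e-9)
  # background is the exact arithmetic mean of the vectors
  expect_equal(pr$background, colMeans(mat), tolerance = 1e-12)
})

test_that("single-isomiR profile is a unit vector at the observed base", {
  ref <- toy_reference()
  cfg <- census_config(min_expression = 1)
  p <- mk_placement(substr(toy_seq(), 44, 65), 5, "toy-mir-1", 44, 65)
  pr <- build_position_profiles(assign_features(p, ref, cfg), ref, cfg)
  first <- pr$profiles[pr$profiles$position == "first", c("A", "C", "G", "U")]
  expect_equal(sort(unname(unlist(first)), decreasing = TRUE)[1], 1)
})

test_that("Welch composition test matches a first-principles oracle", {
  set.seed(303)
  for (i in seq_len(100)) {
    x <- stats::runif(sample(3:30, 1))
    y <- stats::runif(sample(3:30, 1))
    expect_equal(stats::t.test(x, y, var.equal = FALSE)$p.value,
                 welch_p(x, y), tolerance = 1e-9)
  }
})

test_that("composition test flags planted first-position enrichment", {
  # 40 synthetic miRNAs whose first base is U at frequency ~0.8 against a
  # uniform background at the other positions
  set.seed(17)
  bases <- c("A", "C", "G", "U")
  rows <- list()
  for (m in seq_len(40)) {
    for (pos in c("ext5", "first", "last", "ext3")) {
      if (pos == "first") {
        u <- stats::runif(1, 0.75, 0.85)
        v <- c((1 - u) / 3, (1 - u) / 3, (1 - u) / 3, u)
      } else {
        v <- as.numeric(stats::rmultinom(1, 50, rep(0.25, 4))) / 50
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("m", m), hairpin_id = paste0("h", m),
        arm = "five_prime", position = pos,
        A = v[1], C = v[2], G = v[3], U = v[4])
    }
  }
  profiles <- do.call(rbind, rows)
  mat <- as.matrix(profiles[, bases])
  bg <- do.call(rbind, lapply(split(profiles, profiles$name), function(d)
    data.frame(name = d$name[1], arm = "five_prime",
               t(colMeans(as.matrix(d[, bases]))))))
  pr <- structure(list(profiles = profiles, background = colMeans(mat),
                       mirna_background = bg), class = "position_profiles")
  af <- data.frame(name = unique(profiles$name), arm_fraction = 0.9)
  res <- composition_test(pr, af)
  hit <- res[res$group == "major" & res$position == "first" & res$base == "U", ]
  expect_equal(hit$status, "enriched")
  expect_lt(hit$p_value, 1e-6)
})

test_that("profiles identical to background give no composition calls", {
  flat <- expand.grid(name = paste0("m", 1:5),
                      position = c("ext5", "first", "last", "ext3"),
                      stringsAsFactors = FALSE)
  profiles <- data.frame(name = flat$name, hairpin_id = flat$name,
                         arm = "five_prime", position = flat$position,
                         A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  bg <- data.frame(name = paste0("m", 1:5), arm = "five_prime",
                   A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  pr <- structure(list(profiles = profiles,
                       background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       mirna_background = bg), class = "position_profiles")
  af <- data.frame(name = paste0("m", 1:5), arm_fraction = 0.9)
  res <- composition_test(pr, af)
  expect_true(all(res$status == "ns"))
})

test_that("small groups are reported ns with a flag", {
  ref <- toy_reference()
  cfg <- census_config(min_expression = 1)
  p <- mk_placement(substr(toy_seq(), 8, 29), 5, "toy-mir-1", 8, 29)
  pr <- build_position_profiles(assign_features(p, ref, cfg), ref, cfg)
  af <- data.frame(name = "toy-miR-1", arm_fraction = 0.9)
  res <- composition_test(pr, af, cfg)
  expect_true(all(res$status[res$flags == "small_group"] == "ns"))
})

test_that("canonical toy duplex has 2-nt overhangs at both ends", {
  pt <- pair_table(toy_structure())
  d <- reconstruct_duplex(c(8, 29), c(44, 65), pt)
  expect_equal(d$overhang_drosha, 2)
  expect_equal(d$overhang_dicer, 2)
  expect_true(d$first_nt_paired_5p)
  expect_true(d$first_nt_paired_3p)
  expect_false(d$anchored_unpaired)

  # trimming the 3p end to 63 gives a blunt Drosha end
  d2 <- reconstruct_duplex(c(8, 29), c(44, 63), pt)
  expect_equal(d2$overhang_drosha, 0)
  expect_equal(d2$overhang_dicer, 2)
})

test_that("unpaired anchors use the nearest paired position inward", {
  st <- strsplit(toy_structure(), "")[[1]]
  st[c(8, 63)] <- "."   # unpair the 5p start and its partner
  pt <- suppressWarnings(pair_table(paste(st, collapse = "")))
  d <- reconstruct_duplex(c(8, 29), c(44, 65), pt)
  expect_false(d$first_nt_paired_5p)
  expect_true(d$anchored_unpaired)
  expect_equal(d$overhang_drosha, 2)   # gap-corrected estimate
})

test_that("overhang magnitudes are conserved under reverse-complement", {
  # the reverse-complement description swaps the arms and duplex ends and
  # turns 3' overhangs into 5' overhangs (sign flip); magnitudes persist
  pt <- pair_table(toy_structure())
  fwd <- reconstruct_duplex(c(8, 29), c(44, 65), pt)
  n <- 70L
  rev_iv <- function(iv) c(n + 1L - iv[2], n + 1L - iv[1])
  rev_struct <- paste(rev(chartr("()", ")(",
                                 strsplit(toy_structure(), "")[[1]])),
                      collapse = "")
  ptr <- pair_table(rev_struct)
  bwd <- reconstruct_duplex(rev_iv(c(44, 65)), rev_iv(c(8, 29)), ptr)
  expect_equal(bwd$overhang_drosha, -fwd$overhang_dicer)
  expect_equal(bwd$overhang_dicer, -fwd$overhang_drosha)
})

test_that("distortion classes follow the windowed pairing rules", {
  pt <- pair_table(toy_structure())
  dup <- reconstruct_duplex(c(8, 29), c(44, 65), pt)
  d <- classify_distortions(dup, pt)
  expect_equal(d$drosha$kind, "fully_paired")
  # canonical geometry leaves the Dicer site 1 nt from the loop
  expect_equal(d$dicer$kind, "terminal_loop_adjacent")
  expect_equal(d$dicer$offset, 1L)

  # cut immediately before the loop: offset 0
  dup0 <- reconstruct_duplex(c(9, 30), c(43, 64), pt)
  expect_equal(classify_distortions(dup0, pt)$dicer$offset, 0L)

  # symmetric 2-nt internal loop at the Drosha site
  st <- strsplit(toy_structure(), "")[[1]]
  st[c(7, 64)] <- "."
  pt2 <- pair_table(paste(st, collapse = ""))
  d2 <- classify_distortions(reconstruct_duplex(c(8, 29), c(44, 65), pt2), pt2)
  expect_equal(d2$drosha$kind, "sym_internal_loop_2")

  # symmetric 4-nt internal loop
  st4 <- strsplit(toy_structure(), "")[[1]]
  st4[c(6, 7, 64, 65)] <- "."
  pt4 <- suppressWarnings(pair_table(paste(st4, collapse = "")))
  d4 <- classify_distortions(reconstruct_duplex(c(8, 29), c(44, 65), pt4), pt4)
  expect_equal(d4$drosha$kind, "sym_internal_loop_4")

  # a bulge: unpaired run on one strand only near the Drosha boundary
  # (structure with one extra unpaired nt on the 5' strand)
  bulge <- "((((((.((((((....))))))))))))"
  ptb <- pair_table(bulge)
  dupb <- reconstruct_duplex(c(2, 10), c(20, 28), ptb)
  db <- classify_distortions(dupb, ptb)
  expect_equal(db$drosha$kind, "fully_paired")
  dupb2 <- reconstruct_duplex(c(8, 13), c(18, 25), ptb)
  db2 <- classify_distortions(dupb2, ptb)
  expect_equal(db2$drosha$kind, "bulge")
})

test_that("a canonical synthetic cohort reports 2-nt overhangs throughout", {
  sim <- small_sim(seed = 51, n_reads = 6000,
                   nta_rate = 0, error_rate = 0,
                   emir = NULL, antisense = NULL, novel = NULL,
                   offset5_probs = c(`0` = 1), offset3_probs = c(`0` = 1))
  cen <- suppressWarnings(mir_census(sim$lib$reads, sim$ref$hairpins))
  dup <- cen$duplexes$duplexes
  expect_gt(nrow(dup), 0)
  expect_true(all(dup$overhang_drosha == 2))
  expect_true(all(dup$overhang_dicer == 2))
})

test_that("planted Drosha distortions round-trip through the simulator", {
  spec <- sim_spec(n_hairpins = 4, n_reads = 4000, genome_len = 5000,
                   emir = NULL, antisense = NULL, novel = NULL,
                   n_single_arm = 0,
                   distortions = data.frame(hairpin = 3, site = "drosha",
                                            kind = "sym2"),
                   seed = 13)
  ref <- sim_reference(spec)
  lib <- simulate_library(ref)
  cen <- suppressWarnings(mir_census(lib$reads, ref$hairpins))
  dup <- cen$duplexes$duplexes
  hit <- dup[dup$hairpin_id == "syn-mir-3", ]
  expect_equal(hit$drosha_class, "sym_internal_loop_2")
  expect_true(all(dup$drosha_class[dup$hairpin_id != "syn-mir-3"] ==
                    "fully_paired"))
})
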