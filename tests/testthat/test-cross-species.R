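test_that("the engineered nested chain is reproduced exactly", {
  f <- make_chain_fixture()
  bd <- orthology_breakdown(f$regions, f$ortho, f$marks, f$mask, f$calls)
  expect_equal(bd$n_input, 20L)
  expect_equal(bd$n_orthologous, 10L)
  expect_equal(bd$n_marked_in_target, 5L)
  expect_equal(bd$n_trackable, 2L)
  expect_equal(unname(bd$states["maternal_specific"]), 1L)
  expect_equal(sum(bd$states), bd$n_trackable)
})

test_that("breakdown counts are monotone along the chain on random inputs", {
  set.seed(29)
  gh <- genome_decl(c(chrH = 1e5))
  gm <- genome_decl(c(chrM = 1e5))
  for (i in 1:10) {
    st <- sort(sample(seq(1, 9e4, by = 400), 30))
    regions <- GenomicRanges::GRanges(
      "chrH", IRanges::IRanges(st, st + 199),
      seqinfo = allelomap:::seqinfo_from_genome(gh))
    keep <- sort(sample(30, 12))
    src <- regions[keep]
    src$pair <- seq_along(src)
    tst <- seq(1001, by = 500, length.out = 12)
    ortho <- orthology_map(src, rep("chrM", 12), tst, tst + 199, gm)
    marks <- ortho$target[sample(12, 6)]
    mask <- ortho$target[sample(12, 5)]
    bd <- orthology_breakdown(regions, ortho, marks, mask,
                              GenomicRanges::GRanges(
                                seqinfo = allelomap:::seqinfo_from_genome(gm)))
    expect_true(bd$n_input >= bd$n_orthologous)
    expect_true(bd$n_orthologous >= bd$n_marked_in_target)
    expect_true(bd$n_marked_in_target >= bd$n_trackable)
    expect_equal(sum(bd$states), bd$n_trackable)
  }
})

test_that("an empty orthology map yields only the input count", {
  f <- make_chain_fixture()
  empty <- orthology_map(f$ortho$source[0], character(), integer(),
                         integer(), f$gm)
  bd <- orthology_breakdown(f$regions, empty, f$marks, f$mask, f$calls)
  expect_equal(bd[c("n_orthologous", "n_marked_in_target", "n_trackable")],
               list(n_orthologous = 0L, n_marked_in_target = 0L,
                    n_trackable = 0L))
})

test_that("identity-style mapping with matched calls gives full concordance", {
  gh <- genome_decl(c(chrH = 1e5))
  st <- seq(1001, by = 1000, length.out = 10)
  regions <- GenomicRanges::GRanges("chrH", IRanges::IRanges(st, st + 499),
                                    seqinfo = allelomap:::seqinfo_from_genome(gh))
  src <- regions
  src$pair <- 1:10
  ortho <- orthology_map(src, rep("chrH", 10), st, st + 499, gh)
  calls <- GenomicRanges::granges(regions)
  calls$state <- "maternal_specific"
  bd <- orthology_breakdown(regions, ortho, regions, regions, calls)
  expect_equal(bd$n_orthologous, 10L)
  expect_equal(bd$n_trackable, 10L)
  expect_equal(unname(bd$states["maternal_specific"]), 10L)
})

test_that("methylation conservation recovers a planted 82/16 style split", {
  gh <- genome_decl(c(chrH = 2e7))
  gm <- genome_decl(c(chrM = 2e7))
  n <- 708
  st <- seq(1001, by = 20000, length.out = n)
  dmrs <- GenomicRanges::GRanges("chrH", IRanges::IRanges(st, st + 999),
                                 seqinfo = allelomap:::seqinfo_from_genome(gh))
  src <- dmrs
  src$pair <- seq_len(n)
  tst <- seq(1001, by = 20000, length.out = n)
  ortho <- orthology_map(src, rep("chrM", n), tst, tst + 999, gm)
  lab <- rep(c("maternal", "bihypo", "other"), c(111, 578, 19))
  tgt <- ortho$target
  mc <- methylation_conservation(dmrs, ortho, tgt[lab == "maternal"],
                                 tgt[lab == "bihypo"])
  expect_equal(mc$n_orthologous, 708L)
  expect_equal(mc$n_maternal_specific, 111L)
  expect_equal(mc$n_biallelic_or_hypo, 578L)
  expect_equal(mc$n_other, 19L)
  expect_equal(mc$n_maternal_specific + mc$n_biallelic_or_hypo + mc$n_other,
               mc$n_orthologous)
  expect_equal(percent_of(differential_fraction(mc$n_biallelic_or_hypo,
                                                mc$n_orthologous)), 82)
  expect_equal(percent_of(differential_fraction(mc$n_maternal_specific,
                                                mc$n_orthologous)), 16)
})

test_that("conservation contrast matches an all-pairs U oracle and is symmetric", {
  set.seed(37)
  a <- rbeta(60, 2, 8)
  b <- rbeta(60, 8, 2)
  gh <- genome_decl(c(chrH = 1e6))
  step <- 100
  track <- GenomicRanges::GRanges(
    "chrH", IRanges::IRanges(seq(1, 1e6, by = step), width = step),
    seqinfo = allelomap:::seqinfo_from_genome(gh))
  track$score <- 0
  # put each region on its own constant-score step
  idx_a <- 1:60; idx_b <- 101:160
  track$score[idx_a] <- a
  track$score[idx_b] <- b
  regions_at <- function(idx) GenomicRanges::GRanges(
    "chrH", IRanges::IRanges((idx - 1) * step + 1, idx * step),
    seqinfo = allelomap:::seqinfo_from_genome(gh))
  res <- conservation_contrast(regions_at(idx_a), regions_at(idx_b), track)
  u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$statistic, u_oracle)
  expect_lt(res$p_value, 1e-10)
  expect_lt(res$median_difference, 0)
  # symmetry under group swap
  res2 <- conservation_contrast(regions_at(idx_b), regions_at(idx_a),
                                track)
  expect_equal(res2$median_difference, -res$median_difference)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-9)
  # identical distributions: p ~ 1, zero median difference
  res3 <- conservation_contrast(regions_at(idx_a), regions_at(idx_a),
                                track)
  expect_equal(res3$median_difference, 0)
  expect_gt(res3$p_value, 0.9)
  expect_error(conservation_contrast(regions_at(1), regions_at(idx_b),
                                     track), "at least 2")
})
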