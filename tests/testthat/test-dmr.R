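test_that("DMR calling applies the delta threshold on defined bins only", {
  bins <- bin_genome(tiny_genome, 1000)
  pos <- seq(1101, 1901, by = 100)  # 9 CpGs in bin [1001, 2000]
  pg <- mk_meth(pos, rep(9, 9), rep(10, 9))
  ag <- mk_meth(pos, rep(1, 9), rep(10, 9))
  d <- call_dmrs(pg, ag, bins, delta_min = 0.5)
  expect_equal(length(d), 1L)
  expect_equal(d$direction, "PG_hyper")
  expect_equal(d$delta, 0.8)
  expect_equal(d$pg_level, 0.9)
  # sub-threshold difference: no call
  ag2 <- mk_meth(pos, rep(4, 9), rep(10, 9))
  pg2 <- mk_meth(pos, rep(6, 9), rep(10, 9))
  expect_equal(length(call_dmrs(pg2, ag2, bins, delta_min = 0.5)), 0L)
  # undefined bins (too few CpGs elsewhere) are skipped, not called
  expect_equal(length(call_dmrs(pg, ag, bins[3:5], delta_min = 0.5)), 0L)
})

test_that("adjacent same-direction DMR bins merge into one region", {
  bins <- bin_genome(tiny_genome, 1000)
  pos <- c(seq(1101, 1901, by = 200), seq(2101, 2901, by = 200))
  pg <- mk_meth(pos, rep(10, 10), rep(10, 10))
  ag <- mk_meth(pos, rep(0, 10), rep(10, 10))
  d <- call_dmrs(pg, ag, bins)
  expect_equal(length(d), 1L)
  expect_equal(GenomicRanges::start(d), 1001L)
  expect_equal(GenomicRanges::end(d), 3000L)
})

test_that("swapping parents flips DMR directions without changing regions", {
  sim <- default_sim()
  bins <- bin_genome(sim$inputs$genome_h, 1000)
  fwd <- call_dmrs(sim$inputs$meth_pg_blast, sim$inputs$meth_ag_blast,
                   bins)
  rev <- call_dmrs(sim$inputs$meth_ag_blast, sim$inputs$meth_pg_blast,
                   bins)
  expect_equal(GenomicRanges::granges(fwd), GenomicRanges::granges(rev))
  flip <- c(PG_hyper = "AG_hyper", AG_hyper = "PG_hyper")
  expect_equal(rev$direction, unname(flip[fwd$direction]))
  expect_equal(rev$pg_level, fwd$ag_level)
})

test_that("planted DMRs are recovered with correct directions", {
  cfg <- sim_config(seed = 23, n_gdmr = 50, gdmr_maternal_frac = 0.8,
                    n_imprinted = 0, n_coordinated = 0)
  sim <- simulate_study(cfg, components = "methylation")
  bins <- bin_genome(sim$inputs$genome_h, 1000)
  called <- call_dmrs(sim$inputs$meth_pg_blast, sim$inputs$meth_ag_blast,
                      bins)
  tr <- sim$truth$dmrs_blastocyst
  expect_equal(sum(tr$direction == "PG_hyper"), 40L)
  expect_equal(sum(tr$direction == "AG_hyper"), 10L)
  for (dir in c("PG_hyper", "AG_hyper")) {
    r <- recovery(called[called$direction == dir], tr[tr$direction == dir])
    expect_gte(r$sensitivity, if (dir == "PG_hyper") 38 / 40 else 9 / 10)
    expect_equal(r$precision, 1)
  }
  # no false directions: a planted region is never called the other way
  wrong <- sum(IRanges::overlapsAny(called[called$direction == "AG_hyper"],
                                    tr[tr$direction == "PG_hyper"]))
  expect_equal(wrong, 0L)
})

test_that("the germline-DMR rule classifies canonical imprinted patterns", {
  # canonical maternally methylated locus: persistent gamete-to-blastocyst
  # asymmetry, intermediate in both somatic tissues
  r <- gdmr_rule(0.95, 0.05, 0.9, 0.1, 0.9, 0.1, 0.48, 0.51)
  expect_true(r$is_gdmr)
  expect_equal(r$hyper_allele, "maternal")
  expect_equal(r$somatic_class, "non_specific")
  expect_true(r$is_pICR)
  # persistence broken at blastocyst
  r2 <- gdmr_rule(0.95, 0.05, 0.9, 0.1, 0.3, 0.1, 0.48, 0.51)
  expect_false(r2$is_gdmr)
  # placenta-specific intermediate methylation
  r3 <- gdmr_rule(0.95, 0.05, 0.9, 0.1, 0.9, 0.1, 0.50, 0.02)
  expect_equal(r3$somatic_class, "placenta_specific")
  # missing level flags the record rather than passing it
  r4 <- gdmr_rule(NA, 0.05, 0.9, 0.1, 0.9, 0.1, 0.5, 0.5)
  expect_true(is.na(r4$is_gdmr))
})

test_that("the vectorised rule agrees with a scalar oracle on a level grid", {
  # independent scalar re-statement of the decision rule
  oracle <- function(mg, pg, mm, pm, mb, pb, pl, em) {
    mat_h <- mg >= 0.75 && pg <= 0.25 && mm >= 0.75 && pm <= 0.25 &&
      mb >= 0.75 && pb <= 0.25
    pat_h <- pg >= 0.75 && mg <= 0.25 && pm >= 0.75 && mm <= 0.25 &&
      pb >= 0.75 && mb <= 0.25
    g <- mat_h || pat_h
    p_in <- pl >= 0.30 && pl <= 0.70
    e_in <- em >= 0.30 && em <= 0.70
    soma <- if (p_in && e_in) "non_specific" else if (p_in)
      "placenta_specific" else if (e_in) "embryo_specific" else "none"
    c(g, g && soma != "none")
  }
  lv <- seq(0, 1, by = 0.2)
  grid <- expand.grid(mat = lv, pat = lv, pl = lv, em = lv)
  got <- gdmr_rule(grid$mat, grid$pat, grid$mat, grid$pat, grid$mat,
                   grid$pat, grid$pl, grid$em)
  want <- t(mapply(function(m, p, pl, em) oracle(m, p, m, p, m, p, pl, em),
                   grid$mat, grid$pat, grid$pl, grid$em))
  expect_equal(got$is_gdmr, unname(want[, 1]))
  expect_equal(unname(got$is_pICR), unname(want[, 2]))
})

test_that("tightening thresholds never increases the gDMR count", {
  set.seed(31)
  n <- 500
  args <- replicate(8, runif(n), simplify = FALSE)
  count <- function(hyper_min, hypo_max)
    sum(do.call(gdmr_rule, c(args, list(hyper_min = hyper_min,
                                        hypo_max = hypo_max)))$is_gdmr)
  base <- count(0.75, 0.25)
  expect_lte(count(0.80, 0.25), base)
  expect_lte(count(0.75, 0.20), base)
  expect_lte(count(0.90, 0.10), count(0.80, 0.20))
})

test_that("classified gDMRs match the planted truth on the default simulation", {
  sim <- default_sim()
  i <- sim$inputs
  bins <- bin_genome(i$genome_h, 1000)
  dmrs <- call_dmrs(i$meth_pg_blast, i$meth_ag_blast, bins)
  gd <- classify_gdmr(dmrs, list(
    oocyte = i$meth_oocyte, sperm = i$meth_sperm,
    pg_morula = i$meth_pg_morula, ag_morula = i$meth_ag_morula,
    pg_blast = i$meth_pg_blast, ag_blast = i$meth_ag_blast,
    placenta = i$meth_placenta, embryo6w = i$meth_embryo6w))
  called_g <- gd[!is.na(gd$is_gdmr) & gd$is_gdmr]
  r <- recovery(called_g, sim$truth$gdmrs)
  expect_gte(r$sensitivity, 0.9)
  expect_gte(r$precision, 0.9)
  # pICRs are a subset of gDMRs, with matching somatic classes at planted loci
  picr <- called_g[called_g$is_pICR]
  expect_true(all(IRanges::overlapsAny(picr, called_g)))
  hit <- GenomicRanges::findOverlaps(picr, sim$truth$gdmrs)
  expect_equal(picr$somatic_class[S4Vectors::queryHits(hit)],
               sim$truth$gdmrs$somatic_class[S4Vectors::subjectHits(hit)])
})

test_that("gDMR/known-DMR overlap partition matches an all-pairs oracle", {
  set.seed(41)
  st <- sample.int(9000, 30)
  gd <- gr_("chr1", st, st + 199)
  st2 <- sample.int(9000, 15)
  known <- gr_("chr1", st2, st2 + 299)
  res <- gdmr_overlap_known(gd, known)
  # quadratic oracle
  ov <- vapply(seq_along(gd), function(i) {
    any(st[i] <= st2 + 299 & st[i] + 199 >= st2)
  }, logical(1))
  expect_equal(res$n_overlapping, sum(ov))
  expect_equal(res$n_novel, sum(!ov))
  expect_equal(length(res$overlapping) + length(res$novel), 30L)
})

test_that("replicate methylomes pool by count summation", {
  a <- mk_meth(c(100, 200), c(2, 3), c(5, 5), sample_id = "r1",
               stage = "morula", parentage = "PG")
  b <- mk_meth(c(100, 300), c(1, 4), c(4, 6), sample_id = "r2",
               stage = "morula", parentage = "PG")
  p <- pool_methylomes(list(a, b), tiny_genome)
  expect_equal(GenomicRanges::start(p$cpgs), c(100L, 200L, 300L))
  expect_equal(p$cpgs$methylated, c(3L, 3L, 4L))
  expect_equal(p$cpgs$total, c(9L, 5L, 6L))
})
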