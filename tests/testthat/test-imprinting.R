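test_that("allelic expression states follow the threshold and ratio rule", {
  et <- expression_table(
    c("ag", "silent", "bi", "pg", "edge"),
    c("AG_R1", "AG_R2", "PG_R1", "PG_R2"),
    rbind(c(5, 5, 0, 0),        # AG-specific
          c(0.5, 0.5, 0.5, 0.5),  # both below 1: silent
          c(3, 3, 3, 3),          # ratio 1: bi-allelic
          c(0, 0, 8, 8),          # PG-specific
          c(1, 1, 0.15, 0.15)))   # ratio 1/(0.15+0.1) = 4: boundary
  calls <- call_allelic_expression(et)
  expect_equal(calls$state,
               c("AG_specific", "silent", "biallelic", "PG_specific",
                 "AG_specific"))
  expect_equal(calls$ag_rpkm[1], 5)
  expect_error(call_allelic_expression(
    expression_table("g", "AG_R1", matrix(1))), "per parent")
})

test_that("planted allele-specific expression is recovered from noisy replicates", {
  set.seed(13)
  n <- 1000
  planted <- seq_len(n) %% 20 == 0  # 5% AG-specific at 20-fold
  ag_mu <- ifelse(planted, 10, 5)
  pg_mu <- ifelse(planted, 0.5, 5)
  draw <- function(mu) matrix(rlnorm(2 * n, log(mu), 0.3), n, 2)
  et <- expression_table(sprintf("g%04d", 1:n),
                         c("AG_R1", "AG_R2", "PG_R1", "PG_R2"),
                         cbind(draw(ag_mu), draw(pg_mu)))
  calls <- call_allelic_expression(et)
  got <- calls$state == "AG_specific"
  expect_gte(sum(got & planted) / sum(planted), 0.95)   # recall
  expect_gte(sum(got & planted) / max(sum(got), 1), 0.95)  # precision
})

test_that("pICR linkage picks the nearest control region with the stated tie-break", {
  genes <- gene_table("g1", "chr1", "+", 4001, 6000, genome = tiny_genome)
  # inside the promoter window: distance 0
  p0 <- gr_("chr1", 3600, 3800)
  expect_equal(link_picr(genes, p0, genome = tiny_genome)$picr_distance, 0)
  # beyond max_distance: unlinked
  far <- gr_("chr1", 9800, 9900)
  expect_true(is.na(link_picr(genes, far, max_distance = 1000,
                              genome = tiny_genome)$picr))
  # 20 random candidates vs a brute-force argmin with tie-break
  set.seed(19)
  st <- sample.int(9500, 20)
  picrs <- gr_("chr1", st, st + 100)
  got <- link_picr(genes, picrs, max_distance = 1e5, flank = 2000,
                   genome = tiny_genome)
  span <- c(4001 - 2000, 6000)  # promoter start to gene end
  d <- pmax(0, pmax(span[1] - (st + 100), st - span[2]))
  best <- which(d == min(d))
  best <- best[which.min(st[best])]
  expect_equal(got$picr, best)
  expect_equal(got$picr_distance, min(d))
})

test_that("imprinted calls integrate expression, linkage and the catalogue", {
  genes <- gene_table(c("gA", "gB", "gC"), rep("chr1", 3), rep("+", 3),
                      c(1001, 4001, 7001), c(2000, 5000, 8000),
                      genome = tiny_genome)
  picrs <- gr_("chr1", c(900, 3900), c(1100, 4100))
  picrs$hyper_allele <- c("maternal", "maternal")
  et <- expression_table(c("gA", "gB", "gC"),
                         c("AG_R1", "PG_R1"),
                         rbind(c(6, 0.1), c(7, 0.2), c(4, 4)))
  expr_calls <- call_allelic_expression(et)
  links <- link_picr(genes, picrs, genome = tiny_genome,
                     max_distance = 500)
  res <- call_imprinted(expr_calls, links, picrs, catalogue = c("gA", "gC"))
  expect_equal(res$imprinted$gene_id, c("gA", "gB"))
  expect_equal(res$imprinted$status, c("known", "novel"))
  expect_equal(res$imprinted$expressed_allele, c("paternal", "paternal"))
  expect_false(any(res$imprinted$discordant))  # maternal pICR, paternal expr
  expect_equal(res$not_allelic, "gC")
  # discordant flag: expressed allele equals the hypermethylated allele
  picrs$hyper_allele <- c("paternal", "maternal")
  res2 <- call_imprinted(expr_calls, links, picrs, catalogue = "gA")
  expect_true(res2$imprinted$discordant[1])
})

test_that("imprinted set algebra holds and survives a parental swap", {
  sim <- default_sim()
  rep <- default_report()
  imp <- rep$tables$imprinted$imprinted
  ec <- rep$tables$expr_calls
  allelic_ids <- ec$gene_id[ec$state %in% c("AG_specific", "PG_specific")]
  expect_true(all(imp$gene_id %in% allelic_ids))
  expect_equal(sum(imp$status == "known") + sum(imp$status == "novel"),
               nrow(imp))
  # recovery against the planted truth
  tr <- sim$truth$imprinted
  expect_gte(mean(tr$gene_id %in% imp$gene_id), 0.9)
  expect_gte(mean(imp$gene_id %in% tr$gene_id), 0.9)
  expect_equal(imp$expressed_allele[match(tr$gene_id, imp$gene_id)],
               tr$expressed_allele)
  # swap parents: relabel replicate columns and rerun
  et <- sim$inputs$expression
  swapped_ids <- sub("^AG", "XX", colnames(et$values))
  swapped_ids <- sub("^PG", "AG", swapped_ids)
  swapped_ids <- sub("^XX", "PG", swapped_ids)
  et2 <- expression_table(et$genes, swapped_ids, et$values)
  ec2 <- call_allelic_expression(et2)
  links <- link_picr(sim$inputs$genes, rep$tables$picrs,
                     genome = sim$inputs$genome_h)
  imp2 <- call_imprinted(ec2, links, rep$tables$picrs,
                         sim$inputs$imprint_catalogue)$imprinted
  expect_setequal(imp2$gene_id, imp$gene_id)
  flip <- c(paternal = "maternal", maternal = "paternal")
  expect_equal(imp2$expressed_allele[match(imp$gene_id, imp2$gene_id)],
               unname(flip[imp$expressed_allele]))
})
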