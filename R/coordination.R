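#' Screen for promoters repressed by maternal methylation plus paternal
#' H3K27me3
#'
#' Finds genes whose promoter overlaps BOTH an AG-specific (paternal)
#' H3K27me3 region and a PG-hyper (maternal) DMR — the coordinated
#' dual-allele repression configuration — and summarises their expression,
#' catalogue membership and sperm promoter methylation.
#'
#' @param genes a [gene_table()].
#' @param k27_calls allelic H3K27me3 calls from [call_allelic_regions()].
#' @param dmrs DMRs from [call_dmrs()] (blastocyst stage).
#' @param expr_calls output of [call_allelic_expression()] (optional rows
#'   may be missing for some hit genes; those are excluded from the
#'   expression summary only, and flagged).
#' @param imprint_catalogue known imprinted gene ids.
#' @param known_dmrs `GRanges` of reported allelic DMRs.
#' @param sperm optional sperm [methylome()] for promoter ML classes.
#' @param flank promoter half-width (default 2000).
#' @param low_rpkm "low expression" cutoff on both parental means (default
#'   1).
#' @param genome a [genome_decl()].
#' @return list(records = per-gene data.frame, summary = list of counts and
#'   fractions).
#' @export
screen_coordinated <- function(genes, k27_calls, dmrs, expr_calls,
                               imprint_catalogue = character(),
                               known_dmrs = NULL, sperm = NULL,
                               flank = 2000, low_rpkm = 1, genome) {
  prom <- promoter_windows(genes, flank, genome)
  ag_k27 <- IRanges::overlapsAny(
    prom, k27_calls[k27_calls$state == "AG_specific"])
  pg_meth <- IRanges::overlapsAny(
    prom, dmrs[dmrs$direction == "PG_hyper"])
  hit <- ag_k27 & pg_meth
  rec <- data.frame(gene_id = genes$gene_id[hit],
                    chrom = genes$chrom[hit],
                    prom_start = GenomicRanges::start(prom)[hit],
                    prom_end = GenomicRanges::end(prom)[hit],
                    row.names = NULL)
  ei <- match(rec$gene_id, expr_calls$gene_id)
  rec$pg_rpkm <- expr_calls$pg_rpkm[ei]
  rec$ag_rpkm <- expr_calls$ag_rpkm[ei]
  rec$expression_missing <- is.na(ei)
  rec$in_imprint_catalogue <- rec$gene_id %in% imprint_catalogue
  rec$in_known_dmr_list <- if (is.null(known_dmrs)) rep(NA, nrow(rec)) else
    IRanges::overlapsAny(prom[hit], known_dmrs)
  if (!is.null(sperm)) {
    ml <- region_methylation(sperm, prom[hit])$level
    rec$sperm_promoter_ml <- ml
    rec$sperm_class <- ifelse(is.na(ml), NA_character_,
                              ifelse(ml <= 0.25, "low",
                                     ifelse(ml >= 0.75, "high", "mid")))
  }
  has_expr <- !rec$expression_missing
  low <- has_expr & rec$pg_rpkm < low_rpkm & rec$ag_rpkm < low_rpkm
  summary <- list(
    n_genes = nrow(rec),
    n_with_expression = sum(has_expr),
    frac_low_expressed = if (any(has_expr)) sum(low) / sum(has_expr)
                         else NA_real_,
    n_in_imprint_catalogue = sum(rec$in_imprint_catalogue),
    n_in_known_dmr_list = if (is.null(known_dmrs)) NA_integer_ else
      sum(rec$in_known_dmr_list),
    sperm_class_counts = if (!is.null(sperm))
      table(factor(rec$sperm_class, c("low", "mid", "high"))) else NULL)
  list(records = rec, summary = summary)
}
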