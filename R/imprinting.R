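#' Call allele-specific expression from PG/AG replicate RPKM
#'
#' Replicate means are computed per parent. A gene is silent when both
#' means are below `expressed_min`; AG-specific when the AG mean is
#' expressed and exceeds `ratio_min` times the PG mean (with a pseudocount
#' floor); symmetrically for PG; otherwise bi-allelic.
#'
#' @param expr an [expression_table()] with AG and PG samples.
#' @param expressed_min RPKM expression floor (default 1).
#' @param ratio_min minimum parental fold (default 4).
#' @param pseudocount added floor on the comparison mean (default 0.1).
#' @return data.frame: gene_id, pg_rpkm, ag_rpkm, state.
#' @export
call_allelic_expression <- function(expr, expressed_min = 1, ratio_min = 4,
                                    pseudocount = 0.1) {
  stopifnot(inherits(expr, "expression_table"))
  pgc <- expr$samples$parentage == "PG"
  agc <- expr$samples$parentage == "AG"
  if (!any(pgc) || !any(agc))
    stop("expression table needs at least one replicate per parent")
  pg <- rowMeans(expr$values[, pgc, drop = FALSE])
  ag <- rowMeans(expr$values[, agc, drop = FALSE])
  state <- rep("biallelic", length(pg))
  state[pg < expressed_min & ag < expressed_min] <- "silent"
  state[ag >= expressed_min & ag / (pg + pseudocount) >= ratio_min] <-
    "AG_specific"
  state[pg >= expressed_min & pg / (ag + pseudocount) >= ratio_min] <-
    "PG_specific"
  data.frame(gene_id = expr$genes, pg_rpkm = pg, ag_rpkm = ag,
             state = state, row.names = NULL)
}

#' Link a gene to its nearest putative germline ICR
#'
#' Distance is 0 when a pICR overlaps the gene body or its promoter window,
#' otherwise the gap between nearest edges. The nearest qualifying pICR
#' within `max_distance` wins; ties are broken by the smaller pICR start.
#'
#' @param genes a [gene_table()].
#' @param picrs `GRanges` of pICRs.
#' @param max_distance linkage cutoff in bp (default 1e5).
#' @param flank promoter half-width used for the overlap test (default
#'   2000).
#' @param genome a [genome_decl()].
#' @return data.frame per gene: gene_id, picr (index into `picrs`, NA when
#'   unlinked), picr_distance.
#' @export
link_picr <- function(genes, picrs, max_distance = 1e5, flank = 2000,
                      genome) {
  n <- nrow(genes)
  idx <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  if (length(picrs) > 0 && n > 0) {
    span_start <- pmin(genes$start, pmax(1L, genes$tss - as.integer(flank)))
    span_end <- pmax(genes$end,
                     pmin(genome[genes$chrom],
                          genes$tss + as.integer(flank) - 1L))
    ps <- GenomicRanges::start(picrs)
    pe <- GenomicRanges::end(picrs)
    pc <- as.character(GenomeInfoDb::seqnames(picrs))
    for (i in seq_len(n)) {
      same <- pc == genes$chrom[i]
      if (!any(same)) next
      # gap distance; 0 when the pICR overlaps gene body or promoter
      d <- pmax(0, pmax(span_start[i] - pe, ps - span_end[i]))
      d[!same] <- Inf
      d_ok <- d <= max_distance
      if (!any(d_ok)) next
      best <- which(d_ok)[order(d[d_ok], ps[d_ok])][1]
      idx[i] <- best
      dist[i] <- d[best]
    }
  }
  data.frame(gene_id = genes$gene_id, picr = idx, picr_distance = dist,
             row.names = NULL)
}

#' Call imprinted genes by integrating allelic expression with pICRs
#'
#' A gene is called imprinted when its expression is parent-specific AND it
#' links to a pICR. `status` is "known" for genes in the supplied imprinted
#' catalogue, else "novel". Links whose pICR is hypermethylated on the
#' EXPRESSED side are kept but flagged discordant rather than dropped.
#' Catalogue genes that are expressed but bi-allelic are reported
#' separately (evidence against imprinting at this stage), as are silent
#' catalogue genes (no evidence either way).
#'
#' @param expr_calls output of [call_allelic_expression()].
#' @param links output of [link_picr()] for the same genes.
#' @param picrs the `GRanges` the link indices refer to (needs
#'   `hyper_allele`).
#' @param catalogue character vector of known imprinted gene ids.
#' @return list(imprinted = data.frame(gene_id, expressed_allele,
#'   picr, picr_distance, status, discordant), not_allelic = catalogue genes
#'   expressed without allele specificity, silent = silent catalogue genes).
#' @export
call_imprinted <- function(expr_calls, links, picrs, catalogue) {
  stopifnot(identical(expr_calls$gene_id, links$gene_id))
  allelic <- expr_calls$state %in% c("AG_specific", "PG_specific")
  linked <- !is.na(links$picr)
  hit <- allelic & linked
  expressed_allele <- ifelse(expr_calls$state == "AG_specific", "paternal",
                             "maternal")
  hyper <- picrs$hyper_allele[links$picr[hit]]
  imprinted <- data.frame(
    gene_id = expr_calls$gene_id[hit],
    expressed_allele = expressed_allele[hit],
    picr = links$picr[hit],
    picr_distance = links$picr_distance[hit],
    status = ifelse(expr_calls$gene_id[hit] %in% catalogue, "known",
                    "novel"),
    discordant = !is.na(hyper) & hyper == expressed_allele[hit],
    row.names = NULL)
  in_cat <- expr_calls$gene_id %in% catalogue
  list(imprinted = imprinted,
       not_allelic = expr_calls$gene_id[in_cat &
                                          expr_calls$state == "biallelic"],
       silent = expr_calls$gene_id[in_cat & expr_calls$state == "silent"])
}
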