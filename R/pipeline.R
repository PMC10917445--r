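#' Default pipeline thresholds
#'
#' One place for every tunable of the analysis: bin sizes, level-definition
#' cutoffs, the allelic fold gate, the germline-DMR rule thresholds and the
#' expression rule. Values are documented with the functions that consume
#' them.
#'
#' @return named list of parameters.
#' @export
pipeline_params <- function() {
  list(bin_size_signal = 2000, bin_size_meth = 1000, min_cpgs = 3,
       min_depth = 3, fold_min = 4, pseudocount = 0.5, k27_merge_gap = 3000,
       delta_min = 0.5, hyper_min = 0.75, hypo_max = 0.25, inter_lo = 0.30,
       inter_hi = 0.70, expressed_min = 1, ratio_min = 4,
       expr_pseudocount = 0.1, promoter_flank = 2000, link_max_distance = 1e5)
}

#' Run the full allelic-epigenome pipeline and assemble the report
#'
#' Executes every stage the supplied inputs allow: allelic DHS and
#' H3K27me3 calling with differential-fraction accounting, the four-group
#' genome partition, blastocyst DMR calling, germline-DMR / pICR
#' classification against gametes, morula and somatic tissues, imprinted
#' gene calling, the coordinated maternal-methylation / paternal-H3K27me3
#' promoter screen, and the cross-species orthology breakdowns. Stages
#' whose inputs are absent are marked "skipped" in the report. Every
#' fraction in the report is stored as its (m, n) count pair plus the
#' rendered percentage.
#'
#' @param inputs named list as produced by [simulate_study()]`$inputs` (or
#'   assembled from the readers in this package).
#' @param params list from [pipeline_params()]; individual entries may be
#'   overridden.
#' @return list of class `allelomap_report`; component `tables` carries the
#'   intermediate objects every reported number is recomputable from.
#' @export
run_pipeline <- function(inputs, params = pipeline_params()) {
  p <- utils::modifyList(pipeline_params(), params)
  gh <- inputs$genome_h
  rep_frac <- function(m, n) {
    f <- differential_fraction(m, n)
    list(m = f$m, n = f$n, fraction = f$fraction,
         percent = percent_of(f))
  }
  report <- list(params = p)
  tables <- list()

  has <- function(...) all(c(...) %in% names(inputs))

  ## allelic calls per assay
  for (assay in c("dhs", "k27")) {
    pk_pg <- paste0(assay, "_peaks_pg"); pk_ag <- paste0(assay, "_peaks_ag")
    sg_pg <- paste0("sig_", assay, "_pg"); sg_ag <- paste0("sig_", assay,
                                                           "_ag")
    if (!has(pk_pg, pk_ag, sg_pg, sg_ag)) {
      report[[paste0("allelic_", assay)]] <- "skipped"
      next
    }
    calls <- call_allelic_regions(
      inputs[[pk_pg]], inputs[[pk_ag]], inputs[[sg_pg]], inputs[[sg_ag]],
      assay = if (assay == "dhs") "DHS" else "H3K27me3",
      fold_min = p$fold_min, pseudocount = p$pseudocount,
      merge_gap = p$k27_merge_gap)
    tables[[paste0("calls_", assay)]] <- calls
    n_ag <- sum(calls$state == "AG_specific")
    n_pg <- sum(calls$state == "PG_specific")
    report[[paste0("allelic_", assay)]] <- list(
      n_regions = length(calls), n_ag_specific = n_ag,
      n_pg_specific = n_pg,
      n_biallelic = sum(calls$state == "biallelic"),
      differential_fraction = rep_frac(n_ag + n_pg, length(calls)),
      ag_share_of_specific = if (n_ag + n_pg > 0)
        rep_frac(n_ag, n_ag + n_pg) else "undefined")
  }

  ## four-group genome partition
  if (has("dhs_peaks_pg", "dhs_peaks_ag", "k27_peaks_pg", "k27_peaks_ag")) {
    bins <- bin_genome(gh, p$bin_size_signal)
    part <- partition_groups(
      list(inputs$dhs_peaks_pg, inputs$dhs_peaks_ag),
      list(inputs$k27_peaks_pg, inputs$k27_peaks_ag), bins)
    tables$partition <- part
    report$partition <- as.list(table(part$group))
  } else report$partition <- "skipped"

  ## intergenic allelic DHS annotation
  if (!is.null(tables$calls_dhs) && has("genes", "k27ac_peaks")) {
    calls <- tables$calls_dhs
    loc <- classify_location(calls, inputs$genes, p$promoter_flank, gh)
    tables$dhs_location <- loc
    inter <- calls[loc == "intergenic" & calls$state != "biallelic"]
    # region RPKM lookup: a GRanges with an `rpkm` column; unscored -> 0
    rpkm <- rep(0, length(inter))
    if (!is.null(inputs$intergenic_dhs_rpkm)) {
      hits <- GenomicRanges::findOverlaps(inter, inputs$intergenic_dhs_rpkm)
      rpkm[S4Vectors::queryHits(hits)] <-
        inputs$intergenic_dhs_rpkm$rpkm[S4Vectors::subjectHits(hits)]
    }
    report$intergenic_dhs <- intergenic_dhs_annotation(
      inter, rpkm, inputs$k27ac_peaks)
  } else report$intergenic_dhs <- "skipped"

  ## methylation: DMRs, gDMRs, pICRs
  meth_ok <- has("meth_pg_blast", "meth_ag_blast")
  if (meth_ok) {
    mbins <- bin_genome(gh, p$bin_size_meth)
    dmrs <- call_dmrs(inputs$meth_pg_blast, inputs$meth_ag_blast, mbins,
                      p$delta_min, p$min_cpgs, p$min_depth)
    tables$dmrs <- dmrs
    report$dmrs <- list(n = length(dmrs),
                        n_pg_hyper = sum(dmrs$direction == "PG_hyper"),
                        n_ag_hyper = sum(dmrs$direction == "AG_hyper"))
  } else report$dmrs <- "skipped"

  gdmr_ok <- meth_ok && has("meth_oocyte", "meth_sperm", "meth_pg_morula",
                            "meth_ag_morula", "meth_placenta",
                            "meth_embryo6w")
  if (gdmr_ok && length(tables$dmrs)) {
    gd <- classify_gdmr(tables$dmrs,
                        list(oocyte = inputs$meth_oocyte,
                             sperm = inputs$meth_sperm,
                             pg_morula = inputs$meth_pg_morula,
                             ag_morula = inputs$meth_ag_morula,
                             pg_blast = inputs$meth_pg_blast,
                             ag_blast = inputs$meth_ag_blast,
                             placenta = inputs$meth_placenta,
                             embryo6w = inputs$meth_embryo6w),
                        p$hyper_min, p$hypo_max, p$inter_lo, p$inter_hi,
                        p$min_cpgs, p$min_depth)
    tables$gdmr_classified <- gd
    gdmrs <- gd[!is.na(gd$is_gdmr) & gd$is_gdmr]
    picrs <- gdmrs[gdmrs$is_pICR]
    tables$gdmrs <- gdmrs
    tables$picrs <- picrs
    report$gdmrs <- list(
      n_gdmr = length(gdmrs), n_picr = length(picrs),
      n_maternal = sum(gdmrs$hyper_allele == "maternal"),
      n_paternal = sum(gdmrs$hyper_allele == "paternal"),
      somatic_classes = as.list(table(picrs$somatic_class)))
    if (has("known_dmrs")) {
      ov <- gdmr_overlap_known(picrs, inputs$known_dmrs)
      report$gdmrs$n_picr_known <- ov$n_overlapping
      report$gdmrs$n_picr_novel <- ov$n_novel
    }
  } else report$gdmrs <- if (gdmr_ok) list(n_gdmr = 0, n_picr = 0)
         else "skipped"

  ## imprinted genes
  if (has("expression", "genes") && !is.null(tables$picrs)) {
    expr_calls <- call_allelic_expression(inputs$expression,
                                          p$expressed_min, p$ratio_min,
                                          p$expr_pseudocount)
    tables$expr_calls <- expr_calls
    links <- link_picr(inputs$genes, tables$picrs, p$link_max_distance,
                       p$promoter_flank, gh)
    catalogue <- if (has("imprint_catalogue")) inputs$imprint_catalogue
                 else character()
    imp <- call_imprinted(expr_calls, links, tables$picrs, catalogue)
    tables$imprinted <- imp
    report$imprinted <- list(
      n = nrow(imp$imprinted),
      n_known = sum(imp$imprinted$status == "known"),
      n_novel = sum(imp$imprinted$status == "novel"),
      n_paternal_expressed = sum(imp$imprinted$expressed_allele ==
                                   "paternal"),
      n_maternal_expressed = sum(imp$imprinted$expressed_allele ==
                                   "maternal"),
      n_catalogue_not_allelic = length(imp$not_allelic),
      n_catalogue_silent = length(imp$silent))
  } else report$imprinted <- "skipped"

  ## coordinated repression screen
  if (!is.null(tables$calls_k27) && !is.null(tables$dmrs) &&
      !is.null(tables$expr_calls) && has("genes")) {
    scr <- screen_coordinated(inputs$genes, tables$calls_k27, tables$dmrs,
                              tables$expr_calls,
                              imprint_catalogue =
                                if (has("imprint_catalogue"))
                                  inputs$imprint_catalogue else character(),
                              known_dmrs = if (has("known_dmrs"))
                                inputs$known_dmrs else NULL,
                              sperm = if (has("meth_sperm"))
                                inputs$meth_sperm else NULL,
                              flank = p$promoter_flank,
                              low_rpkm = p$expressed_min, genome = gh)
    tables$coordinated <- scr
    report$coordinated <- scr$summary
    report$coordinated$sperm_class_counts <-
      as.list(scr$summary$sperm_class_counts)
  } else report$coordinated <- "skipped"

  ## cross-species breakdowns
  if (has("ortho", "target_marks", "trackable_mask", "target_calls") &&
      !is.null(tables$calls_dhs)) {
    bd <- lapply(c(AG_specific = "AG_specific", PG_specific = "PG_specific"),
                 function(st) orthology_breakdown(
                   tables$calls_dhs[tables$calls_dhs$state == st],
                   inputs$ortho, inputs$target_marks, inputs$trackable_mask,
                   inputs$target_calls))
    report$orthology_dhs <- lapply(bd, function(b)
      c(b[c("n_input", "n_orthologous", "n_marked_in_target",
            "n_trackable")], list(states = as.list(b$states))))
    tables$orthology_dhs <- bd
  } else report$orthology_dhs <- "skipped"
  if (has("ortho", "target_maternal", "target_bihypo") &&
      !is.null(tables$dmrs)) {
    mc <- methylation_conservation(
      tables$dmrs[tables$dmrs$direction == "PG_hyper"], inputs$ortho,
      inputs$target_maternal, inputs$target_bihypo)
    report$meth_conservation <- mc
    tables$meth_conservation <- mc
  } else report$meth_conservation <- "skipped"

  report$tables <- tables
  class(report) <- "allelomap_report"
  report
}

#' @export
print.allelomap_report <- function(x, ...) {
  cat("allelomap pipeline report\n")
  for (sec in setdiff(names(x), c("params", "tables"))) {
    v <- x[[sec]]
    if (identical(v, "skipped")) { cat(" ", sec, ": skipped\n"); next }
    cat(" ", sec, ":\n")
    flat <- unlist(v)
    for (nm in names(flat))
      cat("    ", nm, "=", format(flat[[nm]], digits = 4), "\n")
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Percentages are stored as exact (m, n) pairs alongside the rendered
#' value, so every printed-style figure is recomputable.
#'
#' @param report an `allelomap_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  out <- report[setdiff(names(report), "tables")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
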