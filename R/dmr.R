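#' Call differentially methylated regions between PG and AG methylomes
#'
#' Bin-level methylation levels are computed for both parents; bins where
#' both levels are defined and differ by at least `delta_min` are DMR bins,
#' and touching DMR bins with the same direction are merged into one region.
#' Levels and delta reported per merged region are recomputed over the whole
#' region. Bins with an undefined level on either side are skipped, never
#' called.
#'
#' @param pg,ag [methylome()]s at the same stage (maternal / paternal side).
#' @param bins `GRanges` from [bin_genome()] (1 kb default elsewhere).
#' @param delta_min minimum |PG - AG| level difference (default 0.5).
#' @param min_cpgs,min_depth level-definition cutoffs (defaults 3 / 3).
#' @return `GRanges` of DMRs with metadata `pg_level`, `ag_level`,
#'   `direction` (PG_hyper / AG_hyper), `delta`.
#' @export
call_dmrs <- function(pg, ag, bins, delta_min = 0.5, min_cpgs = 3,
                      min_depth = 3) {
  lp <- region_methylation(pg, bins, min_cpgs, min_depth)$level
  la <- region_methylation(ag, bins, min_cpgs, min_depth)$level
  ok <- !is.na(lp) & !is.na(la) & abs(lp - la) >= delta_min
  dirn <- ifelse(lp > la, "PG_hyper", "AG_hyper")
  out <- lapply(c("PG_hyper", "AG_hyper"), function(d) {
    sel <- bins[ok & dirn == d]
    if (length(sel) == 0) return(sel)
    merged <- GenomicRanges::reduce(sel)
    merged$direction <- d
    merged
  })
  dmrs <- GenomicRanges::sort(do.call(c, out))
  if (length(dmrs)) {
    dmrs$pg_level <- region_methylation(pg, dmrs, min_cpgs, min_depth)$level
    dmrs$ag_level <- region_methylation(ag, dmrs, min_cpgs, min_depth)$level
    dmrs$delta <- abs(dmrs$pg_level - dmrs$ag_level)
  } else {
    dmrs$direction <- character()
    dmrs$pg_level <- dmrs$ag_level <- dmrs$delta <- numeric()
  }
  dmrs
}

#' Core germline-DMR / pICR decision rule on methylation levels
#'
#' Vectorised rule evaluation shared by [classify_gdmr()]. A region is a
#' germline DMR (gDMR) when one parental allele is hypermethylated
#' (level >= `hyper_min`) and the other hypomethylated (level <= `hypo_max`)
#' with the same hyper allele at ALL of the gamete, morula and blastocyst
#' stages. Its somatic class records which bi-parental somatic tissues keep
#' the intermediate methylation expected of an imprinting control region:
#' both placenta and six-week embryo in `[inter_lo, inter_hi]` ->
#' non_specific; only placenta -> placenta_specific; only embryo ->
#' embryo_specific; neither -> none. A putative germline ICR (pICR) is a
#' gDMR whose somatic class is not "none". Any NA level makes the
#' classification NA (flagged, not silently passed).
#'
#' @param mat_gamete,pat_gamete oocyte / sperm levels.
#' @param mat_morula,pat_morula,mat_blast,pat_blast PG / AG embryo levels.
#' @param placenta,embryo6w somatic levels.
#' @param hyper_min,hypo_max,inter_lo,inter_hi rule thresholds.
#' @return data.frame: is_gdmr, hyper_allele (maternal/paternal/NA),
#'   somatic_class, is_pICR.
#' @export
gdmr_rule <- function(mat_gamete, pat_gamete, mat_morula, pat_morula,
                      mat_blast, pat_blast, placenta, embryo6w,
                      hyper_min = 0.75, hypo_max = 0.25,
                      inter_lo = 0.30, inter_hi = 0.70) {
  mat <- cbind(mat_gamete, mat_morula, mat_blast)
  pat <- cbind(pat_gamete, pat_morula, pat_blast)
  mat_hyper <- rowSums(mat >= hyper_min & pat <= hypo_max) == 3L
  pat_hyper <- rowSums(pat >= hyper_min & mat <= hypo_max) == 3L
  is_gdmr <- mat_hyper | pat_hyper
  hyper_allele <- ifelse(mat_hyper, "maternal",
                         ifelse(pat_hyper, "paternal", NA_character_))
  p_in <- placenta >= inter_lo & placenta <= inter_hi
  e_in <- embryo6w >= inter_lo & embryo6w <= inter_hi
  somatic <- ifelse(p_in & e_in, "non_specific",
                    ifelse(p_in, "placenta_specific",
                           ifelse(e_in, "embryo_specific", "none")))
  any_na <- is.na(rowSums(mat) + rowSums(pat) + placenta + embryo6w)
  is_gdmr[any_na] <- NA
  hyper_allele[any_na] <- NA_character_
  somatic[any_na] <- NA_character_
  data.frame(is_gdmr = is_gdmr, hyper_allele = hyper_allele,
             somatic_class = somatic,
             is_pICR = is_gdmr & somatic != "none")
}

#' Classify candidate regions as germline DMRs / putative germline ICRs
#'
#' Applies [gdmr_rule()] to methylation levels measured on the SAME
#' intervals at every stage: gametes (oocyte = maternal side, sperm =
#' paternal side), PG/AG morula, PG/AG blastocyst, and the two bi-parental
#' somatic tissues. No per-stage re-segmentation is done — gDMR identity is
#' positional.
#'
#' @param regions candidate `GRanges` (typically blastocyst DMRs).
#' @param stage_meth named list of methylomes: `oocyte`, `sperm`,
#'   `pg_morula`, `ag_morula`, `pg_blast`, `ag_blast`, `placenta`,
#'   `embryo6w`.
#' @param hyper_min,hypo_max,inter_lo,inter_hi rule thresholds (defaults
#'   0.75 / 0.25 / 0.30 / 0.70).
#' @param min_cpgs,min_depth level-definition cutoffs.
#' @return `regions` with the [gdmr_rule()] columns plus the eight per-stage
#'   levels as metadata.
#' @export
classify_gdmr <- function(regions, stage_meth, hyper_min = 0.75,
                          hypo_max = 0.25, inter_lo = 0.30, inter_hi = 0.70,
                          min_cpgs = 3, min_depth = 3) {
  need <- c("oocyte", "sperm", "pg_morula", "ag_morula", "pg_blast",
            "ag_blast", "placenta", "embryo6w")
  if (!all(need %in% names(stage_meth)))
    stop("stage_meth must supply: ", paste(need, collapse = ", "))
  lv <- function(nm) region_methylation(stage_meth[[nm]], regions,
                                        min_cpgs, min_depth)$level
  levels <- data.frame(mat_gamete = lv("oocyte"), pat_gamete = lv("sperm"),
                       mat_morula = lv("pg_morula"),
                       pat_morula = lv("ag_morula"),
                       mat_blast = lv("pg_blast"),
                       pat_blast = lv("ag_blast"),
                       placenta = lv("placenta"), embryo6w = lv("embryo6w"))
  cls <- gdmr_rule(levels$mat_gamete, levels$pat_gamete, levels$mat_morula,
                   levels$pat_morula, levels$mat_blast, levels$pat_blast,
                   levels$placenta, levels$embryo6w,
                   hyper_min, hypo_max, inter_lo, inter_hi)
  S4Vectors::mcols(regions) <- cbind(S4Vectors::mcols(regions),
                                     S4Vectors::DataFrame(levels),
                                     S4Vectors::DataFrame(cls))
  regions
}

#' Split gDMRs into known-overlapping and novel
#'
#' @param gdmrs `GRanges` of called gDMRs/pICRs.
#' @param known `GRanges` of previously reported allelic DMRs.
#' @return list(overlapping, novel, n_overlapping, n_novel); any >= 1 bp
#'   intersection counts as overlap.
#' @export
gdmr_overlap_known <- function(gdmrs, known) {
  hit <- IRanges::overlapsAny(gdmrs, known)
  list(overlapping = gdmrs[hit], novel = gdmrs[!hit],
       n_overlapping = sum(hit), n_novel = sum(!hit))
}
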