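#' Combine replicate peak sets conservatively
#'
#' A region counts as a peak for a parent only where it is called in every
#' replicate (interval intersection), the conservative choice for the
#' two-replicate designs typical of low-input embryo assays.
#'
#' @param peak_list list of `GRanges`, one per replicate.
#' @return a `GRanges` of intersected peaks.
#' @export
merge_replicate_peaks <- function(peak_list) {
  stopifnot(length(peak_list) >= 1)
  Reduce(function(a, b) GenomicRanges::intersect(a, b), peak_list)
}

#' Call parent-of-origin-specific regions for one assay
#'
#' PG (maternal) and AG (paternal) peak sets are merged into a union of
#' candidate loci so each locus is judged once. A locus is AG-specific when
#' a peak is present in AG only AND its AG bin signal exceeds
#' `fold_min x max(pg_signal, pseudocount)`; symmetrically for PG-specific.
#' Loci with peaks in both parents are bi-allelic; peak-presence differences
#' that fail the fold gate fall back to bi-allelic rather than specific.
#' H3K27me3 forms broad domains, so for that assay peaks are first merged
#' across gaps up to `merge_gap` bp.
#'
#' @param pg_peaks,ag_peaks replicate-merged peak `GRanges` per parent.
#' @param pg_signal,ag_signal [binned_signal()]s per parent on the same grid.
#' @param assay `"DHS"` or `"H3K27me3"`.
#' @param fold_min minimum signal fold for a specific call (default 4).
#' @param pseudocount floor on the comparison signal (default 0.5).
#' @param merge_gap domain-merge gap for H3K27me3 (default 3000 bp).
#' @return `GRanges` of merged loci with metadata columns `assay`, `state`
#'   (AG_specific / PG_specific / biallelic), `pg_signal`, `ag_signal`.
#' @export
call_allelic_regions <- function(pg_peaks, ag_peaks, pg_signal, ag_signal,
                                 assay = c("DHS", "H3K27me3"),
                                 fold_min = 4, pseudocount = 0.5,
                                 merge_gap = 3000) {
  assay <- match.arg(assay)
  if (length(pg_signal$bins) != length(ag_signal$bins) ||
      !all(pg_signal$bins == ag_signal$bins))
    stop("PG and AG signals are on different bin grids")
  if (assay == "H3K27me3") {
    pg_peaks <- GenomicRanges::reduce(pg_peaks, min.gapwidth = merge_gap + 1)
    ag_peaks <- GenomicRanges::reduce(ag_peaks, min.gapwidth = merge_gap + 1)
  }
  loci <- GenomicRanges::reduce(c(GenomicRanges::granges(pg_peaks),
                                  GenomicRanges::granges(ag_peaks)))
  in_pg <- IRanges::overlapsAny(loci, pg_peaks)
  in_ag <- IRanges::overlapsAny(loci, ag_peaks)
  pg_s <- signal_over_regions(pg_signal, loci)
  ag_s <- signal_over_regions(ag_signal, loci)
  state <- rep("biallelic", length(loci))
  state[in_ag & !in_pg & ag_s >= fold_min * pmax(pg_s, pseudocount)] <-
    "AG_specific"
  state[in_pg & !in_ag & pg_s >= fold_min * pmax(ag_s, pseudocount)] <-
    "PG_specific"
  loci$assay <- assay
  loci$state <- state
  loci$pg_signal <- pg_s
  loci$ag_signal <- ag_s
  loci
}

#' Partition genome bins into the four joint DHS/H3K27me3 groups
#'
#' Group I: DHS signal in at least one sample but H3K27me3 in none.
#' Group II: both marks somewhere. Group III: H3K27me3 only. Group IV:
#' neither. The groups are mutually exclusive and cover every bin.
#'
#' @param dhs_peaks list of `GRanges` peak sets (any sample/parent).
#' @param k27_peaks list of `GRanges` H3K27me3 region sets.
#' @param bins `GRanges` from [bin_genome()].
#' @return data.frame(bin index, group in I/II/III/IV) parallel to `bins`.
#' @export
partition_groups <- function(dhs_peaks, k27_peaks, bins) {
  marked <- function(peak_list) {
    if (length(peak_list) == 0) return(rep(FALSE, length(bins)))
    Reduce(`|`, lapply(peak_list, function(p)
      IRanges::overlapsAny(bins, p)))
  }
  d <- marked(dhs_peaks)
  k <- marked(k27_peaks)
  group <- ifelse(d & !k, "I", ifelse(d & k, "II", ifelse(!d & k, "III",
                                                          "IV")))
  data.frame(bin = seq_along(bins), group = group)
}

#' Classify regions as promoter, genic or intergenic
#'
#' Promoter (`tss +/- flank`) takes precedence over genic (gene body), which
#' takes precedence over intergenic; any >= 1 bp overlap counts.
#'
#' @param regions `GRanges` to classify.
#' @param genes a [gene_table()].
#' @param flank promoter half-width in bp (default 2000).
#' @param genome a [genome_decl()].
#' @return character vector of locations parallel to `regions`.
#' @export
classify_location <- function(regions, genes, flank = 2000, genome) {
  prom <- promoter_windows(genes, flank, genome)
  bodies <- genes_gr(genes, genome)
  loc <- rep("intergenic", length(regions))
  loc[IRanges::overlapsAny(regions, bodies)] <- "genic"
  loc[IRanges::overlapsAny(regions, prom)] <- "promoter"
  loc
}

#' Transcription and enhancer-mark annotation of intergenic allelic DHSs
#'
#' For each parental class of intergenic allele-specific DHSs, reports the
#' fraction transcribed (region RPKM >= `rpkm_min`, inclusive) and the
#' fraction overlapping H3K27ac peaks (candidate distal enhancers).
#'
#' @param calls allelic DHS calls (from [call_allelic_regions()]) already
#'   restricted to intergenic regions.
#' @param region_rpkm numeric RPKM per region, parallel to `calls`.
#' @param k27ac_peaks `GRanges` of H3K27ac peaks.
#' @param rpkm_min transcription threshold (default 1).
#' @return data.frame per state: n, frac_transcribed, frac_k27ac (NA with
#'   `defined = FALSE` for empty classes).
#' @export
intergenic_dhs_annotation <- function(calls, region_rpkm, k27ac_peaks,
                                      rpkm_min = 1) {
  stopifnot(length(calls) == length(region_rpkm))
  ac <- IRanges::overlapsAny(calls, k27ac_peaks)
  out <- lapply(c("AG_specific", "PG_specific"), function(st) {
    i <- calls$state == st
    n <- sum(i)
    data.frame(state = st, n = n,
               frac_transcribed = if (n) mean(region_rpkm[i] >= rpkm_min)
                                  else NA_real_,
               frac_k27ac = if (n) mean(ac[i]) else NA_real_,
               defined = n > 0)
  })
  do.call(rbind, out)
}
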