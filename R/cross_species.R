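# map each query region through an orthology map: returns, per query, the
# index of the best source pair (largest source overlap, tie -> smaller
# target start) or NA when the region hits no source interval
.best_ortho_pair <- function(regions, ortho) {
  hits <- GenomicRanges::findOverlaps(regions, ortho$source)
  best <- rep(NA_integer_, length(regions))
  if (length(hits) == 0) return(best)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    regions[qi], ortho$source[si]))
  tstart <- GenomicRanges::start(ortho$target)[si]
  o <- order(qi, -ov, tstart)
  keep <- !duplicated(qi[o])
  best[qi[o][keep]] <- si[o][keep]
  best
}

#' Nested orthology breakdown of allelic regions
#'
#' Follows one set of allele-specific regions through the cross-species
#' chain: how many have an orthologous interval in the target genome; of
#' those, how many are marked (e.g. open chromatin) in the target species;
#' of those, how many fall in regions where parental SNPs make the allele
#' trackable; and of the trackable ones, which target allelic state they
#' show. Counts are monotone along the chain.
#'
#' @param regions `GRanges` of source-species allelic regions (one state).
#' @param ortho an [orthology_map()].
#' @param target_marks `GRanges` of target-species peaks/domains.
#' @param trackable_mask `GRanges` of SNP-trackable target regions.
#' @param target_calls `GRanges` of target allelic calls with a `state`
#'   column (maternal_specific / paternal_specific / biallelic).
#' @return list(n_input, n_orthologous, n_marked_in_target, n_trackable,
#'   states = named counts over the trackable regions; untracked states
#'   default to "other").
#' @export
orthology_breakdown <- function(regions, ortho, target_marks,
                                trackable_mask, target_calls) {
  best <- .best_ortho_pair(regions, ortho)
  mapped <- !is.na(best)
  tgt <- ortho$target[best[mapped]]
  marked <- IRanges::overlapsAny(tgt, target_marks)
  trackable <- marked & IRanges::overlapsAny(tgt, trackable_mask)
  states <- c(maternal_specific = 0L, paternal_specific = 0L,
              biallelic = 0L, other = 0L)
  if (any(trackable)) {
    tt <- tgt[trackable]
    st <- rep("other", length(tt))
    if (length(target_calls)) {
      hits <- GenomicRanges::findOverlaps(tt, target_calls)
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      keep <- !duplicated(qi)
      st[qi[keep]] <- as.character(target_calls$state[si[keep]])
    }
    st[!st %in% names(states)] <- "other"
    tb <- table(factor(st, names(states)))
    states[names(tb)] <- as.integer(tb)
  }
  list(n_input = length(regions), n_orthologous = sum(mapped),
       n_marked_in_target = sum(marked), n_trackable = sum(trackable),
       states = states)
}

#' Cross-species conservation of maternal-specific methylation
#'
#' For PG-hyper (maternally methylated) DMRs with a target-genome
#' orthologue, classifies the target interval as maternal-specific
#' methylation, bi-allelic methylation or hypomethylation, or other. The
#' three parts sum to the orthologous count.
#'
#' @param dmrs source PG-hyper DMRs (`GRanges`).
#' @param ortho an [orthology_map()].
#' @param target_maternal `GRanges`: maternally specific methylation in the
#'   target species.
#' @param target_bihypo `GRanges`: bi-allelically methylated or
#'   hypomethylated target regions.
#' @return list(n_input, n_orthologous, n_maternal_specific,
#'   n_biallelic_or_hypo, n_other).
#' @export
methylation_conservation <- function(dmrs, ortho, target_maternal,
                                     target_bihypo) {
  best <- .best_ortho_pair(dmrs, ortho)
  tgt <- ortho$target[best[!is.na(best)]]
  mat <- IRanges::overlapsAny(tgt, target_maternal)
  bih <- !mat & IRanges::overlapsAny(tgt, target_bihypo)
  list(n_input = length(dmrs), n_orthologous = length(tgt),
       n_maternal_specific = sum(mat), n_biallelic_or_hypo = sum(bih),
       n_other = sum(!mat & !bih))
}

#' Conservation-score contrast of allelic vs common regions
#'
#' Scores each region by the mean of a per-base conservation track
#' (supplied as fixed-step intervals with a `score` column), then compares
#' the allelic and common distributions with a Wilcoxon rank-sum test
#' (mid-ranks for ties; exact null below `exact_below` per group, normal
#' approximation with continuity correction above). Regions with no score
#' coverage are dropped.
#'
#' @param allelic,common `GRanges` of the two region groups.
#' @param score_track `GRanges` with numeric `score` (non-overlapping
#'   intervals).
#' @param exact_below exact-test size cutoff (default 20).
#' @return list(allelic_scores, common_scores, statistic = rank-sum U for
#'   the allelic group, p_value, median_difference = median(allelic) -
#'   median(common)).
#' @export
conservation_contrast <- function(allelic, common, score_track,
                                  exact_below = 20) {
  score_of <- function(regions) {
    hits <- GenomicRanges::findOverlaps(regions, score_track)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out <- rep(NA_real_, length(regions))
    if (length(qi)) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        regions[qi], score_track[si]))
      num <- rowsum(w * score_track$score[si], qi)
      den <- rowsum(w, qi)
      out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
    }
    out[!is.na(out)]
  }
  a <- score_of(allelic)
  b <- score_of(common)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 scored regions in each group")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  exact <- length(a) < exact_below && length(b) < exact_below &&
    !anyDuplicated(c(a, b))
  p <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  list(allelic_scores = a, common_scores = b, statistic = u, p_value = p,
       median_difference = stats::median(a) - stats::median(b))
}
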