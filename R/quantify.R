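#' Methylation level of one region
#'
#' The CpG methylation level (ML) of a region is the coverage-weighted
#' fraction `sum(methylated) / sum(total)` over the CpGs inside it, counting
#' only CpGs sequenced to at least `min_depth` reads. When fewer than
#' `min_cpgs` CpGs qualify the level is undefined (`NA`), mirroring the
#' "unavailable ML" state shown grey in low-input embryo methylomes.
#'
#' @param meth a [methylome()].
#' @param region a single-interval `GRanges`.
#' @param min_cpgs minimum qualifying CpGs for a defined level (default 3).
#' @param min_depth minimum per-CpG total count (default 3).
#' @return list(level, n_cpgs_covered, total_coverage); `level` is `NA` when
#'   undefined.
#' @export
methylation_level <- function(meth, region, min_cpgs = 3, min_depth = 3) {
  stopifnot(inherits(meth, "methylome"), min_cpgs >= 1, min_depth >= 1)
  lv <- region_methylation(meth, region, min_cpgs, min_depth)
  list(level = lv$level[1], n_cpgs_covered = lv$n_cpgs[1],
       total_coverage = lv$coverage[1])
}

#' Methylation levels over many regions at once
#'
#' Vectorised workhorse behind [methylation_level()], DMR calling and the
#' germline-DMR classifier.
#'
#' @inheritParams methylation_level
#' @param regions a `GRanges`.
#' @return data.frame with one row per region: level (NA if undefined),
#'   n_cpgs, coverage.
#' @export
region_methylation <- function(meth, regions, min_cpgs = 3, min_depth = 3) {
  cpgs <- meth$cpgs
  cpgs <- cpgs[cpgs$total >= min_depth]
  hits <- GenomicRanges::findOverlaps(cpgs, regions)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  n <- length(regions)
  nc <- tabulate(si, n)
  mth <- cov <- numeric(n)
  if (length(si)) {
    agg <- rowsum(cbind(cpgs$methylated[qi], cpgs$total[qi]), si)
    idx <- as.integer(rownames(agg))
    mth[idx] <- agg[, 1]
    cov[idx] <- agg[, 2]
  }
  level <- ifelse(nc >= min_cpgs, mth / pmax(cov, 1), NA_real_)
  data.frame(level = level, n_cpgs = nc, coverage = cov)
}

#' Normalised binned signal from fragment intervals
#'
#' Each fragment is assigned to the single bin containing its midpoint
#' (half-open convention: a midpoint on a bin boundary belongs to the bin
#' that starts there) and counts are scaled to fragments per bin per million
#' library fragments.
#'
#' @param fragments `GRanges` of sequenced fragments.
#' @param bins `GRanges` from [bin_genome()].
#' @param library_size total fragment count used for scaling (> 0);
#'   defaults to `length(fragments)`.
#' @return a `binned_signal`: list(bins, values).
#' @export
bin_signal <- function(fragments, bins, library_size = length(fragments)) {
  if (library_size <= 0) stop("library_size must be positive")
  mid0 <- (GenomicRanges::start(fragments) - 1L) +
    GenomicRanges::width(fragments) %/% 2L  # 0-based midpoint of [s, e)
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(fragments),
                                 IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  hits <- GenomicRanges::findOverlaps(mids, bins)
  counts <- tabulate(S4Vectors::subjectHits(hits), length(bins))
  binned_signal(bins, 1e6 * counts / library_size)
}

#' Construct a binned signal track
#' @param bins `GRanges` of fixed-width bins tiling the genome.
#' @param values non-negative per-bin signal, parallel to `bins`.
#' @export
binned_signal <- function(bins, values) {
  stopifnot(length(bins) == length(values), all(values >= 0))
  structure(list(bins = bins, values = as.numeric(values)),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat("Binned signal:", length(x$bins), "bins, mean",
      signif(mean(x$values), 4), "\n")
  invisible(x)
}

# mean bin signal over arbitrary regions (bins weighted equally)
signal_over_regions <- function(signal, regions) {
  hits <- GenomicRanges::findOverlaps(signal$bins, regions)
  si <- S4Vectors::subjectHits(hits)
  out <- numeric(length(regions))
  n <- tabulate(si, length(regions))
  if (length(si)) {
    agg <- rowsum(signal$values[S4Vectors::queryHits(hits)], si)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  ifelse(n > 0, out / pmax(n, 1), 0)
}

#' Differential fraction m / n
#'
#' The accounting statistic of the genome-partition analyses: `m` regions
#' carry a parent-specific mark out of `n` regions marked in either parent.
#'
#' @param m parent-specific region count (0 <= m <= n).
#' @param n regions marked in either parent.
#' @return list(m, n, fraction); fraction is `NA` when `n == 0`.
#' @export
differential_fraction <- function(m, n) {
  if (m < 0 || n < 0 || m > n) stop("need 0 <= m <= n")
  list(m = as.integer(m), n = as.integer(n),
       fraction = if (n > 0) m / n else NA_real_)
}

#' Render a count-pair fraction as a percentage
#'
#' @param frac a [differential_fraction()] or list with `fraction`.
#' @param mode `"one_decimal"` (e.g. `76.9`) or `"integer"` (e.g. `82`);
#'   default picks one decimal when the denominator is >= 10000.
#' @return numeric percentage at the requested rounding.
#' @export
percent_of <- function(frac, mode = NULL) {
  if (is.null(mode)) mode <- if (frac$n >= 10000) "one_decimal" else "integer"
  mode <- match.arg(mode, c("one_decimal", "integer"))
  if (is.na(frac$fraction)) return(NA_real_)
  if (mode == "one_decimal") round(100 * frac$fraction, 1)
  else round(100 * frac$fraction)
}

#' Promoter CpG density of a gene
#'
#' Counts CpG positions in the promoter window `tss +/- flank` (clipped to
#' the chromosome) and reports CpGs per 100 bp. For `-` strand genes the
#' promoter is centred on the last transcribed base.
#'
#' @param gene one row of a [gene_table()].
#' @param cpg_sites `GRanges` of CpG positions (width 1) or a `methylome`.
#' @param flank half-width of the promoter window in bp.
#' @param genome a [genome_decl()].
#' @return CpGs per 100 bp of promoter.
#' @export
promoter_cpg_density <- function(gene, cpg_sites, flank, genome) {
  if (inherits(cpg_sites, "methylome")) cpg_sites <- cpg_sites$cpgs
  win <- promoter_windows(gene, flank, genome)
  if (GenomicRanges::width(win) <= 0) stop("promoter empty after clipping")
  n <- IRanges::countOverlaps(win, cpg_sites)
  as.numeric(100 * n / GenomicRanges::width(win))
}

# promoter windows for a gene table: [tss - flank, tss + flank), clipped
promoter_windows <- function(genes, flank, genome) {
  start <- pmax(1L, genes$tss - as.integer(flank))
  end <- pmin(genome[genes$chrom], genes$tss + as.integer(flank) - 1L)
  if (any(end < start)) stop("promoter empty after clipping")
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start, end),
                         gene_id = genes$gene_id,
                         seqinfo = seqinfo_from_genome(genome))
}
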