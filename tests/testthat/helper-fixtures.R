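# shared fixtures: a tiny two-chromosome genome and quick constructors,
# plus a memoised default simulation reused by the recovery tests

tiny_genome <- genome_decl(c(chr1 = 10000, chr2 = 8000))

gr_ <- function(chrom, start, end, genome = tiny_genome, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...,
                         seqinfo = allelomap:::seqinfo_from_genome(genome))
}

mk_meth <- function(pos, methylated, total, chrom = "chr1",
                    genome = tiny_genome, ...) {
  methylome(rep_len(chrom, length(pos)), pos, methylated, total, genome,
            ...)
}

# constant-signal track helper: every bin at `base`, bins overlapping
# `high_regions` at `high`
mk_signal <- function(bins, base = 0.1, high_regions = NULL, high = 10) {
  v <- rep(base, length(bins))
  if (!is.null(high_regions) && length(high_regions))
    v[unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(high_regions, bins)))] <- high
  binned_signal(bins, v)
}

.sim_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_env$sim))
    .sim_env$sim <- simulate_study(sim_config(seed = 42))
  .sim_env$sim
}

default_report <- function() {
  if (is.null(.sim_env$report))
    .sim_env$report <- run_pipeline(default_sim()$inputs)
  .sim_env$report
}

# nested-chain orthology fixture: 20 source regions of which 10 map, 5 are
# marked in the target species, 2 are SNP-trackable and 1 keeps a
# maternal-specific state
make_chain_fixture <- function() {
  gh <- genome_decl(c(chrH = 1e6))
  gm <- genome_decl(c(chrM = 1e6))
  st <- seq(1001, by = 2000, length.out = 20)
  regions <- GenomicRanges::GRanges(
    "chrH", IRanges::IRanges(st, st + 499),
    seqinfo = allelomap:::seqinfo_from_genome(gh))
  src <- regions[1:10]
  src$pair <- 1:10
  tstart <- seq(5001, by = 3000, length.out = 10)
  ortho <- orthology_map(src, rep("chrM", 10), tstart, tstart + 499, gm)
  tgt <- ortho$target
  target_calls <- GenomicRanges::granges(tgt[1:2])
  target_calls$state <- c("maternal_specific", "biallelic")
  list(regions = regions, ortho = ortho,
       marks = GenomicRanges::granges(tgt[1:5]),
       mask = GenomicRanges::granges(tgt[1:2]),
       calls = target_calls, gh = gh, gm = gm)
}

# overlap-based recovery rates of called vs planted regions
recovery <- function(called, planted) {
  list(sensitivity = if (length(planted) == 0) NA_real_ else
         mean(IRanges::overlapsAny(planted, called)),
       precision = if (length(called) == 0) NA_real_ else
         mean(IRanges::overlapsAny(called, planted)))
}
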