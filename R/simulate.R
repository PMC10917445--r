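#' Configuration for the synthetic uniparental-embryo study
#'
#' The generator emulates the processed inputs of a PG/AG (maternal-only /
#' paternal-only) embryo epigenome study: per-CpG bisulfite counts across
#' gametes, morula, blastocyst and two bi-parental somatic tissues; DHS and
#' H3K27me3 peaks with binned signal for both parents; replicate RPKM
#' expression; an imprinted-gene catalogue and known allelic-DMR list; a
#' cross-species orthology map with planted target states; and a
#' conservation score track. Ground truth for every planted feature is
#' returned alongside. Defaults echo the asymmetries reported for human
#' embryos: H3K27me3 differences skewed to the paternal (AG) side, germline
#' DMRs mostly maternally methylated, more paternally expressed imprinted
#' genes.
#'
#' @param seed integer; fully determines every output.
#' @param chrom_length length of each of the 2 human-side and 2 mouse-side
#'   chromosomes (default 5 Mb).
#' @param cpg_rate background CpG density per bp (default 0.01); island
#'   promoters are 5x denser.
#' @param coverage_mean mean per-CpG read depth (Poisson, default 10).
#' @param beta_conc concentration of the Beta noise around each CpG's true
#'   level (default 20).
#' @param n_gdmr planted germline DMRs (default 40).
#' @param gdmr_maternal_frac fraction maternally methylated (default 0.8).
#' @param n_dhs_ag,n_dhs_pg,n_dhs_shared planted DHS counts (80 / 50 / 200).
#' @param n_k27_ag,n_k27_pg,n_k27_shared planted H3K27me3 region counts
#'   (60 / 20 / 100).
#' @param n_imprinted planted imprinted genes (default 25);
#'   `n_imprinted_paternal` of them paternally expressed (default 18).
#' @param n_imprinted_paternal see above.
#' @param n_coordinated promoters with both maternal hypermethylation and
#'   paternal H3K27me3 (default 15; up to 8 drawn from the paternally
#'   expressed imprinted genes).
#' @param ortho_frac fraction of planted regions given a mouse-side
#'   orthologue (default 0.15).
#' @param expr_sigma log-normal replicate noise sd on RPKM (default 0.3).
#' @param n_replicates expression replicates per parent (default 2).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, chrom_length = 5e6, cpg_rate = 0.01,
                       coverage_mean = 10, beta_conc = 20, n_gdmr = 40,
                       gdmr_maternal_frac = 0.8, n_dhs_ag = 80,
                       n_dhs_pg = 50, n_dhs_shared = 200, n_k27_ag = 60,
                       n_k27_pg = 20, n_k27_shared = 100, n_imprinted = 25,
                       n_imprinted_paternal = NULL, n_coordinated = 15,
                       ortho_frac = 0.15, expr_sigma = 0.3,
                       n_replicates = 2) {
  if (is.null(n_imprinted_paternal))
    n_imprinted_paternal <- round(n_imprinted * 0.72)  # 18 of 25 paternal
  cfg <- as.list(environment())
  cfg$n_genes <- 500L  # fixed 20 kb gene-cell layout, 250 genes per chrom
  cfg$genome_h <- genome_decl(c(chrH1 = chrom_length, chrH2 = chrom_length))
  cfg$genome_m <- genome_decl(c(chrM1 = chrom_length, chrM2 = chrom_length))
  if (n_imprinted > n_gdmr)
    stop("infeasible config: every imprinted gene needs a planted gDMR")
  if (n_imprinted_paternal > n_imprinted)
    stop("infeasible config: n_imprinted_paternal > n_imprinted")
  n_maternal <- round(n_gdmr * gdmr_maternal_frac)
  if (n_imprinted_paternal > n_maternal ||
      (n_imprinted - n_imprinted_paternal) > (n_gdmr - n_maternal))
    stop("infeasible config: imprinted counts exceed gDMR allele counts")
  if (n_coordinated > 15 || n_genes_needed(cfg) > cfg$n_genes)
    stop("infeasible config: planted features exceed the gene-cell layout")
  cfg$n_gdmr_maternal <- n_maternal
  structure(cfg, class = "sim_config")
}

# cells consumed by the fixed layout (see .sim_layout)
n_genes_needed <- function(cfg) {
  55 + 40 + max(cfg$n_dhs_ag - 20, 0) + max(cfg$n_dhs_pg - 12, 0) +
    cfg$n_dhs_shared
}

# deterministic substream: one named RNG stream per simulated artifact so
# adding an output never perturbs the others
.stream <- function(seed, role) {
  h <- sum(utf8ToInt(role) * seq_along(utf8ToInt(role)))
  set.seed((as.numeric(seed) * 2654435 + h * 97) %% 2147483562)
}

# Fixed layout: 500 cells of 20 kb (250 per chromosome). Within a cell
# (coordinates relative, 1-based): gene body [8001,16000], TSS at 8001 for
# "+" genes and 16000 for "-" genes, promoter = TSS +/- 2 kb, intergenic
# element slots in [1001,5500]. Cell ranges below reserve disjoint cells
# per within-assay category so planted features of one assay never overlap.
.sim_layout <- function(cfg) {
  n_cells <- cfg$n_genes
  cell0 <- (seq_len(n_cells) - 1L) %% 250L * 20000L  # 0-based cell start
  chrom <- rep(c("chrH1", "chrH2"), each = 250L)[seq_len(n_cells)]
  strand <- ifelse(seq_len(n_cells) > 100 & seq_len(n_cells) %% 2 == 0,
                   "-", "+")
  strand[1:55] <- "+"
  tss <- ifelse(strand == "+", cell0 + 8001L, cell0 + 16000L)
  list(n_cells = n_cells, cell0 = cell0, chrom = chrom, strand = strand,
       tss = tss)
}

#' Generate the full synthetic study
#'
#' @param cfg a [sim_config()].
#' @param components character subset of
#'   `c("methylation", "peaks", "expression", "orthology")`; all by default.
#'   Skipping components speeds up runs that only need one data modality.
#' @return list(inputs, truth, config). `inputs` holds every object the
#'   pipeline consumes; `truth` holds the planted ground truth used by the
#'   recovery tests.
#' @export
simulate_study <- function(cfg = sim_config(),
                           components = c("methylation", "peaks",
                                          "expression", "orthology")) {
  lay <- .sim_layout(cfg)
  gh <- cfg$genome_h
  genes <- gene_table(sprintf("G%03d", seq_len(lay$n_cells)), lay$chrom,
                      lay$strand, lay$cell0 + 8001L, lay$cell0 + 16000L,
                      genome = gh)

  # ---- role assignment over cells -------------------------------------
  n_imp <- cfg$n_imprinted
  n_imp_pat <- cfg$n_imprinted_paternal
  imp_cells <- seq_len(n_imp)                       # imprinted genes
  imp_pat_cells <- utils::head(imp_cells, n_imp_pat)  # paternally expressed
  imp_mat_cells <- setdiff(imp_cells, imp_pat_cells)
  n_coord_imp <- min(8L, n_imp_pat, cfg$n_coordinated)
  coord_imp_cells <- utils::head(imp_pat_cells, n_coord_imp)
  coord_only_cells <- if (cfg$n_coordinated > n_coord_imp)
    25L + seq_len(cfg$n_coordinated - n_coord_imp) else integer()
  silent_cells <- 451:500
  n_gdmr_extra <- cfg$n_gdmr - n_imp
  n_extra_mat <- cfg$n_gdmr_maternal - n_imp_pat
  extra_cells <- if (n_gdmr_extra > 0) 40L + seq_len(n_gdmr_extra) else
    integer()
  island_cells <- unique(c(imp_cells, coord_only_cells,
                           which(seq_len(lay$n_cells) %% 5 == 0)))

  # ---- planted germline DMRs ------------------------------------------
  # promoter gDMRs for imprinted genes (hyper allele = silenced side),
  # intergenic gDMRs elsewhere; all 2 kb, aligned to the 1 kb bin grid
  gdmr_cell <- c(imp_cells, extra_cells)
  gdmr_at_prom <- c(rep(TRUE, n_imp), rep(FALSE, n_gdmr_extra))
  gdmr_start <- ifelse(gdmr_at_prom, lay$cell0[gdmr_cell] + 7001L,
                       lay$cell0[gdmr_cell] + 3001L)
  gdmr_allele <- c(rep("maternal", n_imp_pat),
                   rep("paternal", n_imp - n_imp_pat),
                   rep("maternal", max(n_extra_mat, 0)),
                   rep("paternal", max(n_gdmr_extra - n_extra_mat, 0)))
  # somatic classes: imprinted gDMRs are all pICRs; of the extras, 9 are
  # pICRs (3 per class) and the rest lose intermediate somatic methylation
  classes <- c("non_specific", "placenta_specific", "embryo_specific")
  gdmr_class <- c(rep(classes, length.out = n_imp),
                  if (n_gdmr_extra > 0)
                    c(rep(classes, length.out = min(9, n_gdmr_extra)),
                      rep("none", max(n_gdmr_extra - 9, 0))))
  gdmrs <- if (cfg$n_gdmr > 0)
    as_regions(lay$chrom[gdmr_cell], gdmr_start, gdmr_start + 1999L, gh,
               cell = gdmr_cell, hyper_allele = gdmr_allele,
               somatic_class = gdmr_class,
               is_pICR = gdmr_class != "none",
               gene_id = ifelse(gdmr_at_prom, genes$gene_id[gdmr_cell],
                                NA_character_),
               in_cpg_island = gdmr_cell %in% island_cells)
  else GenomicRanges::GRanges(seqinfo = seqinfo_from_genome(gh))

  # coordinated-only promoters: maternal hypermethylation arising after
  # fertilisation (blastocyst DMR but not a gDMR: gametes at background)
  coord_dmrs <- if (length(coord_only_cells))
    as_regions(lay$chrom[coord_only_cells],
               lay$cell0[coord_only_cells] + 7001L,
               lay$cell0[coord_only_cells] + 9000L, gh,
               cell = coord_only_cells)
  else GenomicRanges::GRanges(seqinfo = seqinfo_from_genome(gh))

  truth <- list(genes = genes, gdmrs = gdmrs,
                imprinted = data.frame(
                  gene_id = genes$gene_id[imp_cells],
                  expressed_allele = c(rep("paternal", n_imp_pat),
                                       rep("maternal", n_imp - n_imp_pat)),
                  row.names = NULL),
                coordinated_genes = genes$gene_id[
                  c(coord_imp_cells, coord_only_cells)],
                silent_genes = genes$gene_id[silent_cells])
  inputs <- list(genome_h = gh, genome_m = cfg$genome_m, genes = genes)

  # planted blastocyst DMRs = gDMRs + coordinated-only promoter DMRs
  pd <- c(GenomicRanges::granges(gdmrs), GenomicRanges::granges(coord_dmrs))
  pd$direction <- c(ifelse(gdmrs$hyper_allele == "maternal", "PG_hyper",
                           "AG_hyper"),
                    rep("PG_hyper", length(coord_dmrs)))
  truth$dmrs_blastocyst <- GenomicRanges::sort(pd)

  if ("methylation" %in% components) {
    cpgs <- .sim_cpg_sites(cfg, lay, island_cells)
    inputs$cpg_sites <- cpgs
    meths <- .sim_methylomes(cfg, cpgs, gdmrs, coord_dmrs)
    inputs <- c(inputs, meths)
  }
  if ("peaks" %in% components) {
    pk <- .sim_peaks(cfg, lay, genes, coord_imp_cells, coord_only_cells)
    inputs <- c(inputs, pk$inputs)
    truth <- c(truth, pk$truth)
  }
  if ("expression" %in% components) {
    ex <- .sim_expression(cfg, lay, genes, imp_pat_cells, imp_mat_cells,
                          coord_only_cells, silent_cells)
    inputs <- c(inputs, ex$inputs)
    truth <- c(truth, ex$truth)
  }
  if ("orthology" %in% components && "peaks" %in% components) {
    ot <- .sim_orthology(cfg, truth, gdmrs)
    inputs <- c(inputs, ot$inputs)
    truth <- c(truth, ot$truth)
  }
  # known allelic-DMR list: half the planted gDMRs plus intergenic decoys
  .stream(cfg$seed, "known_dmrs")
  n_known <- ceiling(cfg$n_gdmr / 2)
  decoy_cells <- 430:439
  known <- c(if (n_known > 0) GenomicRanges::granges(
    gdmrs[seq_len(n_known)]) else GenomicRanges::GRanges(
      seqinfo = seqinfo_from_genome(gh)),
    as_regions(lay$chrom[decoy_cells], lay$cell0[decoy_cells] + 4001L,
               lay$cell0[decoy_cells] + 4800L, gh))
  inputs$known_dmrs <- GenomicRanges::sort(known)
  truth$known_dmr_gdmr_idx <- seq_len(n_known)

  list(inputs = inputs, truth = truth, config = cfg)
}

# CpG positions: uniform background at cpg_rate, 5x density in island
# promoters; shared by every methylome (CpGs are genomic features)
.sim_cpg_sites <- function(cfg, lay, island_cells) {
  .stream(cfg$seed, "cpg_sites")
  gh <- cfg$genome_h
  pos <- lapply(names(gh), function(ch) {
    n_bg <- round(as.numeric(gh[[ch]]) * cfg$cpg_rate)
    p <- sort(sample.int(gh[[ch]], n_bg))
    isl <- island_cells[lay$chrom[island_cells] == ch]
    if (length(isl)) {
      prom_lo <- lay$tss[isl] - 2000L
      prom_hi <- lay$tss[isl] + 1999L
      extra <- unlist(lapply(seq_along(isl), function(i) {
        k <- round(4000 * cfg$cpg_rate * 4)  # 4x extra on top of background
        prom_lo[i] + sample.int(4000L, k) - 1L
      }))
      p <- sort(unique(c(p, extra)))
    }
    data.frame(chrom = ch, pos = p)
  })
  df <- do.call(rbind, pos)
  as_regions(df$chrom, df$pos, df$pos, gh)
}

# per-stage background methylation levels; AG runs 0.05 below PG along the
# embryonic demethylation trajectory (0.8 in gametes down to 0.45/0.40 at
# blastocyst), somatic tissues partially remethylated
.sim_stage_background <- function() {
  c(sperm = 0.8, oocyte = 0.8, pg_morula = 0.60, ag_morula = 0.55,
    pg_blast = 0.45, ag_blast = 0.40, placenta = 0.45, embryo6w = 0.75)
}

.sim_methylomes <- function(cfg, cpgs, gdmrs, coord_dmrs) {
  bg <- .sim_stage_background()
  n <- length(cpgs)
  # truth level per CpG per sample: background, overridden in planted
  # regions
  lv <- vapply(names(bg), function(s) rep(bg[[s]], n), numeric(n))
  side <- c(sperm = "paternal", oocyte = "maternal", pg_morula = "maternal",
            ag_morula = "paternal", pg_blast = "maternal",
            ag_blast = "paternal")
  if (length(gdmrs)) {
    hit <- GenomicRanges::findOverlaps(cpgs, gdmrs)
    qi <- S4Vectors::queryHits(hit)
    gi <- S4Vectors::subjectHits(hit)
    for (s in names(side)) {
      hyper <- gdmrs$hyper_allele[gi] == side[[s]]
      lv[qi, s] <- ifelse(hyper, 0.9, 0.05)
    }
    cls <- gdmrs$somatic_class[gi]
    lv[qi, "placenta"] <- ifelse(cls %in% c("non_specific",
                                            "placenta_specific"), 0.5, 0.9)
    lv[qi, "embryo6w"] <- ifelse(cls %in% c("non_specific",
                                            "embryo_specific"), 0.5, 0.9)
  }
  if (length(coord_dmrs)) {
    qi <- S4Vectors::queryHits(GenomicRanges::findOverlaps(cpgs,
                                                           coord_dmrs))
    lv[qi, "pg_blast"] <- 0.9
    lv[qi, "ag_blast"] <- 0.05
    lv[qi, "pg_morula"] <- 0.9   # maternal methylation gained by morula
    lv[qi, "ag_morula"] <- 0.05
  }
  meta <- list(sperm = c("sperm", "paternal_gamete"),
               oocyte = c("oocyte", "maternal_gamete"),
               pg_morula = c("morula", "PG"), ag_morula = c("morula", "AG"),
               pg_blast = c("blastocyst", "PG"),
               ag_blast = c("blastocyst", "AG"),
               placenta = c("placenta", "biparental"),
               embryo6w = c("embryo6w", "biparental"))
  out <- lapply(names(bg), function(s) {
    .stream(cfg$seed, paste0("meth_", s))
    total <- pmax(1L, stats::rpois(n, cfg$coverage_mean))
    p <- stats::rbeta(n, cfg$beta_conc * lv[, s],
                      cfg$beta_conc * (1 - lv[, s]))
    meth <- stats::rbinom(n, total, p)
    methylome(as.character(GenomeInfoDb::seqnames(cpgs)),
              GenomicRanges::start(cpgs), meth, total, cfg$genome_h,
              sample_id = s, stage = meta[[s]][1],
              parentage = meta[[s]][2])
  })
  names(out) <- paste0("meth_", names(bg))
  out
}

# planted DHS and H3K27me3 peaks with binned signal (fold 10 for
# parent-specific, equal for shared), plus H3K27ac peaks and region RPKM
# for the intergenic-DHS annotation
.sim_peaks <- function(cfg, lay, genes, coord_imp_cells, coord_only_cells) {
  gh <- cfg$genome_h
  mk <- function(cells, start_rel, width, from_tss = FALSE) {
    if (length(cells) == 0)
      return(GenomicRanges::GRanges(seqinfo = seqinfo_from_genome(gh)))
    start <- if (from_tss) lay$tss[cells] + start_rel
             else lay$cell0[cells] + start_rel
    as_regions(lay$chrom[cells], start, start + width - 1L, gh,
               cell = cells)
  }
  take <- function(from, n) if (n > 0) from - 1L + seq_len(n) else integer()

  # DHS: promoter slice capped at the layout's reserved ranges
  n_ag_prom <- min(20L, cfg$n_dhs_ag)
  n_pg_prom <- min(12L, cfg$n_dhs_pg)
  dhs_ag <- c(mk(take(60L, n_ag_prom), -250L, 500L, TRUE),
              mk(take(200L, cfg$n_dhs_ag - n_ag_prom), 2001L, 500L))
  dhs_pg <- c(mk(take(80L, n_pg_prom), -250L, 500L, TRUE),
              mk(take(260L, cfg$n_dhs_pg - n_pg_prom), 2001L, 500L))
  n_sh_prom <- min(100L, cfg$n_dhs_shared)
  dhs_sh <- c(mk(take(100L, n_sh_prom), -250L, 500L, TRUE),
              mk(take(300L, cfg$n_dhs_shared - n_sh_prom), 2001L, 500L))

  # H3K27me3: broad domains; the coordinated promoters carry AG-specific
  # domains, the rest are intergenic
  k27_ag <- c(mk(c(coord_imp_cells, coord_only_cells), -2000L, 4000L,
                 TRUE),
              mk(take(120L, max(cfg$n_k27_ag - length(coord_imp_cells) -
                                  length(coord_only_cells), 0)),
                 1001L, 4000L))
  k27_pg <- mk(take(165L, cfg$n_k27_pg), 1001L, 4000L)
  k27_sh <- mk(take(185L, cfg$n_k27_shared), 1001L, 4000L)

  bins2k <- bin_genome(gh, 2000)
  mk_signal <- function(role, present_sets, amps) {
    .stream(cfg$seed, role)
    v <- stats::runif(length(bins2k), 0, 0.2)
    for (i in seq_along(present_sets)) {
      idx <- unique(S4Vectors::subjectHits(GenomicRanges::findOverlaps(
        present_sets[[i]], bins2k)))
      v[idx] <- amps[i] * stats::runif(length(idx), 0.9, 1.1)
    }
    binned_signal(bins2k, v)
  }
  sig_dhs_ag <- mk_signal("sig_dhs_ag", list(dhs_sh, dhs_ag), c(5, 10))
  sig_dhs_pg <- mk_signal("sig_dhs_pg", list(dhs_sh, dhs_pg), c(5, 10))
  sig_k27_ag <- mk_signal("sig_k27_ag", list(k27_sh, k27_ag), c(5, 10))
  sig_k27_pg <- mk_signal("sig_k27_pg", list(k27_sh, k27_pg), c(5, 10))

  # H3K27ac: covers ~27% of AG-specific and ~18% of PG-specific intergenic
  # DHSs (candidate distal enhancers) plus decoys away from any DHS
  ag_int <- dhs_ag[GenomicRanges::start(dhs_ag) %% 20000L == 2001L]
  pg_int <- dhs_pg[GenomicRanges::start(dhs_pg) %% 20000L == 2001L]
  n_ac_ag <- round(0.27 * length(ag_int))
  n_ac_pg <- round(0.18 * length(pg_int))
  k27ac <- c(GenomicRanges::granges(ag_int[take(1L, n_ac_ag)]),
             GenomicRanges::granges(pg_int[take(1L, n_ac_pg)]),
             mk(take(405L, 20L), 1001L, 800L))
  # region RPKM: ~12% of AG-specific and ~14% of PG-specific intergenic
  # DHSs transcribed at RPKM >= 1
  n_tx_ag <- round(0.12 * length(ag_int))
  n_tx_pg <- round(0.14 * length(pg_int))
  rpkm_ag <- rep(0.05, length(ag_int)); rpkm_ag[take(1L, n_tx_ag)] <- 2
  rpkm_pg <- rep(0.05, length(pg_int)); rpkm_pg[take(1L, n_tx_pg)] <- 2

  truth_dhs <- c(dhs_ag, dhs_pg, dhs_sh)
  truth_dhs$state <- rep(c("AG_specific", "PG_specific", "biallelic"),
                         c(length(dhs_ag), length(dhs_pg), length(dhs_sh)))
  truth_k27 <- c(k27_ag, k27_pg, k27_sh)
  truth_k27$state <- rep(c("AG_specific", "PG_specific", "biallelic"),
                         c(length(k27_ag), length(k27_pg), length(k27_sh)))
  list(inputs = list(
         dhs_peaks_pg = GenomicRanges::sort(c(
           GenomicRanges::granges(dhs_pg), GenomicRanges::granges(dhs_sh))),
         dhs_peaks_ag = GenomicRanges::sort(c(
           GenomicRanges::granges(dhs_ag), GenomicRanges::granges(dhs_sh))),
         k27_peaks_pg = GenomicRanges::sort(c(
           GenomicRanges::granges(k27_pg), GenomicRanges::granges(k27_sh))),
         k27_peaks_ag = GenomicRanges::sort(c(
           GenomicRanges::granges(k27_ag), GenomicRanges::granges(k27_sh))),
         sig_dhs_pg = sig_dhs_pg, sig_dhs_ag = sig_dhs_ag,
         sig_k27_pg = sig_k27_pg, sig_k27_ag = sig_k27_ag,
         k27ac_peaks = GenomicRanges::sort(k27ac),
         intergenic_dhs_rpkm = {
           r <- c(GenomicRanges::granges(ag_int),
                  GenomicRanges::granges(pg_int))
           r$rpkm <- c(rpkm_ag, rpkm_pg)
           GenomicRanges::sort(r)
         }),
       truth = list(dhs = truth_dhs, k27 = truth_k27,
                    intergenic_dhs = list(
                      ag = ag_int, pg = pg_int, rpkm_ag = rpkm_ag,
                      rpkm_pg = rpkm_pg,
                      frac_k27ac_ag = if (length(ag_int))
                        n_ac_ag / length(ag_int) else NA_real_,
                      frac_k27ac_pg = if (length(pg_int))
                        n_ac_pg / length(pg_int) else NA_real_,
                      frac_tx_ag = if (length(ag_int))
                        n_tx_ag / length(ag_int) else NA_real_,
                      frac_tx_pg = if (length(pg_int))
                        n_tx_pg / length(pg_int) else NA_real_)))
}

.sim_expression <- function(cfg, lay, genes, imp_pat_cells, imp_mat_cells,
                            coord_only_cells, silent_cells) {
  .stream(cfg$seed, "expression")
  n <- nrow(genes)
  base <- stats::rlnorm(n, log(8), 0.5)  # per-gene baseline RPKM
  pg_mean <- ag_mean <- base
  pg_mean[imp_pat_cells] <- 0.05; ag_mean[imp_pat_cells] <- base[imp_pat_cells]
  ag_mean[imp_mat_cells] <- 0.05; pg_mean[imp_mat_cells] <- base[imp_mat_cells]
  pg_mean[coord_only_cells] <- ag_mean[coord_only_cells] <- 0.1
  pg_mean[silent_cells] <- ag_mean[silent_cells] <- 0.05
  reps <- cfg$n_replicates
  draw <- function(mu) matrix(stats::rlnorm(n * reps, log(mu),
                                            cfg$expr_sigma), n, reps)
  vals <- cbind(draw(ag_mean), draw(pg_mean))
  colnames(vals) <- c(paste0("AG_R", seq_len(reps)),
                      paste0("PG_R", seq_len(reps)))
  expr <- expression_table(genes$gene_id, colnames(vals), vals)
  # catalogue: most paternal + some maternal imprinted genes are "known";
  # plus reported genes that are bi-allelic or silent in these embryos
  known_imp <- c(utils::head(genes$gene_id[imp_pat_cells],
                             ceiling(length(imp_pat_cells) * 0.7)),
                 utils::head(genes$gene_id[imp_mat_cells],
                             ceiling(length(imp_mat_cells) * 0.7)))
  catalogue <- c(known_imp, genes$gene_id[380:389],
                 genes$gene_id[silent_cells[1:5]])
  list(inputs = list(expression = expr, imprint_catalogue = catalogue),
       truth = list(known_imprinted = known_imp,
                    catalogue_biallelic = genes$gene_id[380:389],
                    catalogue_silent = genes$gene_id[silent_cells[1:5]]))
}

# mouse-side orthology: ortho_frac of planted allelic DHS, allelic K27 and
# maternal gDMRs get a target interval; target marks / trackable mask /
# allelic states planted along a Fig-2g-style nested chain
.sim_orthology <- function(cfg, truth, gdmrs) {
  gm <- cfg$genome_m
  gh <- cfg$genome_h
  src_list <- list()
  roles <- character()
  add <- function(gr, role) {
    if (length(gr)) {
      src_list[[length(src_list) + 1]] <<- GenomicRanges::granges(gr)
      roles <<- c(roles, rep(role, length(gr)))
    }
  }
  dhs_allelic <- truth$dhs[truth$dhs$state != "biallelic"]
  # restrict the K27 and gDMR sides to intergenic planted regions so the
  # map's source intervals stay pairwise disjoint across assays
  k27_allelic <- truth$k27[truth$k27$state != "biallelic" &
                             GenomicRanges::start(truth$k27) %% 20000L ==
                             1001L]
  mat_gdmr <- if (length(gdmrs))
    gdmrs[gdmrs$hyper_allele == "maternal" & is.na(gdmrs$gene_id)]
  else gdmrs
  .stream(cfg$seed, "orthology")
  pick <- function(gr) {
    n <- round(cfg$ortho_frac * length(gr))
    if (n == 0) gr[integer()] else gr[sort(sample.int(length(gr), n))]
  }
  add(pick(dhs_allelic), "dhs")
  add(pick(k27_allelic), "k27")
  add(pick(mat_gdmr), "gdmr")
  if (length(src_list) == 0)
    return(list(inputs = list(), truth = list()))
  src <- do.call(c, src_list)
  n_pairs <- length(src)
  # targets: one 20 kb mouse cell per pair, same within-cell offset
  tcell <- seq_len(n_pairs) - 1L
  tchrom <- rep(c("chrM1", "chrM2"), each = 200L)[tcell + 1L]
  toff <- (GenomicRanges::start(src) - 1L) %% 20000L
  tstart <- (tcell %% 200L) * 25000L + toff + 1L
  tgt_w <- GenomicRanges::width(src)
  src2 <- src
  src2$pair <- seq_len(n_pairs)
  src2 <- GenomicRanges::sort(src2)
  ortho <- orthology_map(src2, tchrom, tstart, tstart + tgt_w - 1L, gm)
  tgt <- ortho$target
  role_sorted <- roles[src2$pair]

  # nested chain per pair: marked in mouse -> trackable -> allelic state.
  # Deterministic within role: every 2nd mapped region is marked, every
  # 2nd marked is trackable, first trackable per role keeps the human
  # state (conserved), the rest are biallelic
  marked <- trackable <- rep(FALSE, n_pairs)
  state <- rep(NA_character_, n_pairs)
  for (r in unique(role_sorted)) {
    i <- which(role_sorted == r)
    mk <- i[seq_along(i) %% 2 == 1]
    marked[mk] <- TRUE
    tk <- mk[seq_along(mk) %% 2 == 1]
    trackable[tk] <- TRUE
    if (length(tk)) {
      state[tk] <- "biallelic"
      state[tk[1]] <- "maternal_specific"
    }
  }
  target_marks <- GenomicRanges::sort(GenomicRanges::granges(tgt[marked]))
  trackable_mask <- GenomicRanges::sort(GenomicRanges::granges(
    tgt[trackable]))
  tc <- tgt[trackable]
  tc$state <- state[trackable]
  # methylation-conservation labels for gdmr targets: 1 in 6 conserved
  # maternal, the rest bi-allelic/hypo in mouse
  gi <- which(role_sorted == "gdmr")
  mat_idx <- gi[seq_along(gi) %% 6 == 1]
  target_maternal <- GenomicRanges::sort(GenomicRanges::granges(
    tgt[mat_idx]))
  target_bihypo <- GenomicRanges::sort(GenomicRanges::granges(
    tgt[setdiff(gi, mat_idx)]))
  list(inputs = list(ortho = ortho, target_marks = target_marks,
                     trackable_mask = trackable_mask,
                     target_calls = GenomicRanges::sort(tc),
                     target_maternal = target_maternal,
                     target_bihypo = target_bihypo),
       truth = list(ortho_roles = role_sorted,
                    ortho_marked = marked, ortho_trackable = trackable,
                    ortho_state = state,
                    gdmr_target_maternal = length(mat_idx),
                    gdmr_target_bihypo = length(gi) - length(mat_idx)))
}

#' Write a simulated study to disk in the pipeline's exchange formats
#'
#' Methylomes as 4-column count TSVs, peaks as BED, genes and expression as
#' TSV, orthology as the paired-interval TSV. Useful for exercising the
#' readers and for inspecting a simulation externally.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ins <- sim$inputs
  fp <- function(...) file.path(dir, ...)
  for (nm in grep("^meth_", names(ins), value = TRUE))
    write_methylome(ins[[nm]], fp(paste0(nm, ".tsv")))
  for (nm in grep("peaks", names(ins), value = TRUE))
    write_peaks(ins[[nm]], fp(paste0(nm, ".bed")))
  write_genes(ins$genes, fp("genes.tsv"))
  if (!is.null(ins$expression))
    write_expression(ins$expression, fp("expression.tsv"))
  if (!is.null(ins$ortho)) write_orthology(ins$ortho, fp("orthology.tsv"))
  if (!is.null(ins$imprint_catalogue))
    writeLines(ins$imprint_catalogue, fp("imprint_catalogue.txt"))
  if (!is.null(ins$known_dmrs))
    write_peaks(ins$known_dmrs, fp("known_dmrs.bed"))
  invisible(dir)
}

#' Pool methylome replicates by count summation
#'
#' Replicate methylomes of the same sample type are pooled CpG-wise by
#' summing methylated and total counts, maximising CpG coverage in
#' low-input data.
#'
#' @param meth_list list of [methylome()]s with identical stage/parentage.
#' @param genome a [genome_decl()].
#' @return a pooled `methylome`.
#' @export
pool_methylomes <- function(meth_list, genome) {
  stopifnot(length(meth_list) >= 1)
  df <- do.call(rbind, lapply(meth_list, function(m)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(m$cpgs)),
               pos = GenomicRanges::start(m$cpgs),
               methylated = m$cpgs$methylated, total = m$cpgs$total)))
  agg <- stats::aggregate(cbind(methylated, total) ~ chrom + pos, df, sum)
  methylome(agg$chrom, agg$pos, agg$methylated, agg$total, genome,
            sample_id = paste0(meth_list[[1]]$sample_id, "_pooled"),
            stage = meth_list[[1]]$stage,
            parentage = meth_list[[1]]$parentage)
}
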