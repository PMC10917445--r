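#' Construct a methylome from per-CpG counts
#'
#' A methylome is the substrate of all methylation arithmetic: one row per
#' CpG (keyed by the + strand C position) carrying a methylated read count
#' and a total read count. Counts are assumed strand-merged upstream.
#'
#' @param chrom,pos chromosome and 1-based C position of each CpG.
#' @param methylated,total per-CpG read counts, `methylated <= total`,
#'   `total >= 1`.
#' @param genome a [genome_decl()].
#' @param sample_id sample label.
#' @param stage one of sperm, oocyte, 8cell, morula, blastocyst, placenta,
#'   embryo6w.
#' @param parentage one of AG, PG, maternal_gamete, paternal_gamete,
#'   biparental.
#' @return an object of class `methylome`.
#' @export
methylome <- function(chrom, pos, methylated, total, genome,
                      sample_id = "sample",
                      stage = c("sperm", "oocyte", "8cell", "morula",
                                "blastocyst", "placenta", "embryo6w"),
                      parentage = c("AG", "PG", "maternal_gamete",
                                    "paternal_gamete", "biparental")) {
  stage <- match.arg(stage)
  parentage <- match.arg(parentage)
  methylated <- as.integer(methylated)
  total <- as.integer(total)
  if (any(total < 1)) stop("total count must be >= 1 at every CpG")
  if (any(methylated < 0)) stop("methylated count must be non-negative")
  if (any(methylated > total)) {
    i <- which(methylated > total)[1]
    stop("methylated > total at record ", i, " (", chrom[i], ":", pos[i], ")")
  }
  gr <- as_regions(chrom, pos, pos, genome,
                   methylated = methylated, total = total)
  key <- paste(GenomeInfoDb::seqnames(gr), GenomicRanges::start(gr))
  if (anyDuplicated(key))
    stop("duplicate CpG position: ", key[which(duplicated(key))[1]])
  structure(list(sample_id = sample_id, stage = stage,
                 parentage = parentage, cpgs = gr),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat("Methylome", x$sample_id, "(", x$stage, ",", x$parentage, "):",
      length(x$cpgs), "CpGs on",
      length(unique(GenomeInfoDb::seqnames(x$cpgs))), "chromosome(s)\n")
  invisible(x)
}

#' Read a methylome from a 4-column counts file
#'
#' Expected format: tab-separated `chrom  pos  methylated  total`, no header.
#' `dialect` declares the position convention: `"counts1"` for 1-based C
#' positions, `"bed"` for 0-based (converted on read). Malformed lines and
#' invariant violations are hard errors naming the offending line; records
#' are never silently dropped.
#'
#' @param path file path.
#' @param genome a [genome_decl()].
#' @param dialect position convention of column 2.
#' @inheritParams methylome
#' @return a `methylome`.
#' @export
read_methylome <- function(path, genome, sample_id = basename(path),
                           stage = "blastocyst", parentage = "PG",
                           dialect = c("counts1", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(methylome(character(), integer(), integer(), integer(), genome,
                     sample_id = sample_id, stage = stage,
                     parentage = parentage))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("malformed methylome line ", which(nf != 4)[1], " in ", path,
         ": expected 4 tab-separated columns")
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 3]))
  tot <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(tot))
  if (length(bad))
    stop("malformed methylome line ", bad[1], " in ", path,
         ": non-numeric field")
  if (dialect == "bed") pos <- pos + 1L
  bad <- which(meth > tot)
  if (length(bad))
    stop("validation error at line ", bad[1], " in ", path,
         ": methylated > total")
  mm <- methylome(m[, 1], pos, meth, tot, genome, sample_id = sample_id,
                  stage = stage, parentage = parentage)
  if (length(mm$cpgs) != length(lines))
    stop("record count mismatch reading ", path)  # duplicate guard upstream
  mm
}

#' Write a methylome as a 4-column counts file (1-based positions)
#' @param x a `methylome`.
#' @param path output path.
#' @export
write_methylome <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x$cpgs)),
                   pos = GenomicRanges::start(x$cpgs),
                   methylated = x$cpgs$methylated,
                   total = x$cpgs$total)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peak calls (BED3/BED6)
#'
#' BED coordinates are 0-based half-open on disk and converted to the
#' in-memory 1-based closed convention. Unknown chromosomes and
#' `start >= end` are hard errors.
#'
#' @param path BED file.
#' @param genome a [genome_decl()].
#' @return a `GRanges`; BED6 name/score/strand are kept as metadata.
#' @export
read_peaks <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges(seqinfo = seqinfo_from_genome(genome)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path)
  chrom <- vapply(fields, `[`, "", 1)
  start0 <- as.integer(vapply(fields, `[`, "", 2))
  end0 <- as.integer(vapply(fields, `[`, "", 3))
  if (any(is.na(start0) | is.na(end0)))
    stop("non-numeric BED coordinate in ", path)
  if (any(start0 >= end0))
    stop("validation error in ", path, ": start >= end at line ",
         which(start0 >= end0)[1])
  gr <- as_regions(chrom, start0 + 1L, end0, genome)
  if (all(nf >= 4)) {
    o <- order(factor(chrom, levels = names(genome)), start0)
    gr$name <- vapply(fields, `[`, "", 4)[o]
  }
  gr
}

#' Write intervals as BED (canonical: BED3, or BED6 when a name column exists)
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_peaks <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) {
    df$name <- gr$name
    df$score <- 0L
    df$strand <- "."
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a 6-column TSV
#'
#' Columns: gene_id, chrom, strand, tx_start (0-based), tx_end (exclusive),
#' biotype. The TSS is derived from strand: tx_start for `+` genes, the last
#' base for `-` genes.
#'
#' @param path TSV file, no header.
#' @param genome a [genome_decl()].
#' @return a data.frame of class `gene_table` with 1-based start/end and a
#'   `tss` column.
#' @export
read_genes <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "strand",
                                        "start0", "end0", "biotype"),
                          colClasses = c("character", "character",
                                         "character", "integer", "integer",
                                         "character"))
  if (any(df$start0 >= df$end0))
    stop("validation error in ", path, ": tx_start >= tx_end")
  gene_table(df$gene_id, df$chrom, df$strand, df$start0 + 1L, df$end0,
             df$biotype, genome = genome)
}

#' Construct a gene table
#' @param gene_id,chrom,strand,start,end,biotype per-gene fields (1-based,
#'   closed coordinates).
#' @param genome a [genome_decl()].
#' @export
gene_table <- function(gene_id, chrom, strand, start, end,
                       biotype = "protein_coding", genome) {
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")))
  invisible(as_regions(chrom, start, end, genome))  # coordinate validation
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   biotype = rep_len(biotype, length(gene_id)),
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' @export
write_genes <- function(x, path) {
  utils::write.table(
    data.frame(x$gene_id, x$chrom, x$strand, x$start - 1L, x$end, x$biotype),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genes_gr <- function(genes, genome) {
  as_regions(genes$chrom, genes$start, genes$end, genome,
             gene_id = genes$gene_id)
}

#' Read an expression matrix (RPKM)
#'
#' Header row: sample ids formatted `<parentage>_R<replicate>` (e.g.
#' `AG_R1`); first column: gene ids; remaining cells: non-negative RPKM.
#'
#' @param path TSV file with header.
#' @return an `expression_table`: list(genes, samples, values).
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  expression_table(genes, colnames(values), values)
}

#' Construct an expression table
#' @param genes gene ids (rows).
#' @param sample_ids column labels `<parentage>_R<replicate>`.
#' @param values genes x samples matrix of RPKM.
#' @export
expression_table <- function(genes, sample_ids, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(genes),
            ncol(values) == length(sample_ids))
  if (any(values < 0)) stop("RPKM values must be non-negative")
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
  parentage <- sub("_R[0-9]+$", "", sample_ids)
  if (!all(parentage %in% c("AG", "PG")))
    stop("sample ids must look like AG_R1 / PG_R2")
  dimnames(values) <- list(genes, sample_ids)
  structure(list(genes = genes,
                 samples = data.frame(sample_id = sample_ids,
                                      parentage = parentage,
                                      replicate = as.integer(
                                        sub("^.*_R", "", sample_ids))),
                 values = values),
            class = "expression_table")
}

#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = x$genes, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", length(x$genes), "genes x",
      nrow(x$samples), "samples\n")
  invisible(x)
}

#' Read an interval orthology map
#'
#' 8-column TSV: source chrom/start0/end0, target chrom/start0/end0 plus two
#' trailing columns (pair id, target strand) which are tolerated but
#' ignored; a 6-column file is accepted too. Each source interval maps to
#' exactly one target and sources must not overlap one another.
#'
#' @param path TSV file.
#' @param source_genome,target_genome [genome_decl()]s for the two species.
#' @return an `orthology_map`: list(source, target) of parallel `GRanges`.
#' @export
read_orthology <- function(path, source_genome, target_genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  if (!ncol(df) %in% c(6, 8))
    stop("orthology file must have 6 or 8 columns")
  orthology_map(
    source = as_regions(df[[1]], df[[2]] + 1L, df[[3]], source_genome,
                        pair = seq_len(nrow(df))),
    target_chrom = df[[4]], target_start = df[[5]] + 1L,
    target_end = df[[6]], target_genome = target_genome)
}

#' Construct an orthology map
#' @param source `GRanges` in the source genome with a `pair` index column.
#' @param target_chrom,target_start,target_end parallel target coordinates
#'   (1-based closed), ordered by `source$pair`.
#' @param target_genome target [genome_decl()].
#' @export
orthology_map <- function(source, target_chrom, target_start, target_end,
                          target_genome) {
  if (any(target_end > target_genome[as.character(target_chrom)]) ||
      any(target_start < 1))
    stop("orthology target outside declared target genome")
  # as_regions() sorted the source; $pair carries the original row order,
  # so index the target columns through it to keep the two sides parallel
  tgt <- GenomicRanges::GRanges(
    as.character(target_chrom)[source$pair],
    IRanges::IRanges(target_start[source$pair], target_end[source$pair]),
    seqinfo = seqinfo_from_genome(target_genome))
  if (sum(GenomicRanges::width(GenomicRanges::reduce(source))) <
      sum(GenomicRanges::width(source)))
    stop("orthology source intervals overlap")
  structure(list(source = source, target = tgt), class = "orthology_map")
}

#' @export
write_orthology <- function(x, path) {
  utils::write.table(
    data.frame(as.character(GenomeInfoDb::seqnames(x$source)),
               GenomicRanges::start(x$source) - 1L,
               GenomicRanges::end(x$source),
               as.character(GenomeInfoDb::seqnames(x$target)),
               GenomicRanges::start(x$target) - 1L,
               GenomicRanges::end(x$target),
               seq_along(x$source), "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("Orthology map:", length(x$source), "interval pairs\n")
  invisible(x)
}
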