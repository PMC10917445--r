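#' Declare a genome as an ordered set of chromosome lengths
#'
#' A genome declaration pins down which chromosomes exist and how long they
#' are. Every interval entering the pipeline is validated against it, so a
#' coordinate from the wrong assembly (the classic cross-species mix-up)
#' fails loudly instead of silently overlapping nothing.
#'
#' @param lengths named numeric vector, chromosome name -> length in bp.
#' @return a named integer vector of class `genome_decl`.
#' @examples
#' gd <- genome_decl(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_decl <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names in genome declaration")
  if (any(lengths <= 0) || any(!is.finite(lengths)))
    stop("chromosome lengths must be positive and finite")
  structure(stats::setNames(as.integer(lengths), names(lengths)),
            class = "genome_decl")
}

#' @export
print.genome_decl <- function(x, ...) {
  cat("Genome declaration:", length(x), "chromosome(s),",
      format(sum(as.numeric(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

seqinfo_from_genome <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

#' Build a GRanges validated against a genome declaration
#'
#' Internal constructor used by the readers and the simulator. Coordinates
#' are 1-based closed (GRanges convention); converters at the file boundary
#' handle BED-style 0-based input.
#'
#' @param chrom,start,end vectors defining the intervals (1-based, closed).
#' @param genome a [genome_decl()].
#' @param ... further metadata columns.
#' @keywords internal
as_regions <- function(chrom, start, end, genome, ...) {
  chrom <- as.character(chrom)
  bad <- !(chrom %in% names(genome))
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(start < 1) || any(end < start))
    stop("invalid interval coordinates (need 1 <= start <= end)")
  if (any(end > genome[chrom]))
    stop("interval end exceeds declared chromosome length")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...,
                               seqinfo = seqinfo_from_genome(genome))
  GenomicRanges::sort(gr)
}

#' Tile a genome into fixed-width bins
#'
#' Partitions each chromosome into consecutive `bin_size`-bp bins; the last
#' bin of each chromosome is truncated at the chromosome end. The bins are
#' the unit of binned-signal quantification and of bin-level methylation and
#' group-partition analyses.
#'
#' @param genome a [genome_decl()].
#' @param bin_size bin width in bp (> 0).
#' @return a `GRanges` of bins covering the genome exactly, without overlap.
#' @examples
#' bin_genome(genome_decl(c(chr1 = 10)), 4)  # [1,4] [5,8] [9,10]
#' @export
bin_genome <- function(genome, bin_size) {
  stopifnot(inherits(genome, "genome_decl"), bin_size > 0)
  si <- seqinfo_from_genome(genome)
  bins <- GenomicRanges::tileGenome(si, tilewidth = as.integer(bin_size),
                                    cut.last.tile.in.chrom = TRUE)
  bins
}

# mean interval width helper used in reports
.total_bp <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))
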