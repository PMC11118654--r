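#' Build a reference-genome context
#'
#' Bundles reference sequences with an optional stranded gene annotation for
#' use by the context classifiers.
#'
#' @param sequences A named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param genes A `GRanges` of transcribed intervals with strand, or `NULL`
#'   for no annotation (all loci intergenic). Interval names (or a `gene_id`
#'   metadata column) are used for deterministic tie-breaking when genes on
#'   both strands overlap a locus.
#' @return A [GenomeContext].
#' @examples
#' gc <- genomeContext(c(chr1 = "ACGTACGTAC"))
#' genomeFlank(gc, "chr1", 5, 1)
#' @export
genomeContext <- function(sequences, genes = NULL) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by chromosome")
  if (!is.null(genes) && !is(genes, "GRanges"))
    stop("genes must be a GRanges or NULL")
  new("GenomeContext", sequences = sequences, genes = genes)
}

.checkLocus <- function(genome, chrom, pos, width = 1L) {
  if (!chrom %in% names(genome@sequences))
    stop("chromosome '", chrom, "' not in genome context")
  len <- length(genome@sequences[[chrom]])
  if (pos < 1 || pos + width - 1 > len)
    stop("position ", pos, " (width ", width, ") outside sequence '",
         chrom, "' of length ", len)
  invisible(len)
}

#' @rdname genomeContext
#' @param genome A [GenomeContext].
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @export
genomeBase <- function(genome, chrom, pos) {
  .checkLocus(genome, chrom, pos)
  as.character(Biostrings::subseq(genome@sequences[[chrom]], pos, pos))
}

#' @rdname genomeContext
#' @param k Number of flanking bases on each side.
#' @export
genomeFlank <- function(genome, chrom, pos, k = 1L) {
  .checkLocus(genome, chrom, pos)
  len <- length(genome@sequences[[chrom]])
  if (pos - k < 1 || pos + k > len)
    stop("flank of width ", k, " around position ", pos,
         " extends outside sequence '", chrom, "'")
  as.character(Biostrings::subseq(genome@sequences[[chrom]], pos - k, pos + k))
}

## substring of a chromosome, clipped to the sequence bounds; may be shorter
## than requested near contig ends
.genomeSlice <- function(genome, chrom, start, end) {
  len <- length(genome@sequences[[chrom]])
  start <- max(1L, start)
  end <- min(len, end)
  if (start > end) return("")
  as.character(Biostrings::subseq(genome@sequences[[chrom]], start, end))
}

#' Transcribed-strand call at a locus
#'
#' Returns `"plus"` or `"minus"` for loci overlapped by annotated genes and
#' `"none"` for intergenic loci. When genes on both strands overlap the locus
#' the strand of the longest overlapping interval wins, with a lexicographic
#' tie-break on the gene identifier, so the call is deterministic.
#'
#' @inheritParams genomeBase
#' @return One of `"plus"`, `"minus"`, `"none"`.
#' @export
transcribedStrand <- function(genome, chrom, pos) {
  .checkLocus(genome, chrom, pos)
  genes <- genome@genes
  if (is.null(genes) || length(genes) == 0L) return("none")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
  if (length(hits) == 0L) return("none")
  idx <- S4Vectors::subjectHits(hits)
  str <- as.character(GenomicRanges::strand(genes)[idx])
  str[str == "*"] <- "+"
  if (length(unique(str)) > 1L) {
    w <- GenomicRanges::width(genes)[idx]
    ids <- names(genes)[idx]
    if (is.null(ids)) ids <- as.character(idx)
    ord <- order(-w, ids)
    str <- str[ord[1]]
  } else {
    str <- str[1]
  }
  if (str == "+") "plus" else "minus"
}
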