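## Per-event context classifiers. Each classifier is total and deterministic:
## a valid event maps to exactly one category of its schema; invalid or
## ambiguous events raise an error (buildCatalog converts these into logged
## unclassified counts).

#' Classify a single base substitution into its trinucleotide context
#'
#' Maps an SBS to one of the 96 pyrimidine-centered categories
#' `X[C>*]Y` / `X[T>*]Y`. Purine-reference mutations are normalized by reverse
#' complementing the flanks and alleles. With `stranded = TRUE` the label is
#' prefixed `T:` (pyrimidine on the transcribed/template strand), `U:`
#' (untranscribed strand) or `N:` (intergenic), giving the 288-category system.
#'
#' @param genome A [GenomeContext] covering the locus.
#' @param chrom,pos Chromosome and 1-based position of the substituted base.
#' @param ref,alt Single-base reference and alternate alleles.
#' @param stranded Add the transcriptional-strand prefix.
#' @return A category label.
#' @export
classifySBS <- function(genome, chrom, pos, ref, alt, stranded = FALSE) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
    stop("not a single base substitution: ", ref, ">", alt)
  obs <- genomeBase(genome, chrom, pos)
  if (obs != ref)
    stop("reference base mismatch at ", chrom, ":", pos,
         " (genome ", obs, ", record ", ref, ")")
  tri <- genomeFlank(genome, chrom, pos, 1L)
  if (grepl("N", tri, fixed = TRUE) || alt == "N")
    stop("ambiguous base in context at ", chrom, ":", pos)
  five <- substr(tri, 1, 1)
  three <- substr(tri, 3, 3)
  if (ref %in% .PYRIMIDINES) {
    lab <- paste0(five, "[", ref, ">", alt, "]", three)
    pyrStrand <- "+"
  } else {
    lab <- paste0(.complement(three), "[", .complement(ref), ">",
                  .complement(alt), "]", .complement(five))
    pyrStrand <- "-"
  }
  if (!stranded) return(lab)
  ts <- transcribedStrand(genome, chrom, pos)
  prefix <- if (ts == "none") {
    "N"
  } else {
    geneStrand <- if (ts == "plus") "+" else "-"
    ## template strand is the opposite of the gene (coding) strand: the
    ## pyrimidine sits on the template iff its strand differs from the gene's
    if (pyrStrand != geneStrand) "T" else "U"
  }
  paste0(prefix, ":", lab)
}

#' Classify a doublet base substitution
#'
#' Maps a doublet (both bases substituted) to one of the 78 canonical doublet
#' categories; non-canonical reference doublets are reverse complemented.
#'
#' @inheritParams classifySBS
#' @param ref,alt Two-base reference and alternate alleles.
#' @export
classifyDBS <- function(genome, chrom, pos, ref, alt) {
  if (nchar(ref) != 2L || nchar(alt) != 2L)
    stop("not a doublet substitution: ", ref, ">", alt)
  if (substr(ref, 1, 1) == substr(alt, 1, 1) ||
      substr(ref, 2, 2) == substr(alt, 2, 2))
    stop("doublet must substitute both bases: ", ref, ">", alt)
  .checkLocus(genome, chrom, pos, 2L)
  obs <- .genomeSlice(genome, chrom, pos, pos + 1L)
  if (obs != ref)
    stop("reference doublet mismatch at ", chrom, ":", pos,
         " (genome ", obs, ", record ", ref, ")")
  if (grepl("N", paste0(ref, alt), fixed = TRUE))
    stop("ambiguous base in doublet at ", chrom, ":", pos)
  if (is.null(.DBS_LOOKUP)) {
    utils::assignInMyNamespace(".DBS_LOOKUP", .dbsLookup())
  }
  .DBS_LOOKUP[[paste0(ref, alt)]]
}

## longest run of whole-unit copies of `unit` at the start of `seqs`
.unitCopies <- function(seqs, unit, cap = 6L) {
  L <- nchar(unit)
  n <- 0L
  while (n < cap &&
         substr(seqs, n * L + 1L, (n + 1L) * L) == unit &&
         nchar(seqs) >= (n + 1L) * L) {
    n <- n + 1L
  }
  n
}

## junction homology between a deleted sequence and its flanks: longest
## end-overlap between the deleted sequence and the sequence adjacent to the
## deletion junction, evaluated on both flanks
.microhomology <- function(deleted, up, down) {
  L <- nchar(deleted)
  for (k in seq(L - 1L, 1L)) {
    pre <- substr(deleted, 1L, k)
    suf <- substr(deleted, L - k + 1L, L)
    if (nchar(down) >= k && substr(down, 1L, k) == pre) return(k)
    if (nchar(down) >= k && substr(down, 1L, k) == suf) return(k)
    if (nchar(up) >= k && substr(up, nchar(up) - k + 1L, nchar(up)) == suf)
      return(k)
  }
  0L
}

#' Classify a small insertion or deletion
#'
#' Maps a left-aligned, trimmed indel in VCF anchor-base convention to one of
#' the 83 indel categories: 1-bp events by base (pyrimidine-normalized to C/T)
#' and homopolymer context, longer events by length bin and tandem-repeat
#' context, and non-repetitive deletions with junction homology by length and
#' homology-length bins. The final label field counts additional copies of the
#' event unit adjacent in the reference (or the homology length for `M`
#' categories), capped following the COSMIC convention.
#'
#' @inheritParams classifySBS
#' @param ref,alt Alleles with the shared VCF anchor base
#'   (`|ref| != |alt|`, one of them length 1 after trimming).
#' @export
classifyIndel <- function(genome, chrom, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) stop("not an indel: ", ref, ">", alt)
  if (min(nr, na) != 1L)
    stop("indel not trimmed to anchor-base convention: ", ref, ">", alt)
  if (substr(ref, 1, 1) != substr(alt, 1, 1))
    stop("indel anchor bases disagree: ", ref, ">", alt)
  .checkLocus(genome, chrom, pos, nr)
  obs <- .genomeSlice(genome, chrom, pos, pos + nr - 1L)
  if (obs != ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome ", obs, ", record ", ref, ")")
  if (grepl("N", paste0(ref, alt), fixed = TRUE))
    stop("ambiguous base in indel at ", chrom, ":", pos)

  if (nr > na) {                       # deletion
    deleted <- substr(ref, 2L, nr)
    L <- nchar(deleted)
    anchor <- substr(ref, 1L, 1L)
    if (anchor == substr(deleted, L, L))
      stop("deletion not left-aligned at ", chrom, ":", pos)
    down <- .genomeSlice(genome, chrom, pos + nr, pos + nr + 6L * L)
    if (L == 1L) {
      b <- if (deleted %in% .PYRIMIDINES) deleted else .complement(deleted)
      run <- 1L + .unitCopies(down, deleted, cap = 6L)
      return(paste0("1:Del:", b, ":", min(run - 1L, 5L)))
    }
    Lr <- min(L, 5L)
    copies <- .unitCopies(down, deleted, cap = 6L)
    if (copies >= 1L)
      return(paste0(Lr, ":Del:R:", min(copies, 5L)))
    up <- .genomeSlice(genome, chrom, pos - L + 1L, pos)
    mh <- .microhomology(deleted, up, substr(down, 1L, L - 1L))
    if (mh >= 1L) {
      cap <- if (Lr == 5L) 5L else Lr - 1L
      return(paste0(Lr, ":Del:M:", min(mh, cap)))
    }
    return(paste0(Lr, ":Del:R:0"))
  }

  ## insertion
  inserted <- substr(alt, 2L, na)
  L <- nchar(inserted)
  anchor <- substr(alt, 1L, 1L)
  if (anchor == substr(inserted, L, L))
    stop("insertion not left-aligned at ", chrom, ":", pos)
  down <- .genomeSlice(genome, chrom, pos + 1L, pos + 6L * L)
  if (L == 1L) {
    b <- if (inserted %in% .PYRIMIDINES) inserted else .complement(inserted)
    run <- .unitCopies(down, inserted, cap = 6L)
    return(paste0("1:Ins:", b, ":", min(run, 5L)))
  }
  Lr <- min(L, 5L)
  copies <- .unitCopies(down, inserted, cap = 6L)
  paste0(Lr, ":Ins:R:", min(copies, 5L))
}

#' Classify a copy-number segment
#'
#' Assigns the allele state (homozygous deletion, LOH, heterozygous), a
#' total-copy-number bin and a segment-length bin per the schema configuration.
#'
#' @param totalCn,minorCn Integer total and minor-allele copy numbers.
#' @param length Segment length in bp (`end - start + 1`).
#' @param schema A copy-number [ContextSchema] from [schemaCN()].
#' @export
classifyCN <- function(totalCn, minorCn, length, schema = schemaCN()) {
  if (schema@schemaId != "CN_CONFIG") stop("schema is not a copy-number schema")
  if (length <= 0) stop("segment length must be positive")
  if (minorCn < 0 || totalCn < 0) stop("copy numbers must be nonnegative")
  if (totalCn < minorCn) stop("total_cn < minor_cn")
  if (totalCn > 0 && minorCn > totalCn - minorCn)
    stop("minor allele exceeds major allele (minor_cn > total_cn - minor_cn)")
  p <- schema@parameters
  if (totalCn == 0) {
    bin <- findInterval(length, p$homdelLengthBreaks, left.open = TRUE) + 1L
    return(paste0("0:homdel:", p$homdelLengthLabels[bin]))
  }
  state <- if (minorCn == 0) "LOH" else "het"
  tcnBins <- .CN_TCN_BINS[[state]]
  tcnLab <- tcnBins$labels[findInterval(totalCn, tcnBins$upper + 0.5) + 1L]
  bin <- findInterval(length, p$lengthBreaks, left.open = TRUE) + 1L
  paste0(tcnLab, ":", state, ":", p$lengthLabels[bin])
}

#' Classify a structural variant event
#'
#' Assigns clustered status, event type and (for intrachromosomal events) a
#' size bin; translocations carry no size bin.
#'
#' @param svType One of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @param size Event size in bp (ignored for `"TRA"`).
#' @param clustered Logical clustered-event flag (consumed as input, not
#'   computed).
#' @param schema A structural-variant [ContextSchema] from [schemaSV()].
#' @export
classifySV <- function(svType, size = NA, clustered = FALSE,
                       schema = schemaSV()) {
  if (schema@schemaId != "SV_CONFIG") stop("schema is not an SV schema")
  svType <- toupper(svType)
  if (!svType %in% c("DEL", "DUP", "INV", "TRA"))
    stop("unknown SV type: ", svType)
  cl <- if (isTRUE(clustered)) "clustered" else "non-clustered"
  if (svType == "TRA") return(paste0(cl, ":tra"))
  if (is.na(size) || size <= 0)
    stop("non-translocation SV requires a positive size")
  p <- schema@parameters
  ## right-open bins: a size exactly at a break falls in the higher bin, so
  ## the first bin holds events strictly below the sub-kilobase boundary
  bin <- findInterval(size, p$sizeBreaks) + 1L
  paste(cl, tolower(svType), p$sizeLabels[bin], sep = ":")
}
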