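.emptyCatalog <- function(schema) {
  m <- matrix(0, nrow = length(schema@categories), ncol = 0,
              dimnames = list(schema@categories, NULL))
  new("MutationCatalog", counts = m, schema = schema, unclassified = numeric(0))
}

#' Assemble a per-sample catalog from classified events
#'
#' Classifies every record under the schema and tallies counts into a
#' categories-by-samples matrix. Column order follows the first appearance of
#' each sample in the input. Events that fail classification are counted per
#' sample in the catalog's `unclassified` slot and reported with a message.
#'
#' The expected columns of `records` depend on the schema:
#' \describe{
#'   \item{SBS96/SBS288/DBS78/ID83}{`sample`, `chrom`, `pos`, `ref`, `alt`
#'     (VCF-style, 1-based, left-aligned and trimmed indels); requires
#'     `genome`.}
#'   \item{CN}{`sample`, `chrom`, `start`, `end`, `total_cn`, `minor_cn`.}
#'   \item{SV}{`sample`, `sv_type`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'     `clustered`, and optionally `size` (computed from breakpoints for
#'     intrachromosomal events when absent).}
#' }
#'
#' @param records Data frame of events (see Details).
#' @param schema Target [ContextSchema].
#' @param genome A [GenomeContext]; required for sequence-context schemas.
#' @return A [MutationCatalog] whose column sums equal the per-sample counts of
#'   classified events. An empty input yields a zero-sample catalog.
#' @export
buildCatalog <- function(records, schema, genome = NULL) {
  if (is.null(records) || nrow(records) == 0L) return(.emptyCatalog(schema))
  records$sample <- as.character(records$sample)
  samples <- unique(records$sample)
  counts <- matrix(0, nrow = length(schema@categories), ncol = length(samples),
                   dimnames = list(schema@categories, samples))
  unclassified <- setNames(numeric(length(samples)), samples)

  labelOf <- switch(schema@schemaId,
    SBS96 = , SBS288 = , DBS78 = , ID83 = {
      if (is.null(genome))
        stop("a GenomeContext is required for schema ", schema@schemaId)
      function(r) .classifyMutationRow(r, schema, genome)
    },
    CN_CONFIG = function(r)
      classifyCN(r$total_cn, r$minor_cn, r$end - r$start + 1, schema),
    SV_CONFIG = function(r) {
      size <- if (!is.null(r$size) && !is.na(r$size)) r$size
        else if (r$chrom1 == r$chrom2) abs(r$pos2 - r$pos1) else NA
      classifySV(r$sv_type, size, isTRUE(r$clustered) || r$clustered == 1,
                 schema)
    },
    stop("unsupported schema: ", schema@schemaId))

  failures <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    lab <- tryCatch(labelOf(r), error = function(e) conditionMessage(e))
    if (lab %in% schema@categories) {
      counts[lab, r$sample] <- counts[lab, r$sample] + 1
    } else {
      unclassified[[r$sample]] <- unclassified[[r$sample]] + 1
      failures <- c(failures, lab)
    }
  }
  if (length(failures))
    message(length(failures), " event(s) could not be classified (e.g. ",
            failures[1], ")")
  new("MutationCatalog", counts = counts, schema = schema,
      unclassified = unclassified)
}

.classifyMutationRow <- function(r, schema, genome) {
  nr <- nchar(r$ref); na <- nchar(r$alt)
  vclass <- if (nr == 1L && na == 1L) "SBS"
    else if (nr == 2L && na == 2L) "DBS"
    else "ID"
  wanted <- switch(schema@schemaId, SBS96 = "SBS", SBS288 = "SBS",
                   DBS78 = "DBS", ID83 = "ID")
  if (vclass != wanted)
    stop("record is ", vclass, " but schema expects ", wanted)
  switch(vclass,
         SBS = classifySBS(genome, r$chrom, r$pos, r$ref, r$alt,
                           stranded = schema@schemaId == "SBS288"),
         DBS = classifyDBS(genome, r$chrom, r$pos, r$ref, r$alt),
         ID = classifyIndel(genome, r$chrom, r$pos, r$ref, r$alt))
}

#' Collapse a stranded substitution catalog onto the 96-category system
#'
#' Sums the transcribed, untranscribed and intergenic counts of each
#' trinucleotide category; per-sample totals are conserved.
#'
#' @param catalog A [MutationCatalog] under the SBS288 schema.
#' @return A [MutationCatalog] under the SBS96 schema.
#' @export
collapseStrand <- function(catalog) {
  if (catalog@schema@schemaId != "SBS288")
    stop("collapseStrand expects an SBS288 catalog")
  s96 <- schemaSBS96()
  base <- sub("^[TUN]:", "", rownames(catalog@counts))
  counts <- rowsum(catalog@counts, group = base)
  counts <- counts[s96@categories, , drop = FALSE]
  new("MutationCatalog", counts = counts, schema = s96,
      unclassified = catalog@unclassified)
}

#' Fraction of the covered genome with aberrant copy number
#'
#' Computes the fraction of the segment-covered genome lying in segments whose
#' allele-specific state differs from the diploid heterozygous state
#' `(total_cn, minor_cn) = (2, 1)`. The denominator is the genome covered by
#' segments, so the statistic does not depend on uncalled regions.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn` (1-based inclusive coordinates, non-overlapping per
#'   chromosome).
#' @param genomeLengths Optional named vector of chromosome lengths used to
#'   validate segment bounds.
#' @return A fraction in `[0, 1]`.
#' @export
genomeAberrationFraction <- function(segments, genomeLengths = NULL) {
  if (nrow(segments) == 0L) return(0)
  if (any(segments$start > segments$end))
    stop("segment start exceeds end")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", ch)
    if (!is.null(genomeLengths)) {
      if (!ch %in% names(genomeLengths))
        stop("chromosome ", ch, " missing from genomeLengths")
      if (any(s$end > genomeLengths[[ch]]))
        stop("segment beyond length of ", ch)
    }
  }
  width <- segments$end - segments$start + 1
  aberrant <- !(segments$total_cn == 2 & segments$minor_cn == 1)
  sum(width[aberrant]) / sum(width)
}
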