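#' @import methods
#' @importFrom stats median sd quantile rnorm rpois rlnorm rbinom runif rmultinom
#'   glm lm binomial coef vcov pnorm qnorm p.adjust fisher.test wilcox.test
#'   rgamma complete.cases setNames as.formula predict as.dist model.matrix
#' @importFrom utils head read.delim write.table combn assignInMyNamespace
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Context schema: an ordered set of mutation-context categories
#'
#' A `ContextSchema` names the classification space used for a variant class:
#' the 96 or 288 trinucleotide substitution categories, the 78 doublet
#' categories, the 83 indel categories, or configurable copy-number and
#' structural-variant bin systems.
#'
#' @slot schemaId One of `"SBS96"`, `"SBS288"`, `"DBS78"`, `"ID83"`,
#'   `"CN_CONFIG"`, `"SV_CONFIG"`.
#' @slot categories Ordered character vector of unique category labels.
#' @slot parameters Schema-specific bin boundaries (copy-number and
#'   structural-variant schemas only).
#' @export
setClass("ContextSchema",
         representation(schemaId = "character",
                        categories = "character",
                        parameters = "list"))

setValidity("ContextSchema", function(object) {
  fixed <- c(SBS96 = 96L, SBS288 = 288L, DBS78 = 78L, ID83 = 83L)
  msg <- character(0)
  if (length(object@schemaId) != 1L)
    msg <- c(msg, "schemaId must be a single string")
  if (anyDuplicated(object@categories))
    msg <- c(msg, "category labels must be unique")
  if (object@schemaId %in% names(fixed) &&
      length(object@categories) != fixed[[object@schemaId]])
    msg <- c(msg, sprintf("schema %s must have %d categories",
                          object@schemaId, fixed[[object@schemaId]]))
  if (length(msg)) msg else TRUE
})

#' Catalog of classified somatic events
#'
#' Categories-by-samples matrix of event counts under a [ContextSchema].
#' Counts are nonnegative integers for raw catalogs and may be real-valued
#' after hypermutator normalization.
#'
#' @slot counts Nonnegative matrix, categories x samples.
#' @slot schema The [ContextSchema] the rows follow.
#' @slot unclassified Per-sample count of events that could not be classified.
#' @export
setClass("MutationCatalog",
         representation(counts = "matrix",
                        schema = "ContextSchema",
                        unclassified = "numeric"))

setValidity("MutationCatalog", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@counts), object@schema@categories))
    msg <- c(msg, "row names must equal the schema categories, in order")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (ncol(object@counts) > 0 && is.null(colnames(object@counts)))
    msg <- c(msg, "columns must carry sample identifiers")
  if (length(object@unclassified) != ncol(object@counts))
    msg <- c(msg, "unclassified must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' Set of mutational-signature profiles with assignment-rule metadata
#'
#' Holds named signature profiles over a schema (each column a probability
#' distribution over categories) together with the cohort assignment rules:
#' globally excluded signatures, cross-variant-class rescue rules (a trigger
#' signature in another variant class admitting a candidate here), and the
#' set of signatures admitted for microsatellite-unstable samples.
#'
#' @slot schema The [ContextSchema] the profiles are defined over.
#' @slot profiles Nonnegative matrix, categories x signatures; columns sum to 1.
#' @slot exclusions Signature labels never offered as candidates unless rescued.
#' @slot rescueRules Named character vector: names are trigger signature labels
#'   (from another variant class), values the signature admitted here.
#' @slot msiSet Signature labels admitted when a sample is flagged as MSI.
#' @export
setClass("SignatureSet",
         representation(schema = "ContextSchema",
                        profiles = "matrix",
                        exclusions = "character",
                        rescueRules = "character",
                        msiSet = "character"))

setValidity("SignatureSet", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@profiles), object@schema@categories))
    msg <- c(msg, "profile rows must equal the schema categories, in order")
  if (any(object@profiles < 0))
    msg <- c(msg, "profiles must be nonnegative")
  if (ncol(object@profiles) > 0) {
    if (is.null(colnames(object@profiles)))
      msg <- c(msg, "profiles must carry signature names")
    cs <- colSums(object@profiles)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "profile columns must sum to 1 (tolerance 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Reference-genome context for variant classification
#'
#' Wraps the reference sequence and an optional stranded gene annotation,
#' answering base, flank and transcribed-strand queries at a locus.
#'
#' @slot sequences Named `DNAStringSet`, one entry per chromosome.
#' @slot genes `GRanges` of transcribed intervals (strand column used); may be
#'   empty, in which case every locus is treated as intergenic.
#' @export
setClass("GenomeContext",
         representation(sequences = "DNAStringSet",
                        genes = "GRangesOrNULL"))

#' De novo signature extraction result
#'
#' @slot signatures Consensus signature profiles (categories x k), columns
#'   summing to 1.
#' @slot activities Nonnegative activity matrix (k x samples) refit against the
#'   un-normalized catalog.
#' @slot selectedK The chosen number of signatures.
#' @slot stability Mean replicate-cluster silhouette per candidate k.
#' @slot error Reconstruction divergence per candidate k.
#' @slot reconstructionCosine Per-sample cosine similarity between the observed
#'   profile and its reconstruction at the selected k.
#' @slot config The extraction configuration used.
#' @export
setClass("SignatureExtraction",
         representation(signatures = "matrix",
                        activities = "matrix",
                        selectedK = "integer",
                        stability = "numeric",
                        error = "numeric",
                        reconstructionCosine = "numeric",
                        config = "list"))

#' Signature-injection power study result
#'
#' @slot detections Long table with one row per (level, replicate, sample):
#'   injected contribution and whether the target signature was detected.
#' @slot fractions One row per (level, replicate): fraction of samples in which
#'   the target was detected.
#' @slot levels The injection levels studied (fractions of total mutations).
#' @slot target The injected signature label.
#' @export
setClass("PowerResult",
         representation(detections = "data.frame",
                        fractions = "data.frame",
                        levels = "numeric",
                        target = "character"))

## ---- accessors -----------------------------------------------------------

#' @describeIn ContextSchema-accessors Category labels of a schema, catalog or
#'   signature set.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @name ContextSchema-accessors
#' @title Accessors for schemas, catalogs and signature sets
#' @param x A `ContextSchema`, `MutationCatalog` or `SignatureSet`.
NULL

#' @export
setMethod("categories", "ContextSchema", function(x) x@categories)
#' @export
setMethod("categories", "MutationCatalog", function(x) x@schema@categories)
#' @export
setMethod("categories", "SignatureSet", function(x) x@schema@categories)

#' @describeIn ContextSchema-accessors The schema of a catalog or signature set.
#' @export
setGeneric("contextSchema", function(x) standardGeneric("contextSchema"))
#' @export
setMethod("contextSchema", "MutationCatalog", function(x) x@schema)
#' @export
setMethod("contextSchema", "SignatureSet", function(x) x@schema)

#' @describeIn ContextSchema-accessors Count matrix of a catalog.
#' @export
setGeneric("catalogCounts", function(x) standardGeneric("catalogCounts"))
#' @export
setMethod("catalogCounts", "MutationCatalog", function(x) x@counts)

#' @describeIn ContextSchema-accessors Sample identifiers of a catalog.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "MutationCatalog", function(x) colnames(x@counts))

#' @describeIn ContextSchema-accessors Profile matrix of a signature set.
#' @export
setGeneric("signatureProfiles", function(x) standardGeneric("signatureProfiles"))
#' @export
setMethod("signatureProfiles", "SignatureSet", function(x) x@profiles)
#' @export
setMethod("signatureProfiles", "SignatureExtraction", function(x) x@signatures)

#' @describeIn ContextSchema-accessors Signature labels of a signature set.
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))
#' @export
setMethod("signatureNames", "SignatureSet", function(x) colnames(x@profiles))
#' @export
setMethod("signatureNames", "SignatureExtraction",
          function(x) colnames(x@signatures))

#' @describeIn ContextSchema-accessors Activity matrix of an extraction result.
#' @export
setGeneric("signatureActivities",
           function(x) standardGeneric("signatureActivities"))
#' @export
setMethod("signatureActivities", "SignatureExtraction", function(x) x@activities)

#' @describeIn ContextSchema-accessors Selected number of signatures.
#' @export
setGeneric("selectedRank", function(x) standardGeneric("selectedRank"))
#' @export
setMethod("selectedRank", "SignatureExtraction", function(x) x@selectedK)

## ---- show methods --------------------------------------------------------

setMethod("show", "ContextSchema", function(object) {
  cat("ContextSchema", object@schemaId, "with",
      length(object@categories), "categories\n")
})

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog:", length(object@schema@categories), "categories x",
      ncol(object@counts), "samples [", object@schema@schemaId, "]\n")
  if (ncol(object@counts)) {
    tot <- colSums(object@counts)
    cat("  events per sample: median", round(median(tot)),
        "range", round(min(tot)), "-", round(max(tot)), "\n")
  }
  if (sum(object@unclassified) > 0)
    cat("  unclassified events:", sum(object@unclassified), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", ncol(object@profiles), "signatures over",
      object@schema@schemaId, "\n")
  if (length(object@exclusions))
    cat("  excluded:", paste(object@exclusions, collapse = ", "), "\n")
  if (length(object@rescueRules))
    cat("  rescue rules:",
        paste(names(object@rescueRules), "->", object@rescueRules,
              collapse = "; "), "\n")
  if (length(object@msiSet))
    cat("  MSI set:", paste(object@msiSet, collapse = ", "), "\n")
})

setMethod("show", "GenomeContext", function(object) {
  cat("GenomeContext:", length(object@sequences), "sequences,",
      if (is.null(object@genes)) 0L else length(object@genes),
      "annotated gene intervals\n")
})

setMethod("show", "SignatureExtraction", function(object) {
  cat("SignatureExtraction: selected k =", object@selectedK, "\n")
  cat("  stability:", paste(sprintf("k=%s %.2f", names(object@stability),
                                    object@stability), collapse = ", "), "\n")
  cat("  median reconstruction cosine:",
      sprintf("%.4f", median(object@reconstructionCosine)), "\n")
})

setMethod("show", "PowerResult", function(object) {
  cat("PowerResult for", object@target, "at levels",
      paste(object@levels, collapse = ", "), "\n")
  agg <- tapply(object@fractions$fraction, object@fractions$level, mean)
  cat("  mean detection:",
      paste(sprintf("%s:%.2f", names(agg), agg), collapse = " "), "\n")
})
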