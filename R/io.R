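## Catalog and signature matrices are exchanged in the COSMIC text dialect:
## a MutationType column of category labels followed by one column per sample
## (or signature), tab separated.

#' Read and write catalogs and signature matrices (COSMIC text dialect)
#'
#' @param catalog A [MutationCatalog].
#' @param path File path of a tab-separated table whose first column,
#'   `MutationType`, holds category labels.
#' @param schema A [ContextSchema]; when `NULL`, one of the fixed built-in
#'   schemas is inferred from the category labels (configurable copy-number
#'   and structural-variant schemas must be supplied explicitly).
#' @return `readCatalog` returns a [MutationCatalog]; `readSignatures` a
#'   [SignatureSet]; the writers return the path invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  df <- data.frame(MutationType = rownames(catalog@counts),
                   catalog@counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.inferSchema <- function(labels) {
  for (s in list(schemaSBS96(), schemaSBS288(), schemaDBS78(), schemaID83())) {
    if (length(labels) == length(s@categories) &&
        setequal(labels, s@categories)) return(s)
  }
  stop("cannot infer a schema from ", length(labels),
       " category labels; pass `schema` explicitly")
}

.readMatrix <- function(path, schema) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "MutationType")
    stop("first column must be 'MutationType'")
  labels <- df[[1]]
  if (is.null(schema)) schema <- .inferSchema(labels)
  if (!setequal(labels, schema@categories))
    stop("category labels do not match the schema")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  m <- m[schema@categories, , drop = FALSE]
  list(matrix = m, schema = schema)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path, schema = NULL) {
  x <- .readMatrix(path, schema)
  new("MutationCatalog", counts = x$matrix, schema = x$schema,
      unclassified = setNames(numeric(ncol(x$matrix)), colnames(x$matrix)))
}

#' @rdname writeCatalog
#' @param signatures A [SignatureSet].
#' @export
writeSignatures <- function(signatures, path) {
  df <- data.frame(MutationType = rownames(signatures@profiles),
                   signatures@profiles, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @param exclusions,rescueRules,msiSet Assignment-rule metadata attached to
#'   the returned [SignatureSet] (not stored in the text format).
#' @export
readSignatures <- function(path, schema = NULL, exclusions = character(0),
                           rescueRules = character(0), msiSet = character(0)) {
  x <- .readMatrix(path, schema)
  signatureSet(x$matrix, schema = x$schema, exclusions = exclusions,
               rescueRules = rescueRules, msiSet = msiSet)
}

#' Construct a signature set from a profile matrix
#'
#' Columns are renormalized to sum to exactly 1 (they must already be close).
#'
#' @param profiles Nonnegative matrix, categories x signatures, with row names
#'   matching the schema categories and column names naming signatures.
#' @param schema The [ContextSchema]; inferred from the row labels when `NULL`.
#' @param exclusions Signature labels globally excluded from candidate sets.
#' @param rescueRules Named character vector mapping a trigger signature label
#'   (in another variant class) to the signature it admits here.
#' @param msiSet Signatures admitted for samples flagged as microsatellite
#'   unstable.
#' @return A [SignatureSet].
#' @export
signatureSet <- function(profiles, schema = NULL, exclusions = character(0),
                         rescueRules = character(0), msiSet = character(0)) {
  if (is.null(schema)) schema <- .inferSchema(rownames(profiles))
  profiles <- profiles[schema@categories, , drop = FALSE]
  cs <- colSums(profiles)
  if (any(abs(cs - 1) > 1e-6))
    stop("profile columns must sum to 1")
  profiles <- sweep(profiles, 2, cs, "/")
  new("SignatureSet", schema = schema, profiles = profiles,
      exclusions = exclusions, rescueRules = rescueRules, msiSet = msiSet)
}
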