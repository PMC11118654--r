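#' Assignment configuration
#'
#' Penalties are in cosine-similarity units. The default addition penalty of
#' 0.05 and removal penalty of 0.01 control sparsity of the forward-stagewise
#' fit (an asymmetry that admits signatures reluctantly but prunes genuinely
#' contributing ones rarely); the relaxed addition penalty of 0.01 is used
#' where sensitivity matters more than sparsity (signature-injection power
#' studies).
#'
#' @param addPenalty Minimum cosine-similarity gain required to admit a
#'   signature in the forward step.
#' @param removePenalty Maximum cosine-similarity loss tolerated when pruning
#'   a signature in the backward step.
#' @param relaxedAddPenalty Sensitive-mode addition penalty.
#' @return A configuration list.
#' @export
assignmentConfig <- function(addPenalty = 0.05, removePenalty = 0.01,
                             relaxedAddPenalty = 0.01) {
  stopifnot(addPenalty >= 0, addPenalty < 1,
            removePenalty >= 0, removePenalty < 1,
            relaxedAddPenalty >= 0, relaxedAddPenalty < 1)
  list(addPenalty = addPenalty, removePenalty = removePenalty,
       relaxedAddPenalty = relaxedAddPenalty)
}

.fitCosine <- function(profile, cand, support) {
  if (length(support) == 0L)
    return(list(x = setNames(numeric(ncol(cand)), colnames(cand)), cos = 0))
  xs <- .nnls(cand[, support, drop = FALSE], profile)
  x <- setNames(numeric(ncol(cand)), colnames(cand))
  x[support] <- xs
  list(x = x, cos = cosineSimilarity(profile,
                                     cand[, support, drop = FALSE] %*% xs))
}

#' Sparse signature assignment by forward-stagewise nonnegative least squares
#'
#' Fits nonnegative signature activities to a sample profile over an
#' iteratively selected support. Starting from the full candidate set, a
#' backward pass prunes any signature whose removal costs at most
#' `removePenalty` in reconstruction cosine similarity; a forward pass then
#' admits a signature only if it improves the similarity by more than
#' `addPenalty`. The passes alternate until the support is stable. Ties are
#' broken by larger similarity change and then lexicographic signature label,
#' so the result is deterministic. Off-support activities are exactly zero.
#'
#' @param profile Numeric count vector over the schema categories (one catalog
#'   column).
#' @param candidates Candidate profile matrix (categories x signatures) or a
#'   [SignatureSet].
#' @param config An [assignmentConfig()].
#' @param addPenalty Override of the configured addition penalty (e.g. the
#'   relaxed value).
#' @return Named activity vector (mutation counts, exact zeros off support)
#'   with the achieved reconstruction similarity in attribute `"cosine"`.
#' @export
assignActivities <- function(profile, candidates,
                             config = assignmentConfig(),
                             addPenalty = config$addPenalty) {
  if (is(candidates, "SignatureSet")) candidates <- candidates@profiles
  cand <- as.matrix(candidates)
  if (ncol(cand) == 0L) stop("empty candidate set")
  if (is.null(colnames(cand))) stop("candidates must be named")
  profile <- as.numeric(profile)
  if (length(profile) != nrow(cand))
    stop("profile length does not match candidate schema")
  empty <- setNames(numeric(ncol(cand)), colnames(cand))
  if (sum(profile) == 0) {
    attr(empty, "cosine") <- 0
    return(empty)
  }

  support <- sort(colnames(cand))
  cur <- .fitCosine(profile, cand, support)
  repeat {
    changed <- FALSE
    ## backward pruning
    repeat {
      if (length(support) == 0L) break
      drops <- vapply(support, function(s) {
        .fitCosine(profile, cand, setdiff(support, s))$cos
      }, numeric(1))
      ord <- order(-drops, names(drops))
      best <- names(drops)[ord[1]]
      if (cur$cos - drops[best] <= config$removePenalty) {
        support <- setdiff(support, best)
        cur <- .fitCosine(profile, cand, support)
        changed <- TRUE
      } else break
    }
    ## forward addition
    repeat {
      outside <- setdiff(sort(colnames(cand)), support)
      if (length(outside) == 0L) break
      gains <- vapply(outside, function(s) {
        .fitCosine(profile, cand, c(support, s))$cos
      }, numeric(1))
      ord <- order(-gains, names(gains))
      best <- names(gains)[ord[1]]
      if (gains[best] - cur$cos > addPenalty) {
        support <- c(support, best)
        cur <- .fitCosine(profile, cand, support)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  out <- cur$x
  attr(out, "cosine") <- cur$cos
  out
}

#' Decompose de novo signatures into a reference set
#'
#' Each de novo profile is fit against the reference profiles (minus global
#' exclusions) with [assignActivities()]; the fitted weights are normalized to
#' sum to 1.
#'
#' @param denovo A [SignatureExtraction] or a profile matrix
#'   (categories x signatures, columns summing to 1).
#' @param reference A [SignatureSet] sharing the schema.
#' @param config An [assignmentConfig()].
#' @return Named list per de novo signature: `weights` (reference label to
#'   weight, summing to 1) and decomposition `cosine`.
#' @export
decomposeSignatures <- function(denovo, reference,
                                config = assignmentConfig()) {
  W <- if (is(denovo, "SignatureExtraction")) denovo@signatures else denovo
  if (nrow(W) != nrow(reference@profiles))
    stop("schema mismatch between de novo signatures and reference")
  keep <- setdiff(colnames(reference@profiles), reference@exclusions)
  cand <- reference@profiles[, keep, drop = FALSE]
  out <- lapply(seq_len(ncol(W)), function(j) {
    ## scale to a nominal mutation count so penalties act as for samples
    act <- assignActivities(W[, j] * 1000, cand, config)
    w <- act[act > 0]
    list(weights = w / sum(w), cosine = attr(act, "cosine"))
  })
  names(out) <- colnames(W)
  out
}

#' Per-sample candidate signature sets under the cohort rules
#'
#' The base candidate set is the decomposed reference labels minus the global
#' exclusions. Rescue rules admit additional signatures conditional on the
#' activity of a trigger signature from another variant class (by default the
#' homologous-recombination-deficiency indel signature ID6 admits SBS3, and
#' the tobacco-associated indel signature ID3 admits SBS92). Samples flagged
#' as microsatellite unstable additionally receive SBS33 and the
#' mismatch-repair-deficiency set.
#'
#' @param baseLabels Character vector of decomposed reference labels.
#' @param idActivities Named activity vector (or one-column matrix) of
#'   indel-class signatures for the sample.
#' @param msiFlag Logical MSI flag for the sample.
#' @param reference A [SignatureSet] carrying `exclusions`, `rescueRules` and
#'   `msiSet`.
#' @return Sorted character vector of candidate signature labels.
#' @export
buildCandidateSets <- function(baseLabels, idActivities = numeric(0),
                               msiFlag = FALSE, reference) {
  rules <- reference@rescueRules
  if (length(rules) && is.null(names(rules)))
    stop("configuration error: rescue rules must be named by trigger label")
  out <- setdiff(baseLabels, reference@exclusions)
  if (length(rules) && length(idActivities)) {
    unknown <- setdiff(names(rules), names(idActivities))
    if (length(unknown))
      stop("configuration error: unknown trigger signature(s): ",
           paste(unknown, collapse = ", "))
    for (trigger in names(rules)) {
      if (idActivities[[trigger]] > 0)
        out <- c(out, rules[[trigger]])
    }
  }
  if (isTRUE(msiFlag)) out <- c(out, "SBS33", reference@msiSet)
  sort(unique(out))
}

#' Default cohort assignment rules
#'
#' The shipped rule set: SBS23 and SBS32 globally excluded; ID6 activity
#' admits SBS3 and ID3 activity admits SBS92; the MSI rescue set comprises the
#' seven mismatch-repair-deficiency signatures.
#'
#' @return A list with `exclusions`, `rescueRules` and `msiSet` suitable for
#'   [signatureSet()].
#' @export
defaultAssignmentRules <- function() {
  list(exclusions = c("SBS23", "SBS32"),
       rescueRules = c(ID6 = "SBS3", ID3 = "SBS92"),
       msiSet = c("SBS6", "SBS14", "SBS15", "SBS20", "SBS21", "SBS26",
                  "SBS44"))
}
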