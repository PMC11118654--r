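#' Probabilistic attribution of mutations to signatures
#'
#' For each sample, the posterior probability that signature s caused a
#' mutation in context category c is the signature's profile value at c times
#' its activity in the sample, normalized by the reconstructed number of
#' mutations in that category:
#' `P(s | c, j) = W[c, s] A[s, j] / sum_s' W[c, s'] A[s', j]`.
#' Categories with zero reconstructed count have undefined posteriors and are
#' returned as `NA` (flagged).
#'
#' @param activities Activity matrix, signatures x samples (e.g. columns of
#'   [assignActivities()] results).
#' @param reference A [SignatureSet] whose profiles cover the activity rows.
#' @return A list of class `"mutationProbabilities"`: `probabilities`, a
#'   3-d array `[category, signature, sample]`; `reconstructed`, the
#'   categories x samples reconstruction `W A`.
#' @export
mutationProbabilities <- function(activities, reference) {
  A <- as.matrix(activities)
  W <- reference@profiles[, rownames(A), drop = FALSE]
  R <- W %*% A
  arr <- array(NA_real_, dim = c(nrow(W), ncol(W), ncol(A)),
               dimnames = list(rownames(W), colnames(W), colnames(A)))
  for (j in seq_len(ncol(A))) {
    M <- sweep(W, 2, A[, j], "*")
    denom <- rowSums(M)
    P <- sweep(M, 1, denom, "/")
    P[denom == 0, ] <- NA_real_
    arr[, , j] <- P
  }
  structure(list(probabilities = arr, reconstructed = R),
            class = "mutationProbabilities")
}

#' @export
print.mutationProbabilities <- function(x, ...) {
  d <- dim(x$probabilities)
  cat("mutationProbabilities:", d[1], "categories x", d[2], "signatures x",
      d[3], "samples\n")
  invisible(x)
}

#' Attribute driver mutations to their most likely signature
#'
#' Looks up each driver mutation's posterior signature distribution, reports
#' the maximum-probability signature (lexicographic tie-break) and flags the
#' call as confident when that probability strictly exceeds `threshold`.
#' Also aggregates per-gene signature proportions (the mean posterior over a
#' gene's driver mutations), which sum to 1 per gene.
#'
#' @param drivers Data frame with columns `sample`, `category`, `gene`.
#' @param probabilities Result of [mutationProbabilities()].
#' @param threshold Confidence threshold on the top probability (strict).
#' @return List with `mutations` (input rows plus `signature`, `probability`,
#'   `confident`) and `geneProportions` (genes x signatures matrix).
#' @export
attributeDrivers <- function(drivers, probabilities, threshold = 0.5) {
  arr <- probabilities$probabilities
  sigs <- dimnames(arr)[[2]]
  top <- character(nrow(drivers))
  prob <- numeric(nrow(drivers))
  post <- matrix(0, nrow(drivers), length(sigs),
                 dimnames = list(NULL, sigs))
  for (i in seq_len(nrow(drivers))) {
    cat <- drivers$category[i]
    if (!cat %in% dimnames(arr)[[1]])
      stop("missing context: category '", cat, "' absent from the table")
    p <- arr[cat, , drivers$sample[i]]
    if (all(is.na(p)))
      stop("no reconstructed mutations in category '", cat,
           "' for sample ", drivers$sample[i])
    ord <- order(-p, sigs)
    top[i] <- sigs[ord[1]]
    prob[i] <- p[ord[1]]
    post[i, ] <- p
  }
  mutations <- cbind(drivers,
                     data.frame(signature = top, probability = prob,
                                confident = prob > threshold))
  geneProp <- rowsum(post, group = drivers$gene) /
    as.vector(table(drivers$gene)[sort(unique(drivers$gene))])
  list(mutations = mutations, geneProportions = geneProp)
}
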