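#' Hypermutator normalization of a catalog
#'
#' Rescales any sample whose total event count exceeds `cap` down to exactly
#' `cap` events, leaving other samples untouched. This limits the influence of
#' hypermutated samples on de novo extraction; the default cap is 10,000
#' mutations.
#'
#' @param catalog A [MutationCatalog].
#' @param cap Maximum per-sample total after normalization.
#' @return A real-valued [MutationCatalog] with column totals
#'   `min(original, cap)`.
#' @export
normalizeCatalog <- function(catalog, cap = 10000) {
  if (cap <= 0) stop("cap must be positive")
  counts <- catalog@counts
  tot <- colSums(counts)
  over <- tot > cap
  if (any(over))
    counts[, over] <- sweep(counts[, over, drop = FALSE], 2,
                            cap / tot[over], "*")
  new("MutationCatalog", counts = counts, schema = catalog@schema,
      unclassified = catalog@unclassified)
}

#' Extraction configuration
#'
#' @param kMin,kMax Range of candidate signature numbers.
#' @param replicates Factorization replicates per candidate k.
#' @param cap Hypermutator normalization cap (mutations); see
#'   [normalizeCatalog()].
#' @param maxIterations Maximum multiplicative updates per factorization.
#' @param tolerance Relative divergence-change stopping threshold.
#' @param seed Base seed; replicate r at rank k uses a seed derived
#'   deterministically from it.
#' @param resample Poisson-resample the catalog per replicate (bootstrap).
#' @return A configuration list for [extractSignatures()].
#' @export
extractionConfig <- function(kMin = 2L, kMax = 8L, replicates = 20L,
                             cap = 10000, maxIterations = 10000L,
                             tolerance = 1e-9, seed = 1L, resample = TRUE) {
  stopifnot(kMin >= 1L, kMax >= kMin, cap > 0, replicates >= 1L)
  list(kMin = as.integer(kMin), kMax = as.integer(kMax),
       replicates = as.integer(replicates), cap = cap,
       maxIterations = as.integer(maxIterations), tolerance = tolerance,
       seed = as.integer(seed), resample = isTRUE(resample))
}

.klDivergence <- function(V, WH) {
  eps <- .Machine$double.eps
  WH <- pmax(WH, eps)
  Vp <- pmax(V, eps)
  sum(V * log(Vp / WH) - V + WH)
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative catalog `V` (categories x samples) as `W H`,
#' minimizing the generalized Kullback-Leibler divergence with the classical
#' multiplicative update rules, which never increase the divergence. Columns
#' of the returned signature matrix sum to 1, with the activity matrix rescaled
#' so the reconstruction is unchanged.
#'
#' @param V Nonnegative matrix or [MutationCatalog].
#' @param k Number of signatures.
#' @param seed Seed for the nonnegative random initialization (uniform, scaled
#'   to the catalog mean).
#' @param maxIterations,tolerance Stopping rules: iteration cap and relative
#'   divergence-change threshold (checked every 10 iterations).
#' @param trace Record the divergence after every iteration (slower; used by
#'   monotonicity checks).
#' @return List with `signatures` (categories x k, columns summing to 1),
#'   `activities` (k x samples), final `divergence`, `iterations`, and when
#'   `trace = TRUE` the per-iteration `divergenceTrace`.
#' @export
nmfFactorize <- function(V, k, seed = 1L, maxIterations = 10000L,
                         tolerance = 1e-9, trace = FALSE) {
  if (is(V, "MutationCatalog")) V <- V@counts
  V <- as.matrix(V)
  if (any(V < 0)) stop("catalog must be nonnegative")
  if (sum(V) == 0) stop("degenerate input: all-zero catalog")
  if (k < 1) stop("k must be >= 1")
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  set.seed(seed)
  scale <- sqrt(mean(V) / k)
  W <- matrix(runif(m * k), m, k) * scale
  H <- matrix(runif(k * n), k, n) * scale
  lastDiv <- Inf
  traceVec <- if (trace) numeric(0) else NULL
  it <- 0L
  while (it < maxIterations) {
    it <- it + 1L
    WH <- pmax(W %*% H, eps)
    H <- H * (crossprod(W, V / WH) / pmax(colSums(W), eps))
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H), m, k, byrow = TRUE),
                                        eps)
    if (trace) {
      traceVec <- c(traceVec, .klDivergence(V, W %*% H))
    }
    if (it %% 10L == 0L) {
      div <- .klDivergence(V, W %*% H)
      if (is.finite(lastDiv) &&
          abs(lastDiv - div) <= tolerance * max(lastDiv, eps)) {
        lastDiv <- div
        break
      }
      lastDiv <- div
    }
  }
  div <- .klDivergence(V, W %*% H)
  cs <- pmax(colSums(W), eps)
  W <- sweep(W, 2, cs, "/")
  H <- sweep(H, 1, cs, "*")
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  out <- list(signatures = W, activities = H, divergence = div,
              iterations = it)
  if (trace) out$divergenceTrace <- traceVec
  out
}

#' Stability-based rank selection
#'
#' Returns the largest candidate k whose replicate-cluster stability is at
#' least `stabilityFloor` and whose reconstruction error is within
#' `errorSlack` (relative) of the best error among qualifying k. If no k
#' qualifies, the k with maximal stability is returned with a warning.
#'
#' @param stability Named numeric vector, mean silhouette per k.
#' @param error Named numeric vector, reconstruction divergence per k (same
#'   names as `stability`).
#' @param stabilityFloor Minimum acceptable stability.
#' @param errorSlack Acceptable relative excess over the best qualifying error.
#' @return The selected k as an integer.
#' @export
selectRank <- function(stability, error, stabilityFloor = 0.8,
                       errorSlack = 0.05) {
  stopifnot(identical(names(stability), names(error)))
  ks <- as.integer(names(stability))
  ok <- stability >= stabilityFloor
  if (!any(ok)) {
    warning("no candidate rank reaches the stability floor; ",
            "returning the most stable rank")
    return(ks[which.max(stability)])
  }
  best <- min(error[ok])
  qual <- ok & error <= best * (1 + errorSlack) + .Machine$double.eps
  max(ks[qual])
}

#' De novo signature extraction with replicated factorization
#'
#' For every candidate k in `[kMin, kMax]`, runs `replicates` seeded
#' factorizations (each on a Poisson-resampled catalog when `resample = TRUE`)
#' of the hypermutator-normalized catalog, pools the replicate signatures,
#' partitions them into k clusters by replicate-matched cosine clustering
#' (each cluster takes exactly one signature per replicate), and scores
#' stability as the mean silhouette width under cosine distance. Consensus
#' signatures are the
#' normalized cluster centroids; consensus activities are refit by nonnegative
#' least squares against the raw (un-normalized) catalog. The rank is chosen
#' by [selectRank()].
#'
#' @param catalog A [MutationCatalog] of raw counts.
#' @param config An [extractionConfig()].
#' @return A [SignatureExtraction].
#' @export
extractSignatures <- function(catalog, config = extractionConfig()) {
  ## a single replicate is only meaningful without resampling, where the
  ## procedure degenerates to one factorization per k
  if (config$replicates < 2L && config$resample)
    stop("configuration error: resampling requires at least 2 replicates")
  raw <- catalog@counts
  if (ncol(raw) <= config$kMax)
    stop("kMax must be smaller than the number of samples")
  V <- normalizeCatalog(catalog, config$cap)@counts

  ks <- config$kMin:config$kMax
  stability <- setNames(numeric(length(ks)), ks)
  error <- setNames(numeric(length(ks)), ks)
  consensus <- list()

  for (ki in seq_along(ks)) {
    k <- ks[ki]
    pool <- vector("list", config$replicates)
    divs <- numeric(config$replicates)
    for (r in seq_len(config$replicates)) {
      s <- .childSeed(config$seed, 10000L * k + r)
      Vr <- V
      if (config$resample) {
        set.seed(s)
        Vr <- matrix(rpois(length(V), lambda = V), nrow(V), ncol(V),
                     dimnames = dimnames(V))
        if (sum(Vr) == 0) Vr <- V
      }
      fit <- nmfFactorize(Vr, k, seed = .childSeed(s, 7L),
                          maxIterations = config$maxIterations,
                          tolerance = config$tolerance)
      pool[[r]] <- fit$signatures
      divs[r] <- .klDivergence(V, fit$signatures %*%
                                 .nnlsActivities(fit$signatures, V))
    }
    P <- do.call(cbind, pool)
    if (config$replicates == 1L) {
      cen <- .normalizeColumns(P)
      colnames(cen) <- paste0("S", seq_len(k))
      consensus[[ki]] <- cen
      stability[ki] <- 1
    } else if (k == 1L) {
      centroid <- rowMeans(P)
      consensus[[ki]] <- matrix(centroid / sum(centroid), ncol = 1,
                                dimnames = list(rownames(V), "S1"))
      stability[ki] <- mean(.cosineCross(P, matrix(centroid, ncol = 1)))
    } else {
      mc <- .matchedClusters(pool, k)
      stability[ki] <- mc$stability
      cen <- .normalizeColumns(mc$centroids)
      colnames(cen) <- paste0("S", seq_len(k))
      rownames(cen) <- rownames(V)
      consensus[[ki]] <- cen
    }
    error[ki] <- median(divs)
  }

  selected <- selectRank(stability, error)
  W <- consensus[[match(selected, ks)]]
  H <- .nnlsActivities(W, raw)
  recon <- W %*% H
  coss <- vapply(seq_len(ncol(raw)), function(j)
    cosineSimilarity(raw[, j], recon[, j]), numeric(1))
  names(coss) <- colnames(raw)
  rownames(H) <- colnames(W)
  new("SignatureExtraction", signatures = W, activities = H,
      selectedK = as.integer(selected), stability = stability, error = error,
      reconstructionCosine = coss, config = config)
}

## Replicate-matched clustering of pooled replicate signatures: every cluster
## takes exactly one signature from each replicate (greedy cosine matching to
## the current centroids, iterated). This constraint is what makes the
## silhouette a rank discriminator: above the true rank each replicate's
## surplus component differs, the matched cluster is diffuse, and the mean
## silhouette collapses, whereas an unconstrained partition can still find
## tight incidental clusters.
.matchedClusters <- function(pool, k) {
  R <- length(pool)
  cen <- pool[[1]]
  assign <- vector("list", R)
  for (it in seq_len(6L)) {
    for (r in seq_len(R)) {
      cm <- .cosineCross(pool[[r]], cen)
      perm <- integer(k)
      used <- logical(k)
      ord <- order(-cm)
      for (idx in ord) {
        i <- (idx - 1L) %% k + 1L
        j <- (idx - 1L) %/% k + 1L
        if (perm[i] == 0L && !used[j]) {
          perm[i] <- j
          used[j] <- TRUE
        }
      }
      assign[[r]] <- perm
    }
    newcen <- matrix(0, nrow(cen), k)
    for (r in seq_len(R))
      for (i in seq_len(k))
        newcen[, assign[[r]][i]] <- newcen[, assign[[r]][i]] + pool[[r]][, i]
    cen <- sweep(newcen, 2, pmax(colSums(newcen), .Machine$double.eps), "/")
  }
  P <- do.call(cbind, pool)
  cl <- unlist(assign)
  d <- as.dist(1 - .cosineCross(P, P))
  sil <- cluster::silhouette(cl, d)
  list(clustering = cl, centroids = cen, stability = mean(sil[, 3]))
}

## per-sample NNLS refit of activities for fixed signatures
.nnlsActivities <- function(W, V) {
  H <- vapply(seq_len(ncol(V)), function(j) .nnls(W, V[, j]),
              numeric(ncol(W)))
  H <- matrix(H, nrow = ncol(W), ncol = ncol(V),
              dimnames = list(colnames(W), colnames(V)))
  H
}
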