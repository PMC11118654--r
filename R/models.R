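## Association models: logistic presence models, log-scale linear models for
## burden and telomere ratio, driver-gene enrichment, and the nonparametric
## tests used for univariate comparisons.

.DEFAULT_COVARIATES <- c("age", "sex", "ancestry", "histology", "purity")

.modelFrame <- function(data, vars) {
  keep <- complete.cases(data[, vars, drop = FALSE])
  data[keep, vars, drop = FALSE]
}

## Firth-type bias-reduced logistic regression (Newton iterations on the
## modified score); used as the documented fallback when the maximum
## likelihood fit separates
.firthLogistic <- function(X, y, maxIter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    infoInv <- solve(info)
    h <- rowSums((X %*% infoInv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- infoInv %*% U
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (p * (1 - p)))
  se <- sqrt(diag(solve(info)))
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       se = setNames(se, colnames(X)))
}

.waldRow <- function(term, est, se, transform = identity, flag = NA_character_) {
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  ci <- est + c(-1, 1) * qnorm(0.975) * se
  data.frame(term = term, estimate = est, se = se,
             ci_low = ci[1], ci_high = ci[2], p_value = p,
             transformed_estimate = transform(est),
             transformed_ci_low = transform(ci[1]),
             transformed_ci_high = transform(ci[2]),
             flag = flag, stringsAsFactors = FALSE)
}

#' Multivariable logistic presence model
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome (e.g.
#' presence of a signature or of driver mutations in a gene) on an exposure
#' with covariate adjustment. For a continuous PM2.5 exposure, odds ratios are
#' conventionally reported per 10 micrograms per cubic meter via `orPerUnits`.
#' Complete separation is detected and handled by a flagged bias-reduced
#' (Firth) refit rather than a silent failure.
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Name of the logical/binary outcome column.
#' @param exposure Name of the exposure column (numeric or two-level factor).
#' @param covariates Covariate column names (default: age, sex, ancestry,
#'   histology, purity; columns absent from `data` are dropped).
#' @param orPerUnits Report the odds ratio for this many exposure units
#'   (continuous exposures only); `NULL` for per-unit.
#' @return One-row data frame: coefficient (log-odds) scale estimate, standard
#'   error, 95 percent CI and p-value for the exposure term, plus the
#'   odds-ratio scale columns `transformed_*` (scaled by `orPerUnits` when
#'   given) and a `flag` (`NA`, or `"firth"` when the fallback was used).
#' @export
fitLogisticModel <- function(data, outcome, exposure,
                             covariates = .DEFAULT_COVARIATES,
                             orPerUnits = NULL) {
  covariates <- intersect(covariates, names(data))
  df <- .modelFrame(data, c(outcome, exposure, covariates))
  y <- df[[outcome]]
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("outcome must have both classes")
  ex <- df[[exposure]]
  if (length(unique(ex[!is.na(ex)])) < 2L)
    stop("degenerate design: exposure is constant")
  form <- as.formula(paste("y ~", paste(c(exposure, covariates),
                                        collapse = " + ")))
  df$y <- y
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  X <- model.matrix(form, df)
  termName <- grep(paste0("^", exposure), colnames(X), value = TRUE)[1]
  separated <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8) ||
    abs(coef(fit)[termName]) > 15
  units <- if (!is.null(orPerUnits) && is.numeric(ex)) orPerUnits else 1
  trans <- function(b) exp(units * b)
  if (separated) {
    fb <- .firthLogistic(X, y)
    row <- .waldRow(termName, fb$coefficients[termName], fb$se[termName],
                    transform = trans, flag = "firth")
  } else {
    est <- coef(fit)[termName]
    se <- sqrt(diag(vcov(fit)))[termName]
    row <- .waldRow(termName, unname(est), unname(se), transform = trans)
  }
  row$n <- nrow(df)
  rownames(row) <- NULL
  row
}

#' Multivariable log-scale linear model
#'
#' Ordinary least squares on a log-transformed positive outcome: mutation
#' burdens and signature-assigned mutation counts on the log10 scale, the
#' tumor/normal telomere-length ratio on the log2 scale. The exposure
#' coefficient is additionally reported as a percent change per exposure unit,
#' `base^beta - 1`, with the CI transformed the same way. Non-positive
#' outcomes are excluded with their count recorded.
#'
#' @inheritParams fitLogisticModel
#' @param outcome Name of the positive outcome column (transformed
#'   internally).
#' @param logBase 10 for burdens, 2 for telomere ratios.
#' @param subset Optional logical vector restricting the fit (e.g. samples
#'   where the signature is present).
#' @return One-row data frame as in [fitLogisticModel()], with
#'   `transformed_*` columns holding the percent change (`base^beta - 1`) and
#'   `n_dropped` counting excluded non-positive outcomes.
#' @export
fitLinearModel <- function(data, outcome, exposure,
                           covariates = .DEFAULT_COVARIATES, logBase = 10,
                           subset = NULL) {
  covariates <- intersect(covariates, names(data))
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  df <- .modelFrame(data, c(outcome, exposure, covariates))
  pos <- df[[outcome]] > 0
  nDropped <- sum(!pos)
  df <- df[pos, , drop = FALSE]
  df$.y <- log(df[[outcome]], base = logBase)
  ex <- df[[exposure]]
  if (length(unique(ex[!is.na(ex)])) < 2L)
    stop("degenerate design: exposure is constant")
  form <- as.formula(paste(".y ~", paste(c(exposure, covariates),
                                         collapse = " + ")))
  fit <- lm(form, data = df)
  X <- model.matrix(form, df)
  termName <- grep(paste0("^", exposure), colnames(X), value = TRUE)[1]
  est <- coef(fit)[termName]
  se <- sqrt(diag(vcov(fit)))[termName]
  row <- .waldRow(termName, unname(est), unname(se),
                  transform = function(b) logBase^b - 1)
  row$n <- nrow(df)
  row$n_dropped <- nDropped
  rownames(row) <- NULL
  row
}

#' Driver-gene enrichment with an exposure
#'
#' Filters driver genes to those mutated in more than `minPrevalence` of the
#' cohort, fits one covariate-adjusted logistic model per gene, and applies
#' Benjamini-Hochberg correction jointly across the tested genes.
#'
#' @inheritParams fitLogisticModel
#' @param genes Names of logical driver-indicator columns in `data`.
#' @param minPrevalence Strict lower bound on mutated-case prevalence.
#' @return Data frame with one row per tested gene, including `fdr`.
#' @export
driversEnrichment <- function(data, genes, exposure,
                              covariates = .DEFAULT_COVARIATES,
                              minPrevalence = 0.02, orPerUnits = NULL) {
  prevalence <- vapply(genes, function(g) mean(data[[g]], na.rm = TRUE),
                       numeric(1))
  tested <- genes[prevalence > minPrevalence]
  rows <- lapply(tested, function(g) {
    row <- tryCatch(
      fitLogisticModel(data, g, exposure, covariates, orPerUnits),
      error = function(e) NULL)
    if (!is.null(row)) row$gene <- g
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame())
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p_value)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement. Correction is
#' applied within whatever family of p-values is passed, so callers control
#' the family structure (one family per variant class per analysis).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, elementwise at least as large as the input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sided Fisher exact co-occurrence test
#'
#' Tests co-occurrence of two binary traits with the two-sided Fisher exact
#' test (hypergeometric enumeration) and reports the sample odds ratio
#' `(a d) / (b c)`, with a Haldane correction of 0.5 per cell when any cell is
#' zero (flagged).
#'
#' @param a,b Logical vectors over the same samples.
#' @return List with `oddsRatio`, `p_value`, the 2x2 `table`, and `flag`
#'   (`NA`, `"haldane"` or `"degenerate"` for an empty margin).
#' @export
cooccurrenceTest <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("yes", "no"), B = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(oddsRatio = NA_real_, p_value = 1, table = tab,
                flag = "degenerate"))
  p <- fisher.test(tab)$p.value
  flag <- NA_character_
  t2 <- tab
  if (any(tab == 0)) {
    t2 <- tab + 0.5
    flag <- "haldane"
  }
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(oddsRatio = unname(or), p_value = p, table = tab, flag = flag)
}

#' Two-sided rank-sum group comparison
#'
#' Wilcoxon-Mann-Whitney rank-sum test. For combined sample sizes up to
#' `exactLimit` the two-sided p-value is computed by exact enumeration of all
#' group assignments of the (tie-averaged) ranks; larger samples use the
#' normal approximation with tie correction. When every value is identical the
#' p-value is 1 with a tie flag.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exactLimit Largest combined size for exact enumeration.
#' @return List with `p_value`, rank-sum `statistic` (of `x`), `method`, and
#'   `tieFlag`.
#' @export
groupDifferenceTest <- function(x, y, exactLimit = 10L) {
  stopifnot(length(x) > 0, length(y) > 0)
  all <- c(x, y)
  if (length(unique(all)) == 1L)
    return(list(p_value = 1, statistic = sum(rank(all)[seq_along(x)]),
                method = "degenerate", tieFlag = TRUE))
  ties <- anyDuplicated(all) > 0
  r <- rank(all)
  w <- sum(r[seq_along(x)])
  n <- length(all); nx <- length(x)
  if (n <= exactLimit) {
    mu <- nx * (n + 1) / 2
    combos <- combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-12)
    return(list(p_value = p, statistic = w, method = "exact enumeration",
                tieFlag = ties))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  list(p_value = wt$p.value, statistic = w, method = "normal approximation",
       tieFlag = ties)
}
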