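#' Individual fine-particulate exposure estimate
#'
#' Averages the annual region-level PM2.5 concentrations from the year of
#' diagnosis back to the earliest covered year (1998). Subjects diagnosed
#' before the series start, or with unknown diagnosis year, receive the
#' earliest year's value; subjects with unknown region receive `NA` and are
#' excluded from pollution models downstream. A diagnosis year beyond the
#' series coverage is truncated to the covered years with a warning.
#'
#' @param region Region identifier (or `NA`).
#' @param diagnosisYear Year of diagnosis (or `NA`).
#' @param series Data frame with columns `region`, `year`, `pm25`
#'   (micrograms per cubic meter).
#' @param firstYear Earliest year of the series coverage.
#' @return Mean PM2.5 in micrograms per cubic meter, or `NA`.
#' @export
pm25Estimate <- function(region, diagnosisYear, series, firstYear = 1998L) {
  if (is.na(region)) return(NA_real_)
  s <- series[series$region == region, , drop = FALSE]
  if (nrow(s) == 0L) stop("series does not cover region '", region, "'")
  s <- s[order(s$year), , drop = FALSE]
  if (is.na(diagnosisYear) || diagnosisYear < firstYear)
    return(s$pm25[s$year == firstYear])
  lastYear <- max(s$year)
  if (diagnosisYear > lastYear) {
    warning("diagnosis year ", diagnosisYear,
            " beyond series coverage; truncating to ", lastYear)
    diagnosisYear <- lastYear
  }
  use <- s$year >= firstYear & s$year <= diagnosisYear
  mean(s$pm25[use])
}

#' Dichotomize a PM2.5 estimate into high and low exposure
#'
#' Values at or above the threshold are classified as high. The default
#' threshold of 20 micrograms per cubic meter separates subjects diagnosed in
#' regions with high and low pollution levels.
#'
#' @param estimate PM2.5 estimate(s) in micrograms per cubic meter.
#' @param threshold Dichotomization boundary; the boundary value itself is
#'   classified high.
#' @return Factor with levels `low`, `high` (`NA` preserved).
#' @export
dichotomizePm25 <- function(estimate, threshold = 20) {
  factor(ifelse(is.na(estimate), NA,
                ifelse(estimate >= threshold, "high", "low")),
         levels = c("low", "high"))
}

#' Dichotomize signature activities into presence calls
#'
#' Default presence is any strictly positive activity. Signatures present in
#' more than half the cohort are instead dichotomized at the cohort median of
#' assigned mutations (presence above the median). Signatures active in fewer
#' than `minSamples` samples are excluded from association analyses and
#' listed.
#'
#' @param activities Activity matrix, signatures x samples.
#' @param minSamples Minimum number of active samples for a signature to be
#'   analyzed.
#' @return List with `presence` (logical signatures x samples matrix, excluded
#'   signatures dropped), `excluded` (labels), and `rule` (per-signature:
#'   `"positive"` or `"median"`, with the median threshold as an attribute for
#'   median-rule signatures).
#' @export
signaturePresence <- function(activities, minSamples = 2L) {
  A <- as.matrix(activities)
  active <- rowSums(A > 0)
  excluded <- rownames(A)[active < minSamples]
  keep <- setdiff(rownames(A), excluded)
  presence <- matrix(FALSE, length(keep), ncol(A),
                     dimnames = list(keep, colnames(A)))
  rule <- setNames(character(length(keep)), keep)
  thresholds <- setNames(numeric(length(keep)), keep)
  for (s in keep) {
    prevalence <- mean(A[s, ] > 0)
    if (prevalence > 0.5) {
      med <- median(A[s, ])
      presence[s, ] <- A[s, ] > med
      rule[s] <- "median"
      thresholds[s] <- med
    } else {
      presence[s, ] <- A[s, ] > 0
      rule[s] <- "positive"
      thresholds[s] <- 0
    }
  }
  attr(rule, "threshold") <- thresholds
  list(presence = presence, excluded = excluded, rule = rule)
}
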