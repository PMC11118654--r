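test_that("individual PM2.5 estimates average the covered years", {
  series <- data.frame(region = "X",
                       year = c(1998, 1999, 2000),
                       pm25 = c(10, 20, 30))
  expect_equal(pm25Estimate("X", 2000, series), 20)
  expect_equal(pm25Estimate("X", 1999, series), 15)
  ## diagnosed before coverage, or unknown year: the earliest year's value
  expect_equal(pm25Estimate("X", 1995, series), 10)
  expect_equal(pm25Estimate("X", NA, series), 10)
  ## unknown region: missing, for downstream exclusion
  expect_true(is.na(pm25Estimate(NA, 2000, series)))
  ## beyond coverage: truncate with a warning
  expect_warning(v <- pm25Estimate("X", 2010, series), "truncating")
  expect_equal(v, 20)
  expect_error(pm25Estimate("Y", 2000, series), "cover")
  ## the estimate is an average of its inputs
  set.seed(81)
  s2 <- data.frame(region = "R", year = 1998:2021,
                   pm25 = runif(24, 5, 40))
  for (yr in c(1998, 2005, 2021)) {
    est <- pm25Estimate("R", yr, s2)
    used <- s2$pm25[s2$year <= yr]
    expect_gte(est, min(used))
    expect_lte(est, max(used))
  }
})

test_that("the exposure dichotomization boundary is inclusive at 20", {
  expect_equal(as.character(dichotomizePm25(25)), "high")
  expect_equal(as.character(dichotomizePm25(19.9)), "low")
  expect_equal(as.character(dichotomizePm25(20)), "high")
  expect_true(is.na(dichotomizePm25(NA)))
  expect_equal(formals(dichotomizePm25)$threshold, 20)
})

test_that("signature presence rules switch at 50% prevalence", {
  set.seed(82)
  A <- rbind(
    rare = c(rep(0, 70), stats::rlnorm(30, log(500), 0.4)),
    common = stats::rlnorm(100, log(1200), 0.6),
    single = c(900, rep(0, 99)))
  colnames(A) <- paste0("s", 1:100)
  pres <- signaturePresence(A, minSamples = 2)
  expect_equal(pres$excluded, "single")
  expect_equal(unname(pres$rule["rare"]), "positive")
  expect_equal(unname(pres$rule["common"]), "median")
  expect_equal(unname(pres$presence["rare", ]), unname(A["rare", ] > 0))
  med <- median(A["common", ])
  expect_equal(unname(pres$presence["common", ]), unname(A["common", ] > med))
  expect_equal(sum(pres$presence["common", ]), 50)
})

test_that("log-scale linear models report percent change per unit", {
  set.seed(83)
  n <- 400
  d <- nullCohort(n)
  ## exact dose-response: +2.3% mutations per unit of exposure
  d$burden <- 5000 * 1.023^d$exposure
  ## exact data: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(
    fitLinearModel(d, "burden", "exposure",
                   covariates = c("age", "sex", "purity"), logBase = 10))
  expect_equal(fit$estimate, log10(1.023), tolerance = 1e-8)
  expect_equal(fit$transformed_estimate, 0.023, tolerance = 1e-8)
  ## telomere ratios on the log2 scale
  d$tl <- 2^(0.1 - 0.01 * d$exposure)
  fit2 <- suppressWarnings(
    fitLinearModel(d, "tl", "exposure", covariates = character(0),
                   logBase = 2))
  expect_equal(fit2$estimate, -0.01, tolerance = 1e-8)
  ## non-positive outcomes are dropped and counted
  d$burden[1:5] <- 0
  fit3 <- suppressWarnings(
    fitLinearModel(d, "burden", "exposure", covariates = character(0)))
  expect_equal(fit3$n_dropped, 5)
  expect_equal(fit3$n, n - 5)
  expect_error(fitLinearModel(transform(d, exposure = 1), "burden",
                              "exposure"), "degenerate")
})

test_that("logistic presence models recover planted odds ratios", {
  set.seed(84)
  n <- 1500
  d <- nullCohort(n)
  ## planted log-OR of log(2) per 10 units
  eta <- -1 + log(2) / 10 * (d$exposure - mean(d$exposure))
  d$present <- runif(n) < 1 / (1 + exp(-eta))
  fit <- fitLogisticModel(d, "present", "exposure",
                          covariates = c("age", "sex", "purity"),
                          orPerUnits = 10)
  expect_gt(fit$transformed_estimate, 1.5)
  expect_lt(fit$transformed_estimate, 2.7)
  expect_true(is.na(fit$flag))
  expect_error(fitLogisticModel(transform(d, exposure = 3), "present",
                                "exposure"), "degenerate")
  expect_error(fitLogisticModel(transform(d, present = TRUE), "present",
                                "exposure"), "both classes")
})

test_that("separated logistic fits fall back to a flagged Firth estimate", {
  d <- data.frame(present = rep(c(FALSE, TRUE), each = 20),
                  exposure = c(rnorm(20, 0), rnorm(20, 30)))
  fit <- fitLogisticModel(d, "present", "exposure", covariates = character(0))
  expect_equal(fit$flag, "firth")
  expect_true(is.finite(fit$estimate))
  expect_true(is.finite(fit$se))
  expect_gt(fit$estimate, 0)
})

test_that("driver enrichment applies the prevalence filter and joint FDR", {
  set.seed(85)
  n <- 1000
  d <- nullCohort(n)
  d$gene_rare <- c(rep(TRUE, 19), rep(FALSE, n - 19))     # 1.9%: excluded
  d$gene_ok <- c(rep(TRUE, 21), rep(FALSE, n - 21))       # 2.1%: included
  eta <- -2 + log(2.5) / 10 * (d$exposure - mean(d$exposure))
  d$gene_assoc <- runif(n) < 1 / (1 + exp(-eta))
  res <- driversEnrichment(d, c("gene_rare", "gene_ok", "gene_assoc"),
                           "exposure", covariates = c("age", "sex"),
                           orPerUnits = 10)
  expect_false("gene_rare" %in% res$gene)
  expect_true(all(c("gene_ok", "gene_assoc") %in% res$gene))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
})

test_that("step-up adjustment matches the hand-applied rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(86)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p))
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), adj[perm])
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("co-occurrence tests report the sample odds ratio and exact p", {
  a <- c(rep(TRUE, 10), rep(FALSE, 10))
  b <- c(rep(TRUE, 5), rep(FALSE, 5), TRUE, rep(FALSE, 9))
  out <- cooccurrenceTest(a, b)
  expect_equal(out$table[1, ], c(yes = 5, no = 5))
  expect_equal(out$table[2, ], c(yes = 1, no = 9))
  expect_equal(out$oddsRatio, 9)
  expect_equal(out$p_value, oracleFisherP(out$table), tolerance = 1e-12)
  ## identical vectors: a zero-cell table, flagged
  ident <- cooccurrenceTest(a, a)
  expect_equal(ident$flag, "haldane")
  expect_gt(ident$oddsRatio, 100)
  ## empty margin
  deg <- cooccurrenceTest(rep(TRUE, 10), b[1:10])
  expect_equal(deg$flag, "degenerate")
  expect_true(is.na(deg$oddsRatio))
})

test_that("rank-sum p-values match permutation enumeration for small samples", {
  expect_equal(groupDifferenceTest(c(1, 2), c(3, 4))$p_value, 1 / 3)
  ## identical multisets under exact enumeration
  expect_equal(groupDifferenceTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  ## all values identical: tie-flagged p = 1
  deg <- groupDifferenceTest(rep(2, 4), rep(2, 3))
  expect_equal(deg$p_value, 1)
  expect_true(deg$tieFlag)
  set.seed(87)
  for (i in 1:6) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(1:5, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(groupDifferenceTest(x, y)$p_value, oracleRankSumP(x, y),
                 tolerance = 1e-12)
  }
  ## large samples switch to the tie-corrected normal approximation
  big <- groupDifferenceTest(rnorm(30), rnorm(30, 1))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p_value, 0.05)
})
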