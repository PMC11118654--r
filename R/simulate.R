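## Seeded synthetic cohorts with the statistical structure the association
## analyses assume: signature activities log-normal around a baseline, with
## log-linear exposure effects on selected signatures, a hypermutator tail,
## a burden-only passive-smoking effect, a negative PM2.5 effect on the
## telomere-length ratio, and logistic exposure effects on driver genes.

#' Generate a random well-separated signature panel
#'
#' Draws sparse random profiles (Dirichlet weights on a random subset of
#' categories) and rejects draws until all pairwise cosine similarities are at
#' most `1 - separation`. Uses the current RNG state; seed upstream.
#'
#' @param nSignatures Number of profiles.
#' @param schema [ContextSchema] the panel is defined over.
#' @param separation Minimum pairwise cosine separation (pairwise cosine
#'   similarity at most `1 - separation`).
#' @param sparsity Fraction of categories masked to zero in each profile.
#' @param names Signature labels (defaults to `Sig1..SigN`).
#' @param maxTries Resampling budget before giving up.
#' @param exclusions,rescueRules,msiSet Rule metadata forwarded to
#'   [signatureSet()].
#' @return A [SignatureSet].
#' @export
makeSignaturePanel <- function(nSignatures, schema = schemaSBS96(),
                               separation = 0.4, sparsity = 0.75,
                               names = paste0("Sig", seq_len(nSignatures)),
                               maxTries = 500L,
                               exclusions = character(0),
                               rescueRules = character(0),
                               msiSet = character(0)) {
  stopifnot(nSignatures >= 1L, length(names) == nSignatures)
  m <- length(schema@categories)
  nActive <- max(3L, round(m * (1 - sparsity)))
  drawProfile <- function() {
    p <- numeric(m)
    idx <- sample.int(m, nActive)
    p[idx] <- rgamma(nActive, shape = 0.5)
    p / sum(p)
  }
  profiles <- matrix(0, m, 0)
  tries <- 0L
  while (ncol(profiles) < nSignatures) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not achieve the requested separation in ", maxTries,
           " draws")
    cand <- drawProfile()
    if (ncol(profiles) == 0L ||
        all(.cosineCross(profiles, matrix(cand, ncol = 1)) <= 1 - separation))
      profiles <- cbind(profiles, cand)
  }
  dimnames(profiles) <- list(schema@categories, names)
  signatureSet(profiles, schema = schema, exclusions = exclusions,
               rescueRules = rescueRules, msiSet = msiSet)
}

#' Simulation scenario
#'
#' Describes a synthetic cohort: the signature panel, baseline log-normal
#' activities, a hypermutator tail, region-level PM2.5 exposure with
#' log-linear effects on selected signature activities, a passive-smoking
#' effect on total burden only, a negative PM2.5 effect on the log2
#' telomere-length ratio, logistic exposure effects on driver genes, and
#' covariate distributions. All randomness flows from `seed` through
#' deterministic stream splitting.
#'
#' Shipped presets ([scenarioPreset()]): `"null"` (no exposure effects),
#' `"pollution"` (positive PM2.5 slopes on two substitution signatures plus a
#' negative telomere slope and a positive driver effect), `"passive-smoking"`
#' (a burden-only multiplier with no signature-specific effect), and `"msi"`
#' (one extreme indel-rich outlier to exercise the rescue rules).
#'
#' @param nSamples Cohort size.
#' @param panel A [SignatureSet]; when `NULL`, a separated random panel of
#'   `nSignatures` profiles is generated from the scenario seed.
#' @param nSignatures Panel size when `panel` is `NULL`.
#' @param baselineMeanlog,baselineSdlog Per-signature log-normal activity
#'   parameters (recycled).
#' @param hypermutatorFraction,hypermutatorMultiplier Fraction of samples
#'   whose every activity is multiplied by the multiplier.
#' @param regions Data frame with columns `region`, `mean` (long-run mean
#'   PM2.5, micrograms per cubic meter) and `sd` (year-to-year spread).
#' @param pm25Slopes Named per-unit (1 microgram per cubic meter) log-scale
#'   slopes of PM2.5 on the named signatures' activities.
#' @param passivePrevalence,passiveBurdenMultiplier Passive-smoking exposure
#'   prevalence and its multiplier on all activities (burden-only effect).
#' @param telomereBaseline,telomereSlope,telomereSd Log2 tumor/normal
#'   telomere-ratio model: intercept, per-unit PM2.5 slope, residual sd.
#' @param driverGenes Data frame with columns `gene`, `baseline` (prevalence
#'   at the mean exposure) and `logOrPerUnit` (per-unit PM2.5 log odds
#'   ratio).
#' @param seed Root seed.
#' @return A scenario list for [simulateCohort()].
#' @export
simulationScenario <- function(nSamples = 200L,
                               panel = NULL,
                               nSignatures = 5L,
                               baselineMeanlog = log(800),
                               baselineSdlog = 0.5,
                               hypermutatorFraction = 0.03,
                               hypermutatorMultiplier = 8,
                               regions = data.frame(
                                 region = paste0("R", 1:8),
                                 mean = c(8, 10, 12, 15, 22, 26, 30, 35),
                                 sd = 1.5),
                               pm25Slopes = numeric(0),
                               passivePrevalence = 0.5,
                               passiveBurdenMultiplier = 1,
                               telomereBaseline = 0,
                               telomereSlope = 0,
                               telomereSd = 0.3,
                               driverGenes = data.frame(
                                 gene = c("TP53", "EGFR"),
                                 baseline = c(0.3, 0.5),
                                 logOrPerUnit = c(0, 0)),
                               msiOutlier = FALSE,
                               seed = 1L) {
  stopifnot(nSamples >= 2L, hypermutatorFraction >= 0,
            hypermutatorFraction <= 1, passivePrevalence >= 0,
            passivePrevalence <= 1, all(is.finite(pm25Slopes)))
  list(nSamples = as.integer(nSamples), panel = panel,
       nSignatures = as.integer(nSignatures),
       baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
       hypermutatorFraction = hypermutatorFraction,
       hypermutatorMultiplier = hypermutatorMultiplier,
       regions = regions, pm25Slopes = pm25Slopes,
       passivePrevalence = passivePrevalence,
       passiveBurdenMultiplier = passiveBurdenMultiplier,
       telomereBaseline = telomereBaseline, telomereSlope = telomereSlope,
       telomereSd = telomereSd, driverGenes = driverGenes,
       msiOutlier = isTRUE(msiOutlier), seed = as.integer(seed))
}

#' @rdname simulationScenario
#' @param name Preset name: `"null"`, `"pollution"`, `"passive-smoking"` or
#'   `"msi"`.
#' @param ... Overrides passed on to [simulationScenario()].
#' @export
scenarioPreset <- function(name = c("null", "pollution", "passive-smoking",
                                    "msi"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "null" = list(),
    ## slopes echo the reported dose-response magnitudes: a strong effect on
    ## a tobacco-like signature (12 percent per unit), a weak effect on a
    ## clock-like signature (2.3 percent per unit), and telomere shortening
    "pollution" = list(
      pm25Slopes = c(Sig1 = log(1.12), Sig2 = log(1.023)),
      telomereSlope = -0.01,
      driverGenes = data.frame(
        gene = c("TP53", "EGFR", "CTNNB1"),
        baseline = c(0.3, 0.5, 0.08),
        logOrPerUnit = c(log(1.6) / 10, 0, -log(2.5) / 10))),
    ## burden-only effect: 8.3 percent more mutations in exposed subjects
    "passive-smoking" = list(passiveBurdenMultiplier = 1.083),
    "msi" = list(hypermutatorFraction = 0, msiOutlier = TRUE))
  cfg <- utils::modifyList(base, list(...))
  do.call(simulationScenario, cfg)
}

.simCovariates <- function(n) {
  data.frame(
    age = round(pmin(pmax(rnorm(n, 64.1, 10), 21), 92)),
    sex = factor(ifelse(runif(n) < 0.79, "female", "male"),
                 levels = c("female", "male")),
    ancestry = factor(sample(c("EUR", "EAS", "Other"), n, replace = TRUE,
                             prob = c(0.55, 0.40, 0.05)),
                      levels = c("EUR", "EAS", "Other")),
    histology = factor(sample(c("adenocarcinoma", "carcinoid", "other"), n,
                              replace = TRUE, prob = c(0.85, 0.07, 0.08)),
                       levels = c("adenocarcinoma", "carcinoid", "other")),
    purity = pmin(pmax(rnorm(n, 0.5, 0.15), 0.1), 1),
    stringsAsFactors = FALSE)
}

#' Simulate a synthetic cohort
#'
#' Draws covariates, region and diagnosis year per sample; builds annual
#' region-level PM2.5 series and computes each subject's individual estimate
#' with [pm25Estimate()]; draws true signature activities from the log-normal
#' activity model with log-linear PM2.5 effects; applies hypermutator and
#' passive-smoking multipliers; draws the observed catalog as multinomial
#' samples from the activity-weighted mixture of panel profiles; and draws
#' telomere ratios and driver indicators from their models. The full set of
#' planted parameters and per-sample truths is returned as a manifest for
#' recovery tests.
#'
#' @param scenario A [simulationScenario()] or [scenarioPreset()].
#' @param drawCatalogs Draw the observed catalog (disable for association-only
#'   simulations, which need only the truth).
#' @return List with `subjects` (covariates, exposures, burdens, telomere
#'   ratio, driver indicators), `activities` (true signatures x samples
#'   matrix), `catalog` (a [MutationCatalog], or `NULL`), `panel` (the
#'   [SignatureSet]), `series` (the annual exposure series) and `truth` (the
#'   planted parameters).
#' @export
simulateCohort <- function(scenario = simulationScenario(),
                           drawCatalogs = TRUE) {
  n <- scenario$nSamples
  set.seed(.childSeed(scenario$seed, 1L))
  panel <- scenario$panel
  if (is.null(panel))
    panel <- makeSignaturePanel(scenario$nSignatures)
  sigs <- colnames(panel@profiles)
  k <- length(sigs)

  ## covariates, regions, diagnosis years, exposure series
  set.seed(.childSeed(scenario$seed, 2L))
  subjects <- .simCovariates(n)
  subjects$sample_id <- sprintf("S%04d", seq_len(n))
  regions <- scenario$regions
  subjects$region <- sample(regions$region, n, replace = TRUE)
  subjects$diagnosis_year <- sample(2005:2020, n, replace = TRUE)
  years <- 1998:2021
  series <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    data.frame(region = regions$region[i], year = years,
               pm25 = pmax(rnorm(length(years), regions$mean[i],
                                 regions$sd[i]), 0.5))))
  subjects$pm25 <- vapply(seq_len(n), function(i)
    pm25Estimate(subjects$region[i], subjects$diagnosis_year[i], series),
    numeric(1))
  subjects$pm25_group <- dichotomizePm25(subjects$pm25)

  ## true activities: log-normal with log-linear PM2.5 effects, centred so
  ## the baseline refers to the cohort-mean exposure
  set.seed(.childSeed(scenario$seed, 3L))
  pmCentred <- subjects$pm25 - mean(subjects$pm25)
  slopes <- setNames(numeric(k), sigs)
  common <- intersect(names(scenario$pm25Slopes), sigs)
  slopes[common] <- scenario$pm25Slopes[common]
  A <- matrix(0, k, n, dimnames = list(sigs, subjects$sample_id))
  for (s in sigs)
    A[s, ] <- rlnorm(n,
                     meanlog = scenario$baselineMeanlog +
                       slopes[s] * pmCentred,
                     sdlog = scenario$baselineSdlog)
  hyper <- runif(n) < scenario$hypermutatorFraction
  A[, hyper] <- A[, hyper, drop = FALSE] * scenario$hypermutatorMultiplier
  subjects$passive_smoking <- factor(
    ifelse(runif(n) < scenario$passivePrevalence, "exposed", "unexposed"),
    levels = c("unexposed", "exposed"))
  exposed <- subjects$passive_smoking == "exposed"
  A[, exposed] <- A[, exposed, drop = FALSE] *
    scenario$passiveBurdenMultiplier
  ## optional extreme mutation-rich outlier emulating a mismatch-repair
  ## deficient sample; flagged so callers can exercise the MSI rescue rules
  subjects$msi <- rep(FALSE, n)
  if (scenario$msiOutlier) {
    A[, n] <- A[, n] * 25
    subjects$msi[n] <- TRUE
  }
  subjects$hypermutator <- hyper
  subjects$sbs_burden <- colSums(A)

  ## telomere ratio and driver indicators
  set.seed(.childSeed(scenario$seed, 4L))
  subjects$telomere_ratio <- 2^(scenario$telomereBaseline +
                                  scenario$telomereSlope * pmCentred +
                                  rnorm(n, 0, scenario$telomereSd))
  dg <- scenario$driverGenes
  for (i in seq_len(nrow(dg))) {
    eta <- log(dg$baseline[i] / (1 - dg$baseline[i])) +
      dg$logOrPerUnit[i] * pmCentred
    subjects[[paste0("driver_", dg$gene[i])]] <-
      runif(n) < 1 / (1 + exp(-eta))
  }

  ## observed catalog: multinomial draws from the mixture profile
  catalog <- NULL
  if (drawCatalogs) {
    set.seed(.childSeed(scenario$seed, 5L))
    counts <- matrix(0, nrow(panel@profiles), n,
                     dimnames = list(rownames(panel@profiles),
                                     subjects$sample_id))
    mix <- panel@profiles %*% .normalizeColumns(A)
    for (j in seq_len(n))
      counts[, j] <- rmultinom(1, round(sum(A[, j])), mix[, j])
    catalog <- new("MutationCatalog", counts = counts, schema = panel@schema,
                   unclassified = setNames(numeric(n), subjects$sample_id))
  }

  truth <- list(seed = scenario$seed, slopes = slopes,
                baselineMeanlog = scenario$baselineMeanlog,
                baselineSdlog = scenario$baselineSdlog,
                telomereBaseline = scenario$telomereBaseline,
                telomereSlope = scenario$telomereSlope,
                telomereSd = scenario$telomereSd,
                passiveBurdenMultiplier = scenario$passiveBurdenMultiplier,
                hypermutatorFraction = scenario$hypermutatorFraction,
                hypermutatorMultiplier = scenario$hypermutatorMultiplier,
                driverGenes = dg,
                hypermutators = subjects$sample_id[hyper])
  list(subjects = subjects, activities = A, catalog = catalog,
       panel = panel, series = series, truth = truth)
}

#' Write a simulated cohort as a plain-text fixture bundle
#'
#' Writes the catalog and panel in the COSMIC text dialect, the subject table
#' and exposure series as tab-separated tables, and the truth manifest as
#' JSON. Every file round-trips through the package's readers.
#'
#' @param sim Output of [simulateCohort()].
#' @param dir Target directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
writeFixtureBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "catalog.tsv"),
             subjects = file.path(dir, "subjects.tsv"),
             series = file.path(dir, "exposure_series.tsv"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.json"))
  if (!is.null(sim$catalog)) writeCatalog(sim$catalog, paths["catalog"])
  write.table(sim$subjects, paths["subjects"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$series, paths["series"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSignatures(sim$panel, paths["panel"])
  truth <- sim$truth
  ## named vectors must become objects, not bare arrays, to keep their names
  truth$slopes <- as.list(truth$slopes)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
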