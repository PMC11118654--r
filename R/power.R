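#' Injection-simulation configuration
#'
#' Defaults follow the study design for signature-detectability power:
#' injection at 1, 2, 5, 10, 15 and 20 percent of each sample's mutations,
#' 100 simulations per level, 10 percent Gaussian noise, and re-assignment
#' with the relaxed addition penalty.
#'
#' @param levels Injection levels as fractions of each sample's total
#'   mutations. Zero is permitted for false-positive control runs.
#' @param replicates Simulations per level.
#' @param noiseFraction Per-category Gaussian noise, as a fraction of the
#'   category count.
#' @param assignment An [assignmentConfig()].
#' @param target Label of the injected signature.
#' @param minMutations Optional detection threshold on the assigned target
#'   activity (default 0: any strictly positive activity counts as detected).
#' @param seed Base seed; each (level, replicate) derives its own stream.
#' @return A configuration list for [runPowerStudy()].
#' @export
injectionConfig <- function(levels = c(0.01, 0.02, 0.05, 0.10, 0.15, 0.20),
                            replicates = 100L, noiseFraction = 0.10,
                            assignment = assignmentConfig(),
                            target = "SBS4", minMutations = 0,
                            seed = 1L) {
  stopifnot(all(levels >= 0), all(levels < 1), replicates >= 1L,
            noiseFraction >= 0)
  list(levels = levels, replicates = as.integer(replicates),
       noiseFraction = noiseFraction, assignment = assignment,
       target = target, minMutations = minMutations, seed = as.integer(seed))
}

#' Inject a target signature into a mutational profile
#'
#' Removes `round(level * total)` mutations one at a time, each drawn
#' uniformly from the remaining mutations (so counts stay nonnegative), then
#' injects the same number of mutations drawn from the target profile
#' (multinomial), so the pre-noise total equals the original total. Finally
#' each category count is perturbed by zero-mean Gaussian noise with standard
#' deviation `noiseFraction` times the count, rounded to the nearest integer
#' and floored at zero.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param profile Integer count vector over the schema categories.
#' @param target Target signature profile (sums to 1) over the same
#'   categories.
#' @param level Injection level as a fraction of the profile total.
#' @param noiseFraction Noise level (fraction of each category count).
#' @return Perturbed integer count vector; the number of injected mutations is
#'   recorded in attribute `"injected"`.
#' @export
perturbProfile <- function(profile, target, level, noiseFraction = 0.10) {
  profile <- as.numeric(profile)
  total <- sum(profile)
  if (total <= 0) stop("profile total must be positive")
  if (abs(sum(target) - 1) > 1e-6) stop("target profile must sum to 1")
  nInject <- round(level * total)
  if (level > 0 && level * total < 1) {
    warning("injection level below one mutation; injecting 0")
    nInject <- 0L
  }
  out <- profile
  if (nInject > 0) {
    ## uniform draws without replacement from the multiset of mutations
    cum <- cumsum(out)
    picks <- sample.int(total, nInject)
    cats <- findInterval(picks - 1, cum) + 1L
    tab <- tabulate(cats, nbins = length(out))
    out <- out - tab
    out <- out + as.numeric(rmultinom(1, nInject, target))
  }
  if (noiseFraction > 0) {
    noise <- rnorm(length(out), mean = 0, sd = noiseFraction * out)
    out <- pmax(round(out + noise), 0)
  }
  attr(out, "injected") <- nInject
  out
}

#' Signature-injection power study
#'
#' For every injection level and replicate, perturbs each sample's profile
#' with [perturbProfile()] and re-assigns signatures with the target added to
#' the sample's candidate set under the relaxed addition penalty. The target
#' is detected in a sample when its assigned activity exceeds
#' `minMutations` (strictly positive by default, which is well-posed because
#' the sparse assigner returns exact zeros off support).
#'
#' The target must be absent from every input sample under the default
#' penalty; this precondition is verified before the study runs.
#'
#' @param catalog A [MutationCatalog] (or counts matrix) of the samples to
#'   perturb.
#' @param reference A [SignatureSet] containing the candidate and target
#'   profiles.
#' @param candidates Candidate labels offered to every sample (the target is
#'   added automatically), or a list of per-sample label vectors.
#' @param config An [injectionConfig()].
#' @param addPenalty Addition penalty used for re-assignment; defaults to the
#'   configured relaxed penalty.
#' @param checkBaseline Verify the target-absence precondition (disable to
#'   reuse a verified catalog).
#' @return A [PowerResult].
#' @export
runPowerStudy <- function(catalog, reference, candidates,
                          config = injectionConfig(),
                          addPenalty = config$assignment$relaxedAddPenalty,
                          checkBaseline = TRUE) {
  V <- if (is(catalog, "MutationCatalog")) catalog@counts else as.matrix(catalog)
  n <- ncol(V)
  if (!is.list(candidates)) candidates <- rep(list(candidates), n)
  target <- config$target
  if (!target %in% colnames(reference@profiles))
    stop("target signature not in the reference set")
  tProfile <- reference@profiles[, target]

  if (checkBaseline) {
    offending <- character(0)
    for (j in seq_len(n)) {
      cand <- reference@profiles[, unique(c(candidates[[j]], target)),
                                 drop = FALSE]
      act <- assignActivities(V[, j], cand, config$assignment)
      if (act[[target]] > 0) offending <- c(offending, colnames(V)[j])
    }
    if (length(offending))
      stop("target signature already present in: ",
           paste(offending, collapse = ", "))
  }

  det <- vector("list", length(config$levels) * config$replicates)
  frac <- vector("list", length(det))
  idx <- 0L
  for (li in seq_along(config$levels)) {
    level <- config$levels[li]
    for (r in seq_len(config$replicates)) {
      set.seed(.childSeed(config$seed, 1000L * li + r))
      detected <- logical(n)
      injectedFrac <- numeric(n)
      activity <- numeric(n)
      for (j in seq_len(n)) {
        pert <- perturbProfile(V[, j], tProfile, level, config$noiseFraction)
        cand <- reference@profiles[, unique(c(candidates[[j]], target)),
                                   drop = FALSE]
        act <- assignActivities(pert, cand, config$assignment,
                                addPenalty = addPenalty)
        activity[j] <- act[[target]]
        detected[j] <- act[[target]] > config$minMutations
        injectedFrac[j] <- attr(pert, "injected") / max(sum(V[, j]), 1)
      }
      idx <- idx + 1L
      det[[idx]] <- data.frame(level = level, replicate = r,
                               sample = colnames(V),
                               injected = injectedFrac,
                               activity = activity,
                               detected = detected)
      frac[[idx]] <- data.frame(level = level, replicate = r,
                                fraction = mean(detected))
    }
  }
  new("PowerResult",
      detections = do.call(rbind, det),
      fractions = do.call(rbind, frac),
      levels = config$levels, target = target)
}

#' Summarize a power study
#'
#' @param result A [PowerResult].
#' @return List with `byLevel` (mean, sd and quartiles of the detection
#'   fraction per level), `fractions` (the boxplot-ready level x replicate
#'   table) and `contributions` (samples x (level, replicate) matrix of
#'   injected contributions, with detection encoded by sign: negative entries
#'   mark undetected samples).
#' @export
summarizePower <- function(result) {
  fr <- result@fractions
  byLevel <- do.call(rbind, lapply(split(fr$fraction, fr$level), function(x) {
    data.frame(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
               q25 = unname(quantile(x, 0.25)),
               median = median(x),
               q75 = unname(quantile(x, 0.75)))
  }))
  byLevel <- cbind(level = as.numeric(rownames(byLevel)), byLevel)
  rownames(byLevel) <- NULL

  d <- result@detections
  key <- paste(d$level, d$replicate, sep = ":")
  samples <- unique(d$sample)
  cols <- unique(key)
  contrib <- matrix(NA_real_, length(samples), length(cols),
                    dimnames = list(samples, cols))
  contrib[cbind(match(d$sample, samples), match(key, cols))] <-
    ifelse(d$detected, d$injected, -d$injected)
  list(byLevel = byLevel, fractions = fr, contributions = contrib)
}
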