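test_that("single-signature profiles are assigned exactly", {
  set.seed(61)
  panel <- makeSignaturePanel(4, separation = 0.4)
  W <- signatureProfiles(panel)
  act <- assignActivities(1000 * W[, 2], panel)
  expect_equal(unname(act["Sig2"]), 1000, tolerance = 1e-6)
  expect_identical(unname(act[c("Sig1", "Sig3", "Sig4")]), c(0, 0, 0))
  expect_gte(attr(act, "cosine"), 1 - 1e-9)
  ## an all-zero profile yields zero activities, not an error
  z <- assignActivities(numeric(96), panel)
  expect_identical(as.numeric(z), rep(0, 4))
})

test_that("a hand-checkable two-signature fit has zero residual", {
  cand <- matrix(c(0.5, 0.5, 0, 0.5, 0, 0.5), 3, 2,
                 dimnames = list(NULL, c("a", "b")))
  act <- assignActivities(c(6, 4, 2), cand,
                          assignmentConfig(addPenalty = 0.01))
  expect_equal(as.numeric(act), c(8, 4), tolerance = 1e-9)
  expect_equal(attr(act, "cosine"), 1, tolerance = 1e-12)
})

test_that("planted activities are recovered with sparse off-support zeros", {
  set.seed(62)
  panel <- makeSignaturePanel(5, separation = 0.4)
  W <- signatureProfiles(panel)
  relerr <- c(); allZero <- logical(0)
  for (j in 1:50) {
    support <- sort(sample(5, sample(2:4, 1)))
    act <- stats::setNames(numeric(5), colnames(W))
    act[support] <- stats::rlnorm(length(support), log(800), 0.5)
    prof <- as.numeric(rmultinom(1, round(sum(act)),
                                 W %*% (act / sum(act))))
    est <- assignActivities(prof, W)
    big <- which(act >= 300)
    relerr <- c(relerr, abs(est[big] - act[big]) / act[big])
    allZero <- c(allZero, all(est[setdiff(1:5, support)] == 0))
  }
  expect_lte(median(relerr), 0.10)
  expect_gte(mean(allZero), 0.95)
})

test_that("stagewise selection matches exhaustive support enumeration", {
  set.seed(63)
  panel <- makeSignaturePanel(6, separation = 0.4)
  W <- signatureProfiles(panel)
  for (i in 1:15) {
    S <- sort(sample(6, sample(2:3, 1)))
    act <- stats::setNames(numeric(6), colnames(W))
    act[S] <- runif(length(S), 800, 2000)
    prof <- as.numeric(W %*% act)
    mine <- assignActivities(prof, W, assignmentConfig(addPenalty = 0.02))
    orc <- oracleSparseFit(prof, W, 0.02)
    expect_equal(as.numeric(mine), as.numeric(orc$x), tolerance = 1e-5)
  }
})

test_that("lowering the addition penalty never shrinks the support", {
  set.seed(64)
  panel <- makeSignaturePanel(6, separation = 0.4)
  W <- signatureProfiles(panel)
  for (j in 1:8) {
    S <- sort(sample(6, 3))
    act <- stats::setNames(numeric(6), colnames(W))
    act[S] <- runif(3, 300, 1500)
    prof <- as.numeric(rmultinom(1, round(sum(act)), W %*% (act / sum(act))))
    sizes <- vapply(c(0.10, 0.05, 0.02, 0.01), function(pen) {
      sum(assignActivities(prof, W,
                           assignmentConfig(addPenalty = pen)) > 0)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("de novo decomposition recovers blends and honors exclusions", {
  set.seed(65)
  panel <- makeSignaturePanel(6, separation = 0.4,
                              names = c("SBS1", "SBS4", "SBS5", "SBS23",
                                        "SBS32", "SBS40a"),
                              exclusions = c("SBS23", "SBS32"))
  W <- signatureProfiles(panel)
  ## identity decomposition
  dec <- decomposeSignatures(W[, "SBS5", drop = FALSE], panel)
  expect_equal(unname(dec$SBS5$weights["SBS5"]), 1, tolerance = 1e-6)
  expect_gte(dec$SBS5$cosine, 0.999)
  ## 0.7 / 0.3 blend
  blend <- matrix(0.7 * W[, "SBS4"] + 0.3 * W[, "SBS40a"], ncol = 1,
                  dimnames = list(rownames(W), "D1"))
  decB <- decomposeSignatures(blend, panel)$D1
  expect_lte(abs(unname(decB$weights["SBS4"]) - 0.7), 0.05)
  expect_lte(abs(unname(decB$weights["SBS40a"]) - 0.3), 0.05)
  ## excluded signatures can never carry weight, even for their own profile
  decX <- decomposeSignatures(W[, "SBS23", drop = FALSE], panel)$SBS23
  expect_false("SBS23" %in% names(decX$weights))
  expect_false("SBS32" %in% names(decX$weights))
})

test_that("candidate sets follow the rescue and exclusion rules", {
  rules <- defaultAssignmentRules()
  set.seed(66)
  ref <- makeSignaturePanel(
    10, separation = 0.3,
    names = c("SBS1", "SBS3", "SBS5", "SBS92", "SBS33", "SBS6", "SBS23",
              "SBS32", "SBS14", "SBS15"),
    exclusions = rules$exclusions, rescueRules = rules$rescueRules,
    msiSet = rules$msiSet)
  base <- c("SBS1", "SBS5", "SBS23")
  ## ID3 present, ID6 absent: SBS92 in, SBS3 out
  cs <- buildCandidateSets(base, c(ID6 = 0, ID3 = 120), FALSE, ref)
  expect_true("SBS92" %in% cs)
  expect_false("SBS3" %in% cs)
  ## no triggers: base set unchanged apart from exclusions
  cs0 <- buildCandidateSets(base, c(ID6 = 0, ID3 = 0), FALSE, ref)
  expect_setequal(cs0, c("SBS1", "SBS5"))
  ## MSI flag admits the mismatch-repair set and SBS33
  csM <- buildCandidateSets(base, c(ID6 = 0, ID3 = 0), TRUE, ref)
  expect_true(all(c("SBS33", rules$msiSet) %in% csM))
  ## unknown trigger label
  expect_error(buildCandidateSets(base, c(ID9 = 5), FALSE, ref),
               "configuration error")
})

test_that("mutation posteriors normalize and reproduce activities", {
  set.seed(67)
  panel <- makeSignaturePanel(4, separation = 0.4)
  A <- matrix(c(500, 300, 0, 100,
                800, 0, 0, 0), 4, 2,
              dimnames = list(signatureNames(panel), c("s1", "s2")))
  mp <- mutationProbabilities(A, panel)
  P <- mp$probabilities
  ## rows with nonzero reconstruction sum to 1 within 1e-9
  for (j in 1:2) {
    sums <- apply(P[, , j], 1, sum)
    nz <- mp$reconstructed[, j] > 0
    expect_true(all(abs(sums[nz] - 1) < 1e-9))
    expect_true(all(is.na(sums[!nz])))
  }
  ## algebraic identity: sum_c P(s|c,j) R[c,j] = A[s,j]
  for (j in 1:2) {
    back <- colSums(P[, , j] * mp$reconstructed[, j], na.rm = TRUE)
    expect_equal(back, A[, j], tolerance = 1e-6, ignore_attr = TRUE)
  }
  ## single-signature sample: probability 1 wherever the signature acts
  p2 <- P[, "Sig1", 2]
  expect_true(all(p2[!is.na(p2)] == 1))
})

test_that("a two-signature posterior is hand-checkable", {
  prof <- matrix(c(0.01, 0.99, 0.09, 0.91), 2, 2,
                 dimnames = list(c("c1", "c2"), c("X", "Y")))
  s <- new("ContextSchema", schemaId = "TOY", categories = c("c1", "c2"),
           parameters = list())
  ref <- new("SignatureSet", schema = s, profiles = prof,
             exclusions = character(0), rescueRules = character(0),
             msiSet = character(0))
  A <- matrix(c(90, 10), 2, 1, dimnames = list(c("X", "Y"), "j"))
  mp <- mutationProbabilities(A, ref)
  ## 0.01*90 / (0.01*90 + 0.09*10) = 0.5
  expect_equal(unname(mp$probabilities["c1", "X", "j"]), 0.5,
               tolerance = 1e-12)
})

test_that("driver attribution thresholds are strict and proportions normalize", {
  prof <- matrix(c(0.2, 0.8, 0.2, 0.8), 2, 2,
                 dimnames = list(c("c1", "c2"), c("A", "B")))
  s <- new("ContextSchema", schemaId = "TOY", categories = c("c1", "c2"),
           parameters = list())
  ref <- new("SignatureSet", schema = s, profiles = prof,
             exclusions = character(0), rescueRules = character(0),
             msiSet = character(0))
  ## equal activities and identical profiles: posterior exactly 0.5
  A <- matrix(c(100, 100), 2, 1, dimnames = list(c("A", "B"), "j"))
  mp <- mutationProbabilities(A, ref)
  drv <- data.frame(sample = "j", category = "c1", gene = "TP53")
  att <- attributeDrivers(drv, mp, threshold = 0.5)
  expect_equal(att$mutations$probability, 0.5)
  expect_false(att$mutations$confident)        # strictly above 50% required
  expect_equal(att$mutations$signature, "A")   # lexicographic tie-break
  expect_equal(unname(rowSums(att$geneProportions)), 1, tolerance = 1e-9)
  ## single-signature sample: every driver confident at probability 1
  A2 <- matrix(c(200, 0), 2, 1, dimnames = list(c("A", "B"), "j"))
  att2 <- attributeDrivers(drv, mutationProbabilities(A2, ref), 0.5)
  expect_true(att2$mutations$confident)
  expect_equal(att2$mutations$probability, 1)
  expect_error(attributeDrivers(
    data.frame(sample = "j", category = "c9", gene = "x"), mp),
    "missing context")
})
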