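test_that("pseudo-absence sets honor count, spacing and determinism", {
  land <- smallLandscape()
  pa <- samplePseudoAbsences(land, n = 10, minDistM = 1000, nSets = 3, seed = 4)
  expect_length(pa, 3)
  for (s in pa) {
    expect_equal(nrow(s), 10)
    expect_gte(min(dist(s[, c("x", "y")])), 1000)
  }
  expect_false(identical(pa[[1]]$x, pa[[2]]$x))  # sets are independent draws
  pa2 <- samplePseudoAbsences(land, n = 10, minDistM = 1000, nSets = 3, seed = 4)
  expect_identical(pa, pa2)
  # shortfall warns but does not crash
  expect_warning(short <- samplePseudoAbsences(land, n = 5000, nSets = 1,
                                               seed = 1), "shortfall")
  expect_lte(nrow(short[[1]]), 1600)
  expect_error(samplePseudoAbsences(land, n = 0, seed = 1), "positive")
  # spacing wider than a cell uses the greedy sampler
  wide <- samplePseudoAbsences(land, n = 20, minDistM = 3000, nSets = 1,
                               seed = 2)
  expect_gte(min(dist(wide[[1]][, c("x", "y")])), 3000)
})

test_that("TSS matches its confusion-matrix definition", {
  # perfect separation -> TSS 1 at the separating threshold
  expect_equal(tss(c(0, 0, 1, 1), c(.1, .2, .8, .9), 0.5), 1)
  expect_equal(maxTss(c(0, 0, 1, 1), c(.1, .2, .8, .9))$tss, 1)
  # scores carrying no information -> TSS 0
  expect_equal(tss(c(0, 1, 0, 1), rep(0.5, 4), 0.5), 0)
  expect_equal(maxTss(c(0, 1, 0, 1), rep(0.5, 4))$tss, 0)
  # hand-computed confusion: TP 8, FN 2, TN 9, FP 1 -> 0.8 + 0.9 - 1
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.05, 9), 0.95)
  expect_equal(tss(labels, scores, 0.5), 0.7)
  expect_error(tss(c(1, 1), c(.2, .3), .5), "both classes")
  expect_error(maxTss(c(0, 0), c(.2, .3)), "both classes")
})

test_that("maxTss equals an exhaustive threshold scan", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)   # ties on purpose
    naive <- max(vapply(unique(scores), function(t) tss(labels, scores, t),
                        numeric(1)))
    expect_equal(maxTss(labels, scores)$tss, naive)
  }
})

test_that("candidate count equals sets x learners x replicates, failures kept", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 60, nSets = 2, seed = 3)
  one <- fitCandidates(occ, ps, pa[1], roster = "constant", nReplicates = 1,
                       seed = 1)
  expect_length(one$candidates, 1)
  many <- fitCandidates(occ, ps, pa, roster = c("glm", "cta"),
                        nReplicates = 3, seed = 1)
  expect_length(many$candidates, 2 * 2 * 3)
  ev <- candidateEvals(many)
  expect_equal(nrow(ev), 12)
  expect_true(all(ev$tss >= -1 & ev$tss <= 1, na.rm = TRUE))
  expect_true(all(ev$roc >= 0 & ev$roc <= 1, na.rm = TRUE))
  # a failing learner is recorded, not fatal
  bad <- list(boom = list(fit = function(X, y, w) stop("nope"),
                          predict = function(m, X) rep(0, nrow(X))))
  withBad <- fitCandidates(occ, ps, pa[1], roster = bad, nReplicates = 2,
                           seed = 1)
  expect_length(withBad$candidates, 2)
  expect_true(all(candidateEvals(withBad)$status == "failed"))
  expect_error(buildEnsemble(withBad, ps), "no ensemble members")
})

test_that("fits are deterministic under one seed", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 80, nSets = 1, seed = 5)
  a <- candidateEvals(fitCandidates(occ, ps, pa, roster = c("glm", "ann"),
                                    nReplicates = 2, seed = 9))
  b <- candidateEvals(fitCandidates(occ, ps, pa, roster = c("glm", "ann"),
                                    nReplicates = 2, seed = 9))
  expect_identical(a, b)
})

test_that("ensemble weighting, filtering and convexity follow the TSS rule", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 120, nSets = 1, seed = 6)
  cands <- fitCandidates(occ, ps, pa, roster = c("glm", "cta", "ann"),
                         nReplicates = 4, seed = 2)
  ev <- candidateEvals(cands)
  tmin <- median(ev$tss, na.rm = TRUE)   # ensures a strict subset enters
  ens <- buildEnsemble(cands, ps, tssMin = tmin)
  keptTss <- ev$tss[ev$status == "ok" & ev$tss > tmin]
  expect_length(ens@members, length(keptTss))
  expect_equal(sort(ens@weights), sort(keptTss / sum(keptTss)))
  expect_equal(sum(ens@weights), 1)

  # weights 0.9 / 0.85 -> 0.9/1.75, 0.85/1.75 (normalization arithmetic)
  expect_equal(c(0.9, 0.85) / sum(c(0.9, 0.85)),
               c(0.9 / 1.75, 0.85 / 1.75))

  # convexity: ensemble prediction lies within the member envelope
  X <- as.matrix(ens@evalData[, -1])
  preds <- sapply(ens@members, function(m) m$predictFun(m$model, X))
  e <- ensemblePredict(ens, X)
  expect_true(all(e >= apply(preds, 1, min) - 1e-12))
  expect_true(all(e <= apply(preds, 1, max) + 1e-12))

  # binary layer = suitability thresholded at the ensemble max-TSS cutoff
  s <- values(suitabilityLayer(ens)); b <- values(binaryLayer(ens))
  expect_true(all((s >= ensembleThreshold(ens)) == (b == 1), na.rm = TRUE))
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
})

test_that("a single strong member is the whole ensemble", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 100, nSets = 1, seed = 8)
  cands <- fitCandidates(occ, ps, pa, roster = c("glm", "constant"),
                         nReplicates = 1, seed = 3)
  ev <- candidateEvals(cands)
  # constant learner has TSS 0; pick a cutoff that excludes it
  cut <- max(0.05, ev$tss[ev$learner == "glm"] - 0.01)
  ens <- buildEnsemble(cands, ps, tssMin = cut)
  expect_length(ens@members, 1)
  expect_equal(ens@members[[1]]$learner, "glm")
  expect_equal(ens@weights, 1)
})

test_that("importance is zero for unused variables and ranks the causal one", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 100, nSets = 1, seed = 2)
  # constant members use no variable at all -> all importances 0
  cands0 <- fitCandidates(occ, ps, pa, roster = "constant", nReplicates = 2,
                          seed = 4)
  ens0 <- buildEnsemble(cands0, ps, tssMin = -1)
  expect_true(all(variableImportance(ens0, nPerm = 2, seed = 1) == 0))
  # fixture taxon is driven by elevation only
  cands <- fitCandidates(occ, ps, pa, roster = "glm", nReplicates = 3,
                         seed = 4)
  ens <- buildEnsemble(cands, ps, tssMin = 0.1)
  imp <- variableImportance(ens, nPerm = 3, seed = 1)
  expect_true(all(imp >= 0 & imp <= 1))
  expect_equal(names(which.max(imp)), "elevation")
  expect_gt(max(imp), 0)
})

test_that("response curves span the range and track monotone truth", {
  land <- smallLandscape()
  occ <- cleanedFixtureOccs()
  ps <- derivePredictors(land)
  pa <- samplePseudoAbsences(land, n = 100, nSets = 1, seed = 2)
  cands <- fitCandidates(occ, ps, pa, roster = "glm", nReplicates = 3,
                         seed = 4)
  ens <- buildEnsemble(cands, ps, tssMin = 0.1)
  rc <- responseCurves(ens, ps, "elevation", nPoints = 25)
  ev <- values(ps@layers$elevation)
  expect_equal(range(rc$value), range(ev[is.finite(ev)]))
  # positive dependence: allow only tiny non-monotonic wiggles
  expect_true(all(diff(rc$suitability) > -0.02))
  expect_gt(rc$suitability[25], rc$suitability[1])
  expect_error(responseCurves(ens, ps, "nope"), "unknown variable")

  # constant members give a flat curve
  cands0 <- fitCandidates(occ, ps, pa, roster = "constant", nReplicates = 1,
                          seed = 4)
  ens0 <- buildEnsemble(cands0, ps, tssMin = -1)
  rc0 <- responseCurves(ens0, ps, "elevation", nPoints = 10)
  expect_equal(diff(range(rc0$suitability)), 0)
})
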