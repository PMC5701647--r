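test_that("node table satisfies homotopic-pairing invariants", {
  nt <- aal90NodeTable()
  expect_equal(nrow(nt), 90)
  expect_equal(sum(nt$hemisphere == "L"), 45)
  expect_equal(sum(nt$hemisphere == "R"), 45)
  expect_silent(validateNodeTable(nt))
  # abbreviations unique within hemisphere, pair indices a bijection
  expect_equal(anyDuplicated(nt$abbr[nt$hemisphere == "L"]), 0L)
  expect_setequal(nt$pairIndex[nt$hemisphere == "L"], 1:45)

  bad <- nt
  bad$pairIndex[1] <- 2L
  expect_error(validateNodeTable(bad), "bijection")
  bad2 <- nt[-1, ]
  expect_error(validateNodeTable(bad2), "same size")
})

test_that("mirror-null: zero noise and null spec give exactly mirrored hemispheres", {
  nt <- aal90NodeTable()
  cm <- simulateStructuralConnectome(
    nt, structuralParams(noiseSd = 0), asymmetrySpec(), seed = 7)
  hn <- splitHemispheres(cm, nt)
  expect_identical(weights(hn$L), weights(hn$R) * 1)
  expect_true(all(weights(cm) >= 0))
  expect_equal(diag(weights(cm)), setNames(rep(0, 90), nt$label))
})

test_that("structural generator is deterministic under a fixed seed", {
  a <- simulateStructuralConnectome(seed = 42)
  b <- simulateStructuralConnectome(seed = 42)
  expect_identical(weights(a), weights(b))
  c <- simulateStructuralConnectome(seed = 43)
  expect_false(identical(weights(a), weights(c)))
})

test_that("global scale delta multiplies every left weight by 1 + delta", {
  nt <- aal90NodeTable()
  cm <- simulateStructuralConnectome(
    nt, structuralParams(noiseSd = 0),
    asymmetrySpec(globalScaleDelta = 0.1, direction = "leftward"), seed = 3)
  hn <- splitHemispheres(cm, nt)
  expect_equal(weights(hn$L), weights(hn$R) * 1.1, tolerance = 1e-12)

  cmR <- simulateStructuralConnectome(
    nt, structuralParams(noiseSd = 0),
    asymmetrySpec(globalScaleDelta = 0.1, direction = "rightward"), seed = 3)
  hnR <- splitHemispheres(cmR, nt)
  expect_equal(weights(hnR$R), weights(hnR$L) * 1.1, tolerance = 1e-12)
})

test_that("nodal and edge effects scale exactly the targeted entries", {
  nt <- aal90NodeTable()
  spec <- asymmetrySpec(
    nodalTargets = data.frame(pairIndex = 3L, delta = 0.2),
    edgeSubnetwork = data.frame(i = 10L, j = 11L, delta = 0.5))
  cm <- simulateStructuralConnectome(nt, structuralParams(noiseSd = 0),
                                     spec, seed = 11)
  hn <- splitHemispheres(cm, nt)
  l <- weights(hn$L); r <- weights(hn$R)
  expect_equal(l[3, -3], r[3, -3] * 1.2, tolerance = 1e-12)
  expect_equal(l[10, 11], r[10, 11] * 1.5, tolerance = 1e-12)
  expect_gt(r[10, 11], 0)  # spec edges forced into the template
  untouched <- setdiff(1:45, c(3, 10, 11))
  expect_equal(l[untouched, untouched], r[untouched, untouched])
})

test_that("effect monotonicity: larger delta gives larger mean L-R difference", {
  nt <- aal90NodeTable()
  diffs <- vapply(c(0, 0.1, 0.2, 0.3), function(d) {
    cm <- simulateStructuralConnectome(
      nt, structuralParams(noiseSd = 0.05),
      asymmetrySpec(globalScaleDelta = d), seed = 5)
    hn <- splitHemispheres(cm, nt)
    mean(weights(hn$L) - weights(hn$R))
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("simulated time series recover the generating covariance", {
  nt <- aal90NodeTable()
  ts <- simulateRoiTimeseries(nt, functionalCovSpec(moduleSize = 5,
                                                    rhoIn = 0.6,
                                                    rhoOut = 0.1),
                              nTimepoints = 2000, seed = 9)
  expect_equal(dim(ts), c(2000, 90))
  r <- cor(ts[, 1:45])  # left hemisphere, pairIndex order
  mod <- ceiling(1:45 / 5)
  within <- r[outer(mod, mod, `==`) & upper.tri(r)]
  between <- r[outer(mod, mod, `!=`) & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.6), 0.05)
  expect_lt(abs(mean(between) - 0.1), 0.05)
  # seeded determinism
  ts2 <- simulateRoiTimeseries(nt, functionalCovSpec(moduleSize = 5,
                                                     rhoIn = 0.6,
                                                     rhoOut = 0.1),
                               nTimepoints = 2000, seed = 9)
  expect_identical(ts, ts2)
})

test_that("functional asymmetry spec raises left-block correlations", {
  nt <- aal90NodeTable()
  ts <- simulateRoiTimeseries(nt, functionalCovSpec(),
                              nTimepoints = 1000,
                              spec = asymmetrySpec(globalScaleDelta = 0.3),
                              seed = 2)
  rL <- cor(ts[, 1:45]); rR <- cor(ts[, 46:90])
  expect_gt(mean(rL[upper.tri(rL)]), mean(rR[upper.tri(rR)]))
})

test_that("behavior coupling attains the target correlation", {
  # exact linearity at r = 1
  as1 <- rnorm(100)
  b1 <- generateBehavior(as1, couplingR = 1, coupled = "MoCA", seed = 1)
  expect_equal(cor(b1$MoCA, as1), 1, tolerance = 1e-12)
  # Monte-Carlo recovery at r = 0.3
  set.seed(10)
  as2 <- rnorm(2000)
  b2 <- generateBehavior(as2, couplingR = 0.3, coupled = "RAVLT_ir",
                         seed = 2)
  expect_lt(abs(cor(b2$RAVLT_ir, as2) - 0.3), 0.05)
  # uncoupled scores are independent noise
  expect_lt(abs(cor(b2$MMSE, as2)), 3 / sqrt(2000))
  expect_error(generateBehavior(c(1, 2), couplingR = 0.5), "3 subjects")
})

test_that("cohort bundle has the documented shape and determinism", {
  cb <- simulateCohort(4, seed = 123)
  expect_s3_class(cb, "CohortBundle")
  expect_length(cb$subjects, 4)
  expect_equal(ncol(cb$behavior), 13)  # subject_id + 12 battery scores
  expect_true(all(c("RAVLT_ir", "MoCA", "CTT2") %in% names(cb$behavior)))
  expect_true(all(cb$covariates$age >= 60 & cb$covariates$age <= 82))
  expect_true(all(cb$covariates$handedness == "R"))
  expect_length(cb$truth$trueAS, 4)

  cb2 <- simulateCohort(4, seed = 123)
  expect_identical(weights(cb$subjects[[2]]$structural),
                   weights(cb2$subjects[[2]]$structural))
  expect_identical(cb$behavior, cb2$behavior)
  expect_error(simulateCohort(1, seed = 1), "at least 2")
})

test_that("pairedEffectDelta yields the requested homotopic effect size", {
  s <- 0.1
  delta <- pairedEffectDelta(1.0, s)
  # Monte-Carlo check of the closed form on the generating model
  set.seed(4)
  eL <- exp(rnorm(2e5, 0, s)); eR <- exp(rnorm(2e5, 0, s))
  d <- eL * (1 + delta) - eR
  expect_lt(abs(mean(d) / sd(d) - 1.0), 0.02)
})
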