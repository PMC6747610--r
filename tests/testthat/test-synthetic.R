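test_that("generators are deterministic given the scenario seed", {
  a <- makeRelaxationInputs(germlineScenario(3, nResidues = 4))
  b <- makeRelaxationInputs(germlineScenario(3, nResidues = 4))
  expect_identical(a, b)
  expect_identical(makeCpmgInputs(germlineScenario(3, nResidues = 3)),
                   makeCpmgInputs(germlineScenario(3, nResidues = 3)))
  expect_identical(makeHdxInputs(germlineScenario(3, nResidues = 4)),
                   makeHdxInputs(germlineScenario(3, nResidues = 4)))
  expect_identical(makeVectorTrajectories(germlineScenario(3),
                                          nFrames = 200, nResidues = 2),
                   makeVectorTrajectories(germlineScenario(3),
                                          nFrames = 200, nResidues = 2))
  # different seeds differ
  c1 <- makeRelaxationInputs(germlineScenario(4, nResidues = 4))
  expect_false(identical(a$r1Series[[1]]@intensities,
                         c1$r1Series[[1]]@intensities))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(makeRelaxationInputs(germlineScenario(9, nResidues = 2)))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise relaxation inputs refit to the emitted ground truth", {
  scn <- germlineScenario(6, nResidues = 5,
                          noise = c(intensity = 1e-9, r1 = 0.05, r2 = 0.4,
                                    noe = 0.03, r2eff = 0.3, hdx = 0.02,
                                    dls = 0))
  g <- makeRelaxationInputs(scn)
  for (i in seq_along(g$r1Series)) {
    f <- fitMonoexponential(g$r1Series[[i]], nReplicas = 0)
    expect_equal(f@rate, g$truth$r1[i], tolerance = 1e-6)
    f2 <- fitMonoexponential(g$r2Series[[i]], nReplicas = 0)
    expect_equal(f2@rate, g$truth$r2[i], tolerance = 1e-6)
  }
  noe <- g$noePairs$i_sat / g$noePairs$i_ref
  expect_equal(noe, g$truth$noe, tolerance = 1e-6)
})

test_that("scenario cohorts carry the configured mean order parameter", {
  g <- makeRelaxationRates(germlineScenario(10, nResidues = 60))
  expect_equal(mean(g$truth$s2), 0.84, tolerance = 1e-9)
  m <- makeRelaxationRates(mutantScenario(10, nResidues = 60))
  expect_equal(mean(m$truth$s2), 0.88, tolerance = 1e-9)
})

test_that("variant contrast scales exchange and lifetimes as configured", {
  ref <- germlineScenario(2)
  var <- applyVariantContrast(ref)
  expect_equal(var@exchange@kex, 2008, tolerance = 1e-9)
  expect_equal(var@exchange@pb, 0.10, tolerance = 1e-9)
  expect_equal(var@exchange@dw, ref@exchange@dw)
  expect_equal(exp(var@hdxMeanlog - ref@hdxMeanlog), 1 / 6,
               tolerance = 1e-12)
  expect_equal(var@s2Mean - ref@s2Mean, 0.04, tolerance = 1e-12)
})

test_that("null CPMG scenario produces no significant dispersion", {
  g <- makeCpmgInputs(germlineScenario(5, nResidues = 6, rexFraction = 0))
  sig <- vapply(g$profiles, function(p) rexSize(p)$significant,
                logical(1))
  expect_false(any(sig))
})

test_that("CPMG truth sidecar matches the profile forward model", {
  scn <- germlineScenario(7, nResidues = 3, rexFraction = 1,
                          noise = c(intensity = 0.01, r1 = 0.05, r2 = 0.4,
                                    noe = 0.03, r2eff = 1e-9, hdx = 0.02,
                                    dls = 0))
  g <- makeCpmgInputs(scn, fields = 700e6)
  for (i in seq_along(g$profiles)) {
    p <- g$profiles[[i]]
    tr <- g$truth[g$truth$residue_id == p@residueId, ]
    pred <- carverRichardsR2eff(TwoSiteParams(tr$kex, tr$pb,
                                              max(tr$dw, 1e-12), tr$r20),
                                p@nuCpmg, p@field1H, p@tRelax)
    if (tr$dw == 0) pred <- rep(tr$r20, length(p@nuCpmg))
    expect_equal(p@r2eff, pred, tolerance = 1e-6)
  }
})

test_that("HDX censoring edge: effectively static residues never class low", {
  scn <- germlineScenario(5, nResidues = 6, hdxMeanlog = log(1e6),
                          hdxSdlog = 1e-6)
  g <- makeHdxInputs(scn)
  expect_true(all(g$truth$class_ref == "gt_600s"))
  fits <- lapply(g$reference$slow, fitExchangeDecay, nReplicas = 0)
  cls <- vapply(fits, `[[`, "", "lifetimeClass")
  # nothing decays within 12 h; fits either censor at plateau-like flat
  # traces or return very long lifetimes, never a fast class
  expect_false(any(cls %in% c("lt_100s", "100_600s")))
})

test_that("DLS generator round trip and noiseless residuals", {
  m <- makeDlsTrace(2.1e-9)
  f <- cumulantFit(m)
  expect_equal(f$radius, 2.1e-9, tolerance = 0.02)
  pred <- exp(-2 * attr(m, "truth")$gamma * m@lagTimes)
  expect_lt(max(abs(pred - m@g2Minus1)), 1e-10)
  mn <- makeDlsTrace(2.1e-9, noise = 1e-4, seed = 3)
  expect_false(identical(mn@g2Minus1, m@g2Minus1))
})
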