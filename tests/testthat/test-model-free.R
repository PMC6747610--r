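spinFx <- SpinParameters()

test_that("spectral density closed-form values and limits", {
  # rigid limit at zero frequency
  p <- ModelFreeParams(1, s2 = 1, tm = 10e-9)
  expect_equal(spectralDensity(p, 0), 0.4 * 10e-9)
  # direct evaluation of the model-1 form
  p2 <- ModelFreeParams(1, s2 = 0.84, tm = 10.7e-9)
  expect_equal(spectralDensity(p2, 0), 0.4 * 0.84 * 10.7e-9)
  # model 2 with te = 0 collapses onto model 1
  w <- c(0, 1e8, 5e8, 4e9)
  p3 <- ModelFreeParams(2, s2 = 0.7, te = 0, tm = 8e-9)
  p1 <- ModelFreeParams(1, s2 = 0.7, tm = 8e-9)
  expect_equal(spectralDensity(p3, w), spectralDensity(p1, w))
  # J is non-increasing in |omega|
  for (m in 1:5) {
    p <- switch(m, ModelFreeParams(1, s2 = 0.8, tm = 1e-8),
                ModelFreeParams(2, s2 = 0.8, te = 5e-10, tm = 1e-8),
                ModelFreeParams(3, s2 = 0.8, rex = 3, tm = 1e-8),
                ModelFreeParams(4, s2 = 0.8, te = 2e-10, rex = 3, tm = 1e-8),
                ModelFreeParams(5, s2f = 0.9, s2s = 0.85, te = 1e-9,
                                tm = 1e-8))
    J <- spectralDensity(p, seq(0, 5e9, length.out = 40))
    expect_true(all(diff(J) <= 1e-15))
    expect_true(all(J >= 0))
  }
})

test_that("forward rates match an independent brute-force evaluation", {
  for (cfg in list(c(0.84, 10.7e-9), c(0.88, 11e-9), c(0.5, 7.5e-9))) {
    p <- ModelFreeParams(1, s2 = cfg[1], tm = cfg[2])
    expect_equal(forwardRates(p, spinFx),
                 bruteForceRates(cfg[1], cfg[2]), tolerance = 1e-12)
  }
})

test_that("Rex adds to R2 only", {
  p0 <- ModelFreeParams(3, s2 = 0.85, rex = 0, tm = 1e-8)
  p5 <- ModelFreeParams(3, s2 = 0.85, rex = 5, tm = 1e-8)
  r0 <- forwardRates(p0, spinFx); r5 <- forwardRates(p5, spinFx)
  expect_equal(r5[["r2"]] - r0[["r2"]], 5)
  expect_equal(r5[["r1"]], r0[["r1"]])
  expect_equal(r5[["noe"]], r0[["noe"]])
})

test_that("rates vanish and NOE hits extreme narrowing as S2 -> 0", {
  p <- ModelFreeParams(2, s2 = 1e-9, te = 1e-14, tm = 1e-8)
  r <- forwardRates(p, spinFx)
  expect_lt(r[["r1"]], 1e-3)
  expect_lt(r[["r2"]], 1e-3)
  # with S2 = 0 and te -> 0 the spectral density becomes flat, so the
  # NOE tends to the extreme-narrowing limit
  # 1 + (gH/gN) (d^2/4) 5 / ((d^2/4) 10 + c^2), strongly negative for
  # 15N, not to unity
  gH <- 2.6752218744e8; gN <- -2.7126180e7
  d <- 1e-7 * abs(gH * gN) * 1.054571817e-34 / (1.02e-10)^3
  cc <- 2 * pi * 700e6 * abs(gN / gH) * (-172e-6) / sqrt(3)
  lim <- 1 + (gH / gN) * (d^2 / 4) * 5 / ((d^2 / 4) * 10 + cc^2)
  expect_equal(r[["noe"]], lim, tolerance = 1e-3)
  expect_lt(lim, -3)
})

test_that("noiseless refits recover the generating parameters", {
  sds <- c(r1 = 0.01, r2 = 0.1, noe = 0.01)
  f <- fitResidue(forwardRates(ModelFreeParams(1, s2 = 0.88, tm = 11e-9),
                               spinFx), sds, spinFx, 11e-9, 1)
  expect_equal(f$params$s2, 0.88, tolerance = 1e-3)
  f3 <- fitResidue(forwardRates(ModelFreeParams(3, s2 = 0.84, rex = 4,
                                                tm = 10.7e-9), spinFx),
                   sds, spinFx, 10.7e-9, 3)
  expect_equal(f3$params$s2, 0.84, tolerance = 1e-3)
  expect_equal(f3$params$rex, 4, tolerance = 1e-2)
})

test_that("parameter round trip over random draws in bounds", {
  set.seed(42)
  for (i in 1:20) {
    m <- sample(c(1L, 2L, 3L), 1)
    tm <- runif(1, 6e-9, 14e-9)
    p <- switch(m,
      ModelFreeParams(1, s2 = runif(1, 0.3, 0.98), tm = tm),
      ModelFreeParams(2, s2 = runif(1, 0.3, 0.95),
                      te = runif(1, 2e-11, 2e-9), tm = tm),
      ModelFreeParams(3, s2 = runif(1, 0.3, 0.98),
                      rex = runif(1, 0.5, 12), tm = tm))
    obs <- forwardRates(p, spinFx)
    f <- fitResidue(obs, c(r1 = 0.005, r2 = 0.05, noe = 0.005),
                    spinFx, tm, m)
    expect_true(f$converged)
    expect_equal(f$params$s2, p$s2, tolerance = 2e-3)
  }
})

test_that("BIC selection prefers parsimony on nested models", {
  sds <- c(r1 = 0.01, r2 = 0.1, noe = 0.01)
  obs <- forwardRates(ModelFreeParams(1, s2 = 0.9, tm = 1e-8), spinFx)
  f1 <- fitResidue(obs, sds, spinFx, 1e-8, 1)
  f3 <- fitResidue(obs, sds, spinFx, 1e-8, 3)
  expect_lt(f3$params$rex, 0.05)
  expect_lt(f1$bic, f3$bic)
  win <- selectModel(list(f1, f3))
  expect_identical(win$model, 1L)
  # singleton passes through; equal BIC breaks toward fewer parameters
  expect_identical(selectModel(list(f3))$model, 3L)
  fTie <- f3; fTie$bic <- f1$bic
  expect_identical(selectModel(list(fTie, f1))$model, 1L)
})

test_that("Monte-Carlo parameter uncertainties are produced and positive", {
  obs <- forwardRates(ModelFreeParams(3, s2 = 0.85, rex = 5, tm = 1e-8),
                      spinFx)
  f <- fitResidue(obs + c(0.01, 0.2, -0.005),
                  c(r1 = 0.03, r2 = 0.3, noe = 0.02), spinFx, 1e-8, 3,
                  nReplicas = 60L, seed = 4L)
  expect_true(all(f$paramSDs > 0))
  expect_lt(abs(f$params$s2 - 0.85), 0.1)
})

test_that("identical rigid residues give identical fitted S2", {
  obs <- forwardRates(ModelFreeParams(1, s2 = 0.87, tm = 1e-8), spinFx)
  tab <- data.frame(residue_id = 1:6,
                    r1 = obs[["r1"]], r1_sd = 0.02,
                    r2 = obs[["r2"]], r2_sd = 0.2,
                    noe = obs[["noe"]], noe_sd = 0.02)
  fd <- fitDataset(RelaxationDataset(tab, 700e6), spinFx, 1e-8,
                   models = c(1, 3))
  expect_lt(diff(range(fd$s2)), 1e-6)
})

test_that("global tm optimization recovers the generating tumbling time", {
  for (tmTrue in c(10.7e-9, 7.5e-9)) {
    scn <- germlineScenario(3, nResidues = 12, tm = tmTrue,
                            noise = c(intensity = 0.005, r1 = 0.01,
                                      r2 = 0.08, noe = 0.006,
                                      r2eff = 0.3, hdx = 0.02, dls = 0))
    g <- makeRelaxationRates(scn)
    out <- fitGlobalTm(g$dataset, g$spin, models = c(1, 3))
    expect_lt(abs(out$tm - tmTrue), 0.2e-9)
  }
})
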