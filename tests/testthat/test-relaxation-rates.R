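test_that("noiseless monoexponential decays are recovered exactly", {
  for (rate in c(0.1, 1.05, 17.3, 50)) {
    f <- fitMonoexponential(noiselessSeries(rate), nReplicas = 0)
    expect_lt(abs(f@rate - rate) / rate, 1e-6)
    expect_equal(f@amplitude, 1, tolerance = 1e-6)
    expect_true(f@converged)
  }
})

test_that("constant intensities fit to rate zero", {
  s <- IntensitySeries(1, r1DelaysFx, rep(1, 9), 1e-6)
  f <- fitMonoexponential(s, nReplicas = 0)
  expect_identical(f@rate, 0)
})

test_that("rate fitting rejects degenerate input", {
  expect_error(fitMonoexponential(
    IntensitySeries(1, c(0.1, 0.2), exp(-c(0.1, 0.2)), 1e-3),
    nReplicas = 0), "3 distinct delays")
  expect_error(fitMonoexponential(
    IntensitySeries(1, c(0.1, 0.2, 0.3), c(1e-4, 1e-4, 1e-4), 1),
    nReplicas = 0), "noise floor")
  expect_error(fitMonoexponential(noiselessSeries(1), seed = NULL),
               "seed")
})

test_that("Monte-Carlo coverage: noisy R2 decays cover the truth", {
  # rate 17.3 at the nine R2 delays, 1% noise: the 0.68 CI should
  # contain the generating rate in a solid majority of repeats
  hits <- 0L
  for (s in 1:25) {
    series <- withr::with_seed(s, {
      y <- exp(-17.3 * r2DelaysFx) + rnorm(9, sd = 0.01)
      IntensitySeries(1L, r2DelaysFx, y, 0.01)
    })
    f <- fitMonoexponential(series, nReplicas = 500, seed = s + 1000L)
    if (abs(f@rate - 17.3) <= f@rateSD) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.6)
})

test_that("Monte-Carlo rate uncertainty scales with the noise level", {
  mkFit <- function(noise, seed) {
    series <- withr::with_seed(seed, {
      y <- exp(-1.05 * r1DelaysFx) + rnorm(9, sd = noise)
      IntensitySeries(1L, r1DelaysFx, y, noise)
    })
    fitMonoexponential(series, nReplicas = 400, seed = seed)
  }
  sdLow <- mean(vapply(1:6, function(s) mkFit(0.002, s)@rateSD, 1))
  sdHigh <- mean(vapply(1:6, function(s) mkFit(0.02, s)@rateSD, 1))
  expect_gt(sdHigh / sdLow, 10 * 0.8)
  expect_lt(sdHigh / sdLow, 10 * 1.2)
})

test_that("HetNOE is the saturated/reference ratio with propagated error", {
  h <- computeHetNoe(0.88, 1.0, 0.001)
  expect_equal(h$noe, 0.88)
  expect_gt(h$noeSD, 0)
  expect_equal(computeHetNoe(1, 1, 1e-4)$noe, 1)
  expect_equal(computeHetNoe(-0.2, 1.0, 1e-4)$noe, -0.2)
  expect_error(computeHetNoe(0.5, 0.0005, 0.01), "noise floor")
})

test_that("correlation time from R2/R1 reproduces both printed values", {
  expect_equal(estimateTcFromR2R1(1.05, 17.3, 700e6) * 1e9, 10.7,
               tolerance = 0.1 / 10.7)
  expect_equal(estimateTcFromR2R1(1.09, 18.9, 700e6) * 1e9, 11.0,
               tolerance = 0.1 / 11.0)
})

test_that("tc estimator identities and domain", {
  # ratio forced to 8/6 makes the radicand exactly 1
  nuN <- larmorN(700e6)
  expect_equal(estimateTcFromR2R1(6, 8, 700e6), 1 / (4 * pi * nuN))
  expect_error(estimateTcFromR2R1(10, 1, 700e6), "threshold")
  # monotone in the ratio
  tcs <- vapply(seq(1.5, 20, length.out = 12),
                function(r) estimateTcFromR2R1(1, r, 700e6), 1)
  expect_true(all(diff(tcs) > 0))
})

test_that("batch fitting assembles a coherent rate table", {
  g <- makeRelaxationInputs(germlineScenario(5, nResidues = 6))
  ds <- fitRelaxationDataset(g$r1Series, g$r2Series, g$noePairs,
                             nReplicas = 50L, seed = 9L)
  expect_s4_class(ds, "RelaxationDataset")
  expect_equal(nrow(ds@rates), 6)
  expect_equal(ds@rates$r1, g$truth$r1, tolerance = 0.05)
  expect_equal(ds@rates$r2, g$truth$r2, tolerance = 0.05)
  expect_true(all(ds@rates$r1_sd > 0))
})
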