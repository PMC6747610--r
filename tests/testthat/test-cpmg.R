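test_that("intensity-to-rate conversion follows the log-ratio relation", {
  expect_equal(r2effFromIntensity(1, 1, 0.030), 0)
  expect_equal(r2effFromIntensity(0.6, 1, 0.030), -log(0.6) / 0.030)
  expect_equal(r2effFromIntensity(exp(-1), 1, 0.030), 1 / 0.030)
  # non-positive intensity flags the point instead of aborting
  out <- r2effFromIntensity(c(0.5, -0.1, 0), 1, 0.030)
  expect_true(is.na(out[2]) && is.na(out[3]) && is.finite(out[1]))
  expect_error(r2effFromIntensity(0.5, -1, 0.030))
})

test_that("exchange-free limits collapse onto r20", {
  nu <- ProtDynamics:::.nuGrid()
  p1 <- TwoSiteParams(1000, 1e-9, 0.8, 17)
  p2 <- TwoSiteParams(1000, 0.2, 0, 17)
  for (amp in c(TRUE, FALSE)) {
    expect_equal(carverRichardsR2eff(p1, nu, amplitude = amp),
                 rep(17, length(nu)), tolerance = 1e-6)
    expect_equal(carverRichardsR2eff(p2, nu, amplitude = amp),
                 rep(17, length(nu)))
  }
  bm <- blochMcConnellR2eff(TwoSiteParams(1000, 1e-12, 0.8, 17), nu)
  expect_equal(bm$r2eff, rep(17, length(nu)), tolerance = 1e-6)
})

test_that("Bloch-McConnell oracle reaches the fast-exchange limit", {
  # kex >> dw: Luz-Meiboom expression
  kex <- 20000; pb <- 0.1; dwPpm <- 0.5; r20 <- 12
  nu <- ProtDynamics:::.nuGrid()
  dw <- dwPpm * 1e-6 * 2 * pi * larmorN(700e6)
  lm <- r20 + (1 - pb) * pb * dw^2 / kex *
    (1 - 4 * nu / kex * tanh(kex / (4 * nu)))
  bm <- blochMcConnellR2eff(TwoSiteParams(kex, pb, dwPpm, r20), nu)
  expect_equal(bm$r2eff, lm, tolerance = 0.02)
})

test_that("high refocusing frequency suppresses the exchange contribution", {
  p <- TwoSiteParams(800, 0.05, 0.3, 15)
  r <- carverRichardsR2eff(p, c(33.33, 1000))
  expect_lt(r[2] - 15, 0.35)
  expect_gt(r[1], r[2])
})

test_that("closed form matches the numerical propagation over a sweep", {
  # 200 seeded draws spanning slow to fast exchange
  set.seed(11)
  nu <- ProtDynamics:::.nuGrid()
  worst <- 0
  for (i in 1:200) {
    p <- TwoSiteParams(exp(runif(1, log(100), log(20000))),
                       runif(1, 0.01, 0.35),
                       runif(1, 0.2, 2.0),
                       runif(1, 8, 25))
    cr <- carverRichardsR2eff(p, nu)
    bm <- blochMcConnellR2eff(p, nu)
    worst <- max(worst, max(abs(cr - bm$r2eff)))
  }
  expect_lte(worst, 0.2)
})

test_that("table-derived parameters reproduce the oracle profile", {
  p <- TwoSiteParams(1175, 0.15, 0.8, 15)
  nu <- ProtDynamics:::.nuGrid()
  cr <- carverRichardsR2eff(p, nu)
  bm <- blochMcConnellR2eff(p, nu)
  expect_lt(max(abs(cr - bm$r2eff)), 0.2)
  # dispersion monotone decreasing for these parameters
  expect_true(all(diff(cr) < 0))
  # R2eff never below the exchange-free rate floor
  expect_true(all(cr >= p@r20 - 1e-9))
})

test_that("dispersion size and strict significance threshold", {
  flat <- cleanProfile(1000, 1e-9, 0.8, 16)
  s <- rexSize(flat)
  expect_equal(s$rex, 0, tolerance = 1e-6)
  expect_false(s$significant)
  prof <- DispersionProfile(1, c(33.33, 1000), c(21.0, 16.5))
  expect_equal(rexSize(prof)$rex, 4.5)
  expect_true(rexSize(prof)$significant)
  prof29 <- DispersionProfile(1, c(33.33, 1000), c(19.4, 16.5))
  expect_false(rexSize(prof29)$significant)   # 2.9 is not > 3
  expect_error(rexSize(DispersionProfile(1, 100, 17)), "single-point")
})

test_that("duplicate reduction averages pairs and floors the sd", {
  p <- DispersionProfile(1, c(100, 100, 200, 200), c(20, 21, 18, 18),
                         minSD = 0.1)
  expect_equal(p@nuCpmg, c(100, 200))
  expect_equal(p@r2eff, c(20.5, 18))
  expect_equal(p@r2effSD, c(0.5, 0.1))
})

test_that("individual fit recovers noiseless mutant-like parameters", {
  prof <- cleanProfile(2008, 0.10, 0.5, 18)
  f <- fitIndividual(prof)
  expect_true(f$converged)
  expect_equal(f$params@kex, 2008, tolerance = 0.01)
  expect_equal(f$params@pb, 0.10, tolerance = 0.01)
  expect_equal(f$params@dw, 0.5, tolerance = 0.01)
  expect_equal(f$params@r20, 18, tolerance = 0.01)
})

test_that("individual fit demands enough points and yields MC errors", {
  short <- DispersionProfile(1, c(33, 66, 100, 200, 1000),
                             c(20, 19, 18, 17, 16))
  expect_error(fitIndividual(short), "6 distinct")
  prof <- cleanProfile(1175, 0.15, 0.8, 15)
  prof@r2eff <- prof@r2eff + withr::with_seed(2, rnorm(13, sd = 0.2))
  prof@r2effSD <- rep(0.2, 13)
  f <- fitIndividual(prof, nReplicas = 25L, seed = 5L)
  expect_true(all(f$sds[c("kex", "pb")] > 0))
})

test_that("global fit of one profile degenerates to the individual fit", {
  prof <- cleanProfile(1175, 0.15, 0.8, 15)
  g <- fitGlobal(list(prof))
  f <- fitIndividual(prof)
  expect_equal(g$kex, f$params@kex, tolerance = 1e-6)
  expect_equal(g$pb, f$params@pb, tolerance = 1e-6)
})

test_that("global fit shares kex and pb and anchors dw across fields", {
  scn <- germlineScenario(21, nResidues = 8, rexFraction = 1)
  g <- makeCpmgInputs(scn)
  gf <- fitGlobal(g$profiles)
  expect_true(gf$converged)
  expect_equal(gf$kex, 1175, tolerance = 0.10)
  expect_lt(abs(gf$pb - 0.15), 0.02)
  # dw shared per residue across the two fields
  dwTab <- tapply(gf$residues$dw, gf$residues$residue_id,
                  function(x) diff(range(x)))
  expect_true(all(dwTab < 1e-9))
  # recovered dw track the generating values
  truth1 <- g$truth[g$truth$field_1h == 7e8, ]
  est <- gf$residues$dw[match(truth1$residue_id, gf$residues$residue_id)]
  expect_equal(est, truth1$dw, tolerance = 0.2)
})

test_that("pb is canonicalized below one half with nonnegative dw", {
  prof <- cleanProfile(1175, 0.15, 0.8, 15)
  f <- fitIndividual(prof)
  expect_lt(f$params@pb, 0.5)
  expect_gte(f$params@dw, 0)
})
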