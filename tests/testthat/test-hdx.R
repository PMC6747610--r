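test_that("noiseless exchange decays round-trip through the fitter", {
  t <- seq(420, 43200, by = 420)
  s <- HdxSeries(1, t, exp(-t / 300), mode = "d2o_100")
  f <- fitExchangeDecay(s, noiseSD = 1e-9, nReplicas = 0)
  expect_equal(f$lifetime, 300, tolerance = 1e-4)
  expect_identical(f$lifetimeClass, "100_600s")
  # 50/50 mode with the plateau pinned at half amplitude
  t2 <- seq(60, 3600, by = 60)
  s2 <- HdxSeries(2, t2, 2 * (0.5 + 0.5 * exp(-t2 / 500)),
                  mode = "d2o_50")
  f2 <- fitExchangeDecay(s2, noiseSD = 1e-9, nReplicas = 0)
  expect_equal(f2$lifetime, 500, tolerance = 1e-4)
  expect_equal(f2$amplitude, 2, tolerance = 1e-4)
})

test_that("fast exchange on a coarse grid is censored as before-first-point", {
  t <- seq(120, 3600, by = 120)  # 2-min sampling
  s <- HdxSeries(1, t, 0.5 + 0.5 * exp(-0.05 * t), mode = "d2o_50")
  f <- fitExchangeDecay(s, noiseSD = 0.01, nReplicas = 0)
  expect_true(f$censored)
  expect_identical(f$lifetimeClass, "before_first_point")
  # a constant series at plateau likewise
  s3 <- HdxSeries(1, t, rep(0.5, length(t)), mode = "d2o_50")
  expect_identical(fitExchangeDecay(s3, noiseSD = 0.01,
                                    nReplicas = 0)$lifetimeClass,
                   "before_first_point")
  # but sub-sampled times resolve it
  tf <- seq(5, 300, by = 5)
  sf <- HdxSeries(1, tf, 0.5 + 0.5 * exp(-0.05 * tf), mode = "d2o_50",
                  firstPointTime = 5)
  ff <- fitExchangeDecay(sf, noiseSD = 1e-9, nReplicas = 0)
  expect_equal(ff$ke, 0.05, tolerance = 1e-4)
})

test_that("lifetime classes use the exact 100 s and 600 s boundaries", {
  expect_identical(hdxLifetimeClass(c(99.9, 100, 600, 600.1)),
                   c("lt_100s", "100_600s", "100_600s", "gt_600s"))
  expect_identical(hdxLifetimeClass(50, beforeFirst = TRUE),
                   "before_first_point")
})

test_that("class binning matches generator truth at zero noise", {
  scn <- germlineScenario(8, nResidues = 30,
                          noise = c(intensity = 0.01, r1 = 0.05, r2 = 0.4,
                                    noe = 0.03, r2eff = 0.3, hdx = 1e-9,
                                    dls = 0))
  g <- makeHdxInputs(scn)
  fits <- lapply(g$reference$slow, fitExchangeDecay, noiseSD = 1e-8,
                 nReplicas = 0)
  cls <- vapply(fits, `[[`, "", "lifetimeClass")
  expect_identical(cls, g$truth$class_ref)
})

test_that("fast/slow normalization recovers a constructed scale factor", {
  g <- makeHdxInputs(germlineScenario(2, nResidues = 20))
  slow2 <- lapply(g$reference$slow, function(s) {
    s@intensities <- 2 * s@intensities; s
  })
  m <- normalizeFastSeries(g$reference$fast, slow2)
  expect_true(m$merged)
  expect_equal(m$scale, 2, tolerance = 0.02)
  expect_lte(m$effectiveEarliestTime, 60)
  # disjoint residue sets take the warning path
  fastOdd <- g$reference$fast[1:3]
  for (i in seq_along(fastOdd)) fastOdd[[i]]@residueId <- 900L + i
  expect_warning(m2 <- normalizeFastSeries(fastOdd, g$reference$slow),
                 "unmerged")
  expect_false(m2$merged)
})

test_that("intrinsic rates follow the reference-scheme arithmetic", {
  # independent hand evaluation for an Ala-Ala context at pH 7.4, 298.15 K
  pD <- 7.4 + 0.4
  arr <- function(Ea) exp(-Ea / 1.987204e-3 * (1 / 298.15 - 1 / 293))
  kA <- 10^1.62 * arr(14); kB <- 10^10.05 * arr(17)
  kW <- 10^(-1.5) * arr(19)
  byHand <- (kA * 10^(-pD) + kB * 10^(pD - 15.05) + kW) / 60
  expect_equal(intrinsicRate("AAA", 2), byHand, tolerance = 1e-12)
  # base-catalyzed regime: one pH unit is a factor of ten
  expect_equal(intrinsicRate("AAA", 2, pH = 7.4) /
                 intrinsicRate("AAA", 2, pH = 6.4), 10, tolerance = 0.01)
  expect_error(intrinsicRate("APA", 2), "proline")
  expect_error(intrinsicRate("AAA", 1), "chain start")
})

test_that("protection factors and free energies follow the stated relation", {
  # unprotected amide
  pe <- protectionAndEnergy(1, 1)
  expect_equal(pe$P, 1); expect_equal(pe$dg, 0)
  # direct evaluation of -RT ln(1e-3)
  pe2 <- protectionAndEnergy(1e-3, 1, temperature = 298.15)
  expect_equal(pe2$dg, 17.1237, tolerance = 1e-4)
  expect_equal(pe2$Pprime, 1000)
  # halving ke raises dG by RT ln 2
  d <- protectionAndEnergy(5e-4, 1)$dg - pe2$dg
  expect_equal(d, 8.314462618e-3 * 298.15 * log(2), tolerance = 1e-9)
  expect_error(protectionAndEnergy(-1, 1), "positive")
})

test_that("ddG identities hold to numerical precision", {
  expect_equal(ddgBetweenVariants(0.2, 0.2), 0)
  expect_equal(ddgBetweenVariants(exp(1) * 0.1, 0.1),
               -8.314462618e-3 * 298.15, tolerance = 1e-9)
  # ddG equals dG_var - dG_ref algebraically
  set.seed(3)
  pv <- runif(20, 1e-4, 1); pr <- runif(20, 1e-4, 1)
  dgv <- protectionAndEnergy(pv, 1)$dg
  dgr <- protectionAndEnergy(pr, 1)$dg
  expect_equal(ddgBetweenVariants(pv, pr), dgv - dgr, tolerance = 1e-9)
  expect_error(ddgBetweenVariants(1, 1, convention = c("a", "b")),
               "convention")
})

test_that("paired variant contrast yields uniform ddG and a ~6x ratio", {
  g <- makeHdxInputs(germlineScenario(4, nResidues = 40))
  mR <- normalizeFastSeries(g$reference$fast, g$reference$slow)
  mV <- normalizeFastSeries(g$variant$fast, g$variant$slow)
  okR <- mR$table[!mR$table$censored, ]
  okV <- mV$table[!mV$table$censored, ]
  shared <- intersect(okR$residue_id, okV$residue_id)
  expect_gte(length(shared), 10)
  ltR <- okR$lifetime[match(shared, okR$residue_id)]
  ltV <- okV$lifetime[match(shared, okV$residue_id)]
  expect_equal(mean(ltR) / mean(ltV), 6, tolerance = 0.15)
  # per-residue ddG (quotient convention P = ke/kint; shared kint cancels)
  ddg <- ddgBetweenVariants(1 / ltV, 1 / ltR)
  expect_lt(stats::sd(ddg), 0.9)
  expect_equal(mean(ddg), -8.314462618e-3 * 298.15 * log(6),
               tolerance = 0.12)
})

test_that("result table assigns censored residues the fastest rate", {
  ft <- data.frame(residue_id = 2:5,
                   ke = c(0.01, NA, 0.002, 1 / 650),
                   ke_sd = c(1e-4, NA, 1e-5, 1e-5),
                   lifetime = c(100, NA, 500, 650),
                   censored = c(FALSE, TRUE, FALSE, FALSE),
                   lifetime_class = c("100_600s", "before_first_point",
                                      "100_600s", "gt_600s"),
                   stringsAsFactors = FALSE)
  out <- hdxResultTable(ft, "MAKLAVQWT")
  expect_equal(out$ke[out$residue_id == 3], 0.01)  # fastest measured
  expect_true(all(is.finite(out$kint)))
  expect_equal(out$protection, out$ke / out$kint)
  expect_equal(out$dg, -8.314462618e-3 * 298.15 * log(out$protection),
               tolerance = 1e-12)
  # proline position yields NA intrinsic rate but keeps the row
  ftP <- ft; ftP$residue_id <- c(2L, 3L, 4L, 6L)
  outP <- hdxResultTable(ftP, "MAKLAPQWT")  # residue 6 is proline
  expect_true(is.na(outP$kint[outP$residue_id == 6]))
})
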