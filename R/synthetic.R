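## Forward simulation of every input the pipeline consumes, from known
## ground truth, so each stage is testable by parameter recovery. Every
## generator is deterministic given the scenario seed and returns its
## ground truth alongside the data; recovery tests read truth only from
## that sidecar.

#' Construct a synthetic scenario
#'
#' See \linkS4class{SyntheticScenario} for the meaning of each setting.
#' Defaults encode the germ-line study conditions: 90 residues, tm
#' 10.7 ns, cohort mean S2 0.84 (sd 0.06), roughly two thirds of fitted
#' residues carrying exchange broadening, a shared excited state at
#' kex 1175 s^-1 / pB 15% with per-residue shift differences around
#' 0.8 ppm, log-normal HDX lifetimes with median 600 s, and a variant
#' contrast of kex x1.709, pB x2/3, lifetimes x1/6, S2 +0.04.
#'
#' @param seed integer seed (mandatory).
#' @param nResidues cohort size.
#' @param tm tumbling time (s).
#' @param s2Mean,s2SD order-parameter distribution.
#' @param rexFraction fraction of residues with Rex > 0.
#' @param exchange \linkS4class{TwoSiteParams}; the dw slot is the mean
#'   of the per-residue dw draw.
#' @param hdxMeanlog,hdxSdlog log-normal lifetime parameters (s).
#' @param contrast named multipliers for the second variant (kex, pb,
#'   lifetime multiplicative; s2shift additive).
#' @param noise named noise sds; see the class docs.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
SyntheticScenario <- function(seed, nResidues = 90L, tm = 10.7e-9,
                              s2Mean = 0.84, s2SD = 0.06,
                              rexFraction = 39 / 58,
                              exchange = TwoSiteParams(1175, 0.15, 0.8, 15),
                              hdxMeanlog = log(600), hdxSdlog = 1.0,
                              contrast = c(kex = 2008 / 1175, pb = 2 / 3,
                                           lifetime = 1 / 6,
                                           s2shift = 0.04),
                              noise = c(intensity = 0.01, r1 = 0.05,
                                        r2 = 0.4, noe = 0.03, r2eff = 0.3,
                                        hdx = 0.02, dls = 0)) {
  new("SyntheticScenario", seed = as.integer(seed),
      nResidues = as.integer(nResidues), tm = tm, s2Mean = s2Mean,
      s2SD = s2SD, rexFraction = rexFraction, exchange = exchange,
      hdxMeanlog = hdxMeanlog, hdxSdlog = hdxSdlog, contrast = contrast,
      noise = noise)
}

#' Germ-line and mutant scenario presets
#'
#' \code{germlineScenario} is the reference condition;
#' \code{mutantScenario} carries the variant's conditions directly
#' (tm 11.0 ns, mean S2 0.88, kex 2008 s^-1, pB 10%, mean dw 0.5 ppm,
#' 6-fold shorter HDX lifetimes).
#'
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{SyntheticScenario}}.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
germlineScenario <- function(seed, ...) SyntheticScenario(seed, ...)

#' @rdname germlineScenario
#' @export
mutantScenario <- function(seed, ...) {
  args <- list(seed = seed, tm = 11.0e-9, s2Mean = 0.88, s2SD = 0.05,
               rexFraction = 54 / 69,
               exchange = TwoSiteParams(2008, 0.10, 0.5, 15),
               hdxMeanlog = log(600) - log(6))
  user <- list(...)
  args[names(user)] <- user
  do.call(SyntheticScenario, args)
}

#' Derive the variant scenario from a reference scenario
#'
#' Applies the scenario's contrast factors to produce the second
#' variant's conditions: kex and pB are scaled multiplicatively, HDX
#' lifetimes by the lifetime factor, and the mean order parameter is
#' shifted additively. Everything else (including the per-residue shift
#' differences, which the contrast does not touch) is inherited.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @param seed optional new seed (defaults to the reference seed).
#' @return a \linkS4class{SyntheticScenario} for the variant.
#' @export
applyVariantContrast <- function(scn, seed = scn@seed) {
  ct <- scn@contrast
  ex <- scn@exchange
  new("SyntheticScenario", seed = as.integer(seed),
      nResidues = scn@nResidues, tm = scn@tm,
      s2Mean = min(scn@s2Mean + ct[["s2shift"]], 0.99), s2SD = scn@s2SD,
      rexFraction = scn@rexFraction,
      exchange = TwoSiteParams(ex@kex * ct[["kex"]], ex@pb * ct[["pb"]],
                               ex@dw, ex@r20),
      hdxMeanlog = scn@hdxMeanlog + log(ct[["lifetime"]]),
      hdxSdlog = scn@hdxSdlog, contrast = ct, noise = scn@noise)
}

## truncated-normal draw recentred so the sample mean equals `mean`
## (the scenario defines the cohort mean)
.drawS2 <- function(n, mean, sd) {
  s2 <- stats::rnorm(n, mean, sd)
  s2 <- pmin(pmax(s2, 0.02), 0.995)
  s2 <- s2 + (mean - mean(s2))
  pmin(pmax(s2, 0.01), 0.999)
}

## nine relaxation delays of the standard acquisition (seconds)
.r1Delays <- c(100, 900, 300, 2000, 500, 1500, 700, 1300, 200) / 1000
.r2Delays <- c(10, 250, 30, 210, 50, 150, 70, 130, 90) / 1000

## per-residue ground-truth parameter draw shared by the relaxation
## generators
.drawRelaxTruth <- function(scn, spin) {
  n <- scn@nResidues
  s2 <- .drawS2(n, scn@s2Mean, scn@s2SD)
  nRex <- round(scn@rexFraction * n)
  hasRex <- seq_len(n) <= nRex    # deterministic partition, ids ordered
  rex <- ifelse(hasRex, 1 + stats::rgamma(n, shape = 2, scale = 1.5), 0)
  truth <- data.frame(residue_id = seq_len(n), s2 = s2, rex = rex,
                      model = ifelse(hasRex, 3L, 1L), tm = scn@tm)
  rates <- t(vapply(seq_len(n), function(i) {
    p <- ModelFreeParams(if (hasRex[i]) 3 else 1, s2 = s2[i],
                         rex = rex[i], tm = scn@tm)
    forwardRates(p, spin)
  }, numeric(3)))
  truth$r1 <- rates[, 1]; truth$r2 <- rates[, 2]; truth$noe <- rates[, 3]
  truth
}

#' Generate relaxation intensity decays and HetNOE pairs
#'
#' Forward model: per-residue model-free parameters (model 1 or, for the
#' exchanging fraction, model 3) give (R1, R2, NOE) at the scenario
#' field; monoexponential decays are sampled at the nine standard R1 and
#' R2 delays with unit amplitude and Gaussian spectral noise, and HetNOE
#' pairs at the same noise level.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @param field1H proton frequency (Hz).
#' @return list with \code{r1Series}, \code{r2Series} (lists of
#'   \linkS4class{IntensitySeries}), \code{noePairs} (data.frame),
#'   \code{truth} (ground-truth sidecar data.frame), \code{spin}.
#' @export
makeRelaxationInputs <- function(scn, field1H = 700e6) {
  spin <- SpinParameters(field1H = field1H)
  withSeed(scn@seed, {
    truth <- .drawRelaxTruth(scn, spin)
    nsd <- scn@noise[["intensity"]]
    mk <- function(id, delays, rate) {
      I <- exp(-rate * delays) + stats::rnorm(length(delays), sd = nsd)
      IntensitySeries(id, delays, I, max(nsd, 1e-9))
    }
    r1Series <- lapply(seq_len(nrow(truth)), function(i)
      mk(truth$residue_id[i], .r1Delays, truth$r1[i]))
    r2Series <- lapply(seq_len(nrow(truth)), function(i)
      mk(truth$residue_id[i], .r2Delays, truth$r2[i]))
    noePairs <- data.frame(
      residue_id = truth$residue_id,
      i_sat = truth$noe + stats::rnorm(nrow(truth), sd = nsd),
      i_ref = 1 + stats::rnorm(nrow(truth), sd = nsd),
      noise_sd = max(nsd, 1e-9))
    list(r1Series = r1Series, r2Series = r2Series, noePairs = noePairs,
         truth = truth, spin = spin)
  })
}

#' Generate a rate-level relaxation dataset
#'
#' Same forward model as \code{\link{makeRelaxationInputs}} but with
#' Gaussian noise added directly to the rates at the scenario's
#' rate-level noise sds (r1, r2, noe), matching the spread of typical
#' per-residue measurements. Used by the model-free recovery
#' experiments.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @param field1H proton frequency (Hz).
#' @return list with \code{dataset} (\linkS4class{RelaxationDataset}),
#'   \code{truth}, \code{spin}.
#' @export
makeRelaxationRates <- function(scn, field1H = 700e6) {
  spin <- SpinParameters(field1H = field1H)
  withSeed(scn@seed, {
    truth <- .drawRelaxTruth(scn, spin)
    n <- nrow(truth)
    tab <- data.frame(
      residue_id = truth$residue_id,
      r1 = truth$r1 + stats::rnorm(n, sd = scn@noise[["r1"]]),
      r1_sd = scn@noise[["r1"]],
      r2 = truth$r2 + stats::rnorm(n, sd = scn@noise[["r2"]]),
      r2_sd = scn@noise[["r2"]],
      noe = truth$noe + stats::rnorm(n, sd = scn@noise[["noe"]]),
      noe_sd = scn@noise[["noe"]])
    list(dataset = RelaxationDataset(tab, field1H), truth = truth,
         spin = spin)
  })
}

## refocusing-frequency grid realizable with integer echo counts in tRelax
.nuGrid <- function(tRelax = 0.030) {
  n <- c(2, 3, 4, 6, 8, 10, 14, 18, 24, 30, 40, 50, 60)
  n / (2 * tRelax)
}

#' Generate CPMG dispersion profiles
#'
#' Residues are partitioned into an exchanging set sharing (kex, pB)
#' with per-residue shift differences drawn around the scenario mean,
#' and a flat set (dw = 0). Each profile is sampled on the 33-1000 Hz
#' grid with a pair of repeats per frequency, perturbed independently
#' at the scenario's r2eff noise.
#'
#' @param scn a \linkS4class{SyntheticScenario}; \code{rexFraction}
#'   gives the exchanging fraction.
#' @param fields proton frequencies (Hz); the default reproduces the
#'   two-field acquisition (700 and 800 MHz). The shift difference is
#'   anchored in ppm across fields; the exchange-free rate is drawn per
#'   residue per field.
#' @param tRelax constant relaxation delay (s).
#' @param nResidues optional override of the cohort size.
#' @return list with \code{profiles} (list of
#'   \linkS4class{DispersionProfile}, one per residue per field),
#'   \code{truth} (sidecar with residue_id, field_1h, exchanging, kex,
#'   pb, dw, r20).
#' @export
makeCpmgInputs <- function(scn, fields = c(700e6, 800e6), tRelax = 0.030,
                           nResidues = NULL) {
  n <- if (is.null(nResidues)) scn@nResidues else as.integer(nResidues)
  ex <- scn@exchange
  withSeed(scn@seed, {
    nEx <- round(scn@rexFraction * n)
    exch <- seq_len(n) <= nEx
    ## 15N shift differences are broad and right-skewed across residues;
    ## a log-normal draw (sdlog 0.6) with the sample mean pinned to the
    ## scenario average reproduces both the average dw and a realistic
    ## spread of dispersion sizes around the significance threshold
    dwRaw <- pmin(pmax(stats::rlnorm(n, log(ex@dw) - 0.18, 0.6), 0.1), 2.5)
    dwRaw <- dwRaw * (ex@dw / mean(dwRaw[exch]))
    dw <- ifelse(exch, dwRaw, 0)
    nu <- .nuGrid(tRelax)
    nsd <- scn@noise[["r2eff"]]
    profiles <- list()
    truth <- NULL
    for (fld in fields) {
      r20 <- pmax(stats::rnorm(n, ex@r20, 2), 5)
      pf <- lapply(seq_len(n), function(i) {
        clean <- .crExact(ex@kex, ex@pb, dw[i], r20[i], nu, fld, tRelax)
        nuDup <- rep(nu, each = 2)
        noisy <- rep(clean, each = 2) +
          stats::rnorm(2 * length(nu), sd = nsd)
        DispersionProfile(i, nuDup, noisy, field1H = fld,
                          tRelax = tRelax, minSD = max(nsd / 2, 0.05))
      })
      profiles <- c(profiles, pf)
      truth <- rbind(truth, data.frame(
        residue_id = seq_len(n), field_1h = fld, exchanging = exch,
        kex = ex@kex, pb = ex@pb, dw = dw, r20 = r20))
    }
    list(profiles = profiles, truth = truth)
  })
}

#' Generate paired H/D exchange series for two variants
#'
#' Per-residue lifetimes are drawn log-normally for the reference
#' variant and scaled by the lifetime contrast factor for the second
#' variant (the paired design isolates the contrast). Both acquisition
#' modes are produced: 100% D2O sampled every 7 min (12 h total) and
#' 50/50 solvent sampled every 2 min (1 h total) with the plateau at
#' half amplitude. Residues whose lifetime is shorter than a third of
#' the mode's first sampling time are marked censored
#' (before_first_point) in the truth sidecar.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @param slowDt,slowTotal slow-mode sampling interval and total (s).
#' @param fastDt,fastTotal fast-mode sampling interval and total (s).
#' @return list with \code{reference} and \code{variant}, each holding
#'   \code{slow} and \code{fast} lists of \linkS4class{HdxSeries}, and
#'   \code{truth} (residue_id, lifetime_ref, lifetime_var, ke_ref,
#'   ke_var, class_ref, class_var, censored flags per mode).
#' @export
makeHdxInputs <- function(scn, slowDt = 420, slowTotal = 43200,
                          fastDt = 120, fastTotal = 3600) {
  withSeed(scn@seed, {
    n <- scn@nResidues
    lt <- stats::rlnorm(n, scn@hdxMeanlog, scn@hdxSdlog)
    ltVar <- lt * scn@contrast[["lifetime"]]
    tSlow <- seq(slowDt, slowTotal, by = slowDt)
    tFast <- seq(fastDt, fastTotal, by = fastDt)
    nsd <- scn@noise[["hdx"]]
    mkSet <- function(lifetimes, times, mode) {
      base <- if (mode == "d2o_100") 0 else 0.5
      lapply(seq_len(n), function(i) {
        k <- 1 / lifetimes[i]
        I <- base + (1 - base) * exp(-k * times) +
          stats::rnorm(length(times), sd = nsd)
        HdxSeries(i, times, I, mode = mode)
      })
    }
    reference <- list(slow = mkSet(lt, tSlow, "d2o_100"),
                      fast = mkSet(lt, tFast, "d2o_50"))
    variant <- list(slow = mkSet(ltVar, tSlow, "d2o_100"),
                    fast = mkSet(ltVar, tFast, "d2o_50"))
    truth <- data.frame(
      residue_id = seq_len(n), lifetime_ref = lt, lifetime_var = ltVar,
      ke_ref = 1 / lt, ke_var = 1 / ltVar,
      class_ref = hdxLifetimeClass(lt, beforeFirst = lt < tSlow[1] / 3),
      class_var = hdxLifetimeClass(ltVar, beforeFirst = ltVar < tSlow[1] / 3),
      censored_slow_ref = lt < tSlow[1] / 3,
      censored_slow_var = ltVar < tSlow[1] / 3,
      censored_fast_ref = lt < tFast[1] / 3,
      censored_fast_var = ltVar < tFast[1] / 3)
    list(reference = reference, variant = variant, truth = truth)
  })
}

#' Generate diffusion-in-a-cone N-H vector trajectories
#'
#' Reflected random walk on a spherical cap whose semi-angle is chosen
#' per residue so the closed-form cone order parameter
#' \eqn{S^2 = [\cos\theta_0 (1+\cos\theta_0)/2]^2} matches the target S2
#' drawn from the scenario distribution.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @param nFrames frames per trajectory.
#' @param dt frame spacing (s), default 10 ps.
#' @param stepSD angular step of the walk (radians/frame).
#' @param nResidues optional override of the cohort size.
#' @return list with \code{trajectories} (list of
#'   \linkS4class{VectorTrajectory}) and \code{truth} (residue_id,
#'   s2_target, coneAngle in radians).
#' @export
makeVectorTrajectories <- function(scn, nFrames = 1000L, dt = 1e-11,
                                   stepSD = 0.15, nResidues = NULL) {
  n <- if (is.null(nResidues)) scn@nResidues else as.integer(nResidues)
  withSeed(scn@seed, {
    s2 <- .drawS2(n, scn@s2Mean, scn@s2SD)
    cosT <- (-1 + sqrt(1 + 8 * sqrt(s2))) / 2   # inverts S2 = [c(1+c)/2]^2
    theta0 <- acos(pmin(cosT, 1))
    trajectories <- lapply(seq_len(n), function(i) {
      VectorTrajectory(i, .coneWalk(nFrames, theta0[i], stepSD), dt = dt)
    })
    truth <- data.frame(residue_id = seq_len(n), s2_target = s2,
                        coneAngle = theta0)
    list(trajectories = trajectories, truth = truth)
  })
}

## random walk on the spherical cap theta <= theta0 (z-axis cone):
## geodesic steps of Gaussian length in a uniform tangent direction
## (a symmetric proposal), rejecting moves that leave the cap. The
## stationary distribution is exactly uniform on the cap, the
## equilibrium of diffusion in a cone with a reflecting boundary.
.coneWalk <- function(nFrames, theta0, stepSD) {
  out <- matrix(0, nFrames, 3)
  ## start at a uniform draw on the cap: F(theta) ~ 1 - cos(theta)
  u <- stats::runif(1)
  th <- acos(1 - u * (1 - cos(theta0)))
  ph <- stats::runif(1, 0, 2 * pi)
  v <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  cosT0 <- cos(theta0)
  steps <- abs(stats::rnorm(nFrames, sd = stepSD))
  dirs <- stats::runif(nFrames, 0, 2 * pi)
  for (i in seq_len(nFrames)) {
    ## orthonormal tangent basis at v
    ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * v) * v
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(v[2] * e1[3] - v[3] * e1[2],
            v[3] * e1[1] - v[1] * e1[3],
            v[1] * e1[2] - v[2] * e1[1])
    d <- steps[i]
    cand <- v * cos(d) + (e1 * cos(dirs[i]) + e2 * sin(dirs[i])) * sin(d)
    if (cand[3] >= cosT0) v <- cand   # reject moves outside the cap
    out[i, ] <- v
  }
  out
}

#' Generate a single-species DLS correlogram
#'
#' Single-exponential \eqn{g_2 - 1 = \exp(-2\Gamma\tau)} with
#' \eqn{\Gamma = q^2 D(R_H)} from \code{\link{stokesEinstein}} and
#' \code{\link{scatteringVector}}, on a log-spaced lag grid spanning the
#' decay, with optional additive Gaussian noise.
#'
#' @param radius hydrodynamic radius (m).
#' @param noise additive noise sd on g2-1.
#' @param seed integer seed, required when noise > 0.
#' @param nLags number of lag points.
#' @param temperature,viscosity,wavelength,refractiveIndex,angle optics
#'   and solvent constants (defaults as in
#'   \linkS4class{DlsMeasurement}).
#' @return a \linkS4class{DlsMeasurement}; ground truth (radius, D,
#'   gamma) in the \code{truth} attribute.
#' @export
makeDlsTrace <- function(radius, noise = 0, seed = NULL, nLags = 80L,
                         temperature = 298.15, viscosity = 8.872e-4,
                         wavelength = 633e-9, refractiveIndex = 1.333,
                         angle = 173) {
  stopifnot(radius > 0)
  D <- stokesEinstein(radius, temperature, viscosity)
  q <- scatteringVector(wavelength, refractiveIndex, angle)
  gamma <- q^2 * D
  tau <- exp(seq(log(0.005 / gamma), log(6 / gamma), length.out = nLags))
  g2 <- exp(-2 * gamma * tau)
  if (noise > 0) {
    if (is.null(seed)) stop("a seed is required when noise > 0")
    g2 <- withSeed(seed, g2 + stats::rnorm(nLags, sd = noise))
  }
  out <- DlsMeasurement(tau, g2, wavelength, refractiveIndex, angle,
                        temperature, viscosity)
  attr(out, "truth") <- list(radius = radius, D = D, gamma = gamma)
  out
}
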