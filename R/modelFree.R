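## Lipari-Szabo model-free analysis under isotropic global tumbling:
## spectral densities for models 1-5, forward 15N dipolar+CSA relaxation
## rates, per-residue weighted fits, BIC model selection and a global
## tumbling-time optimization.

## Model parameter sets (k = number of fitted parameters per residue):
##   1: S2              3: S2, Rex           5: S2f, S2s, te
##   2: S2, te          4: S2, te, Rex
.mfModelPars <- list(`1` = "s2", `2` = c("s2", "te"), `3` = c("s2", "rex"),
                     `4` = c("s2", "te", "rex"), `5` = c("s2f", "s2s", "te"))

#' Model-free parameter record
#'
#' Assembles the parameter list for one of the five Lipari-Szabo models.
#' For model 5 the total order parameter is \code{s2 = s2f * s2s}.
#'
#' @param model model id, 1-5.
#' @param s2 squared generalized order parameter in [0, 1] (models 1-4).
#' @param te effective internal correlation time (s; models 2, 4; slow
#'   timescale for model 5).
#' @param rex exchange broadening (s^-1, models 3-4), at the reporting field.
#' @param s2f,s2s fast and slow order parameters (model 5).
#' @param tm global rotational correlation time (s).
#' @return named list with class \code{"ModelFreeParams"}.
#' @export
ModelFreeParams <- function(model, s2 = NA_real_, te = 0, rex = 0,
                            s2f = NA_real_, s2s = NA_real_, tm) {
  model <- as.integer(model)
  stopifnot(model %in% 1:5, tm > 0, te >= 0, rex >= 0)
  if (model == 5L) {
    stopifnot(s2f >= 0, s2f <= 1, s2s >= 0, s2s <= 1)
    s2 <- s2f * s2s
  } else {
    stopifnot(s2 >= 0, s2 <= 1)
  }
  structure(list(model = model, s2 = s2, te = te, rex = rex,
                 s2f = s2f, s2s = s2s, tm = tm),
            class = "ModelFreeParams")
}

#' Lipari-Szabo spectral density
#'
#' \eqn{J(\omega)} for the model-free forms: the single-timescale
#' expression \eqn{(2/5) S^2 t_m / (1 + (\omega t_m)^2)}, its extension
#' with an internal-motion term \eqn{(2/5)(1 - S^2)\tau'/(1+(\omega\tau')^2)}
#' where \eqn{1/\tau' = 1/t_m + 1/t_e} (models 2 and 4), and the
#' two-timescale extended form for model 5.
#'
#' @param params a \code{\link{ModelFreeParams}}.
#' @param omega angular frequency, rad/s (vectorized).
#' @return spectral density J(omega) in s/rad; always >= 0.
#' @export
spectralDensity <- function(params, omega) {
  tm <- params$tm
  if (tm <= 0) stop("tm must be > 0")
  lor <- function(s, tau) 0.4 * s * tau / (1 + (omega * tau)^2)
  if (params$model %in% c(1L, 3L)) {
    lor(params$s2, tm)
  } else if (params$model %in% c(2L, 4L)) {
    tp <- if (params$te > 0) 1 / (1 / tm + 1 / params$te) else 0
    lor(params$s2, tm) + if (tp > 0) lor(1 - params$s2, tp) else 0
  } else {
    s2 <- params$s2f * params$s2s
    tp <- if (params$te > 0) 1 / (1 / tm + 1 / params$te) else 0
    lor(s2, tm) + if (tp > 0) lor(params$s2f - s2, tp) else 0
  }
}

## Dipolar and CSA interaction constants (rad/s).
## d = (mu0/4pi) * gammaH * gammaN * hbar / rNH^3 ; c = omegaN * dCSA / sqrt(3)
.spinConstants <- function(spin) {
  cst <- .constants
  r <- spin@rNH * 1e-10
  d <- (cst$mu0 / (4 * pi)) * abs(cst$gammaH * cst$gammaN) * cst$hbar / r^3
  omegaH <- 2 * pi * spin@field1H
  omegaN <- -2 * pi * larmorN(spin@field1H)  # gammaN < 0
  csa <- abs(omegaN) * spin@csa * 1e-6 / sqrt(3)
  list(d = d, c = csa, omegaH = omegaH, omegaN = omegaN)
}

#' Forward 15N relaxation rates from model-free parameters
#'
#' Standard dipole-dipole + CSA expressions:
#' \deqn{R_1 = (d^2/4)[J(\omega_H-\omega_N) + 3J(\omega_N) + 6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = (d^2/8)[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) + 6J(\omega_H) + 6J(\omega_H+\omega_N)] + (c^2/6)[4J(0) + 3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + (d^2/4)(\gamma_H/\gamma_N)[6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]/R_1}
#'
#' @param params a \code{\link{ModelFreeParams}}.
#' @param spin a \linkS4class{SpinParameters}.
#' @return named numeric vector c(r1, r2, noe).
#' @export
forwardRates <- function(params, spin) {
  k <- .spinConstants(spin)
  J <- function(w) spectralDensity(params, w)
  wH <- abs(k$omegaH); wN <- abs(k$omegaN)
  d2 <- k$d^2; c2 <- k$c^2
  JmHN <- J(wH - wN); JN <- J(wN); JpHN <- J(wH + wN)
  r1 <- (d2 / 4) * (JmHN + 3 * JN + 6 * JpHN) + c2 * JN
  r2 <- (d2 / 8) * (4 * J(0) + JmHN + 3 * JN + 6 * J(wH) + 6 * JpHN) +
    (c2 / 6) * (4 * J(0) + 3 * JN) + params$rex
  gratio <- .constants$gammaH / .constants$gammaN
  noe <- 1 + (d2 / 4) * gratio * (6 * JpHN - JmHN) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

## chi2 of one residue's rates against a parameter vector for `model`
.mfChi2 <- function(theta, model, obs, sds, spin, tm) {
  p <- .mfThetaToParams(theta, model, tm)
  pred <- forwardRates(p, spin)
  if (!all(is.finite(pred))) return(1e12)  # e.g. NOE at exactly S2 = 0
  sum(((obs - pred) / sds)^2)
}

.mfThetaToParams <- function(theta, model, tm) {
  switch(as.character(model),
    `1` = ModelFreeParams(1, s2 = theta[1], tm = tm),
    `2` = ModelFreeParams(2, s2 = theta[1], te = theta[2], tm = tm),
    `3` = ModelFreeParams(3, s2 = theta[1], rex = theta[2], tm = tm),
    `4` = ModelFreeParams(4, s2 = theta[1], te = theta[2], rex = theta[3],
                          tm = tm),
    `5` = ModelFreeParams(5, s2f = theta[1], s2s = theta[2], te = theta[3],
                          tm = tm))
}

.mfBounds <- function(model, tm) {
  ## S2-type in [0,1], te in [0, tm], Rex in [0, 50 s^-1]
  lo <- c(s2 = 0, te = 0, rex = 0, s2f = 0, s2s = 0)
  hi <- c(s2 = 1, te = tm, rex = 50, s2f = 1, s2s = 1)
  pars <- .mfModelPars[[as.character(model)]]
  list(lower = unname(lo[pars]), upper = unname(hi[pars]))
}

.mfStarts <- function(model, tm) {
  s2g <- c(0.5, 0.8, 0.95)
  teg <- c(2e-11, 2e-10, 1e-9)
  rxg <- c(0.5, 4, 12)
  switch(as.character(model),
    `1` = lapply(s2g, function(a) a),
    `2` = unlist(lapply(s2g, function(a) lapply(teg, function(b) c(a, b))),
                 recursive = FALSE),
    `3` = unlist(lapply(s2g, function(a) lapply(rxg, function(b) c(a, b))),
                 recursive = FALSE),
    `4` = {
      g <- expand.grid(s2 = s2g, te = c(5e-11, 5e-10), rex = c(1, 8))
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    },
    `5` = {
      g <- expand.grid(s2f = c(0.85, 0.95), s2s = c(0.8, 0.95),
                       te = c(2e-10, 1.5e-9))
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    })
}

#' Fit one residue's relaxation rates to a model-free model
#'
#' Minimizes the 1/sd^2-weighted sum of squared residuals of (R1, R2, NOE)
#' against the chosen model at fixed global tumbling time. Parameters are
#' bounded to their physical ranges (S2-type terms in [0, 1], te in
#' [0, tm], Rex in [0, 50] s^-1). Monte-Carlo uncertainties come from
#' seeded refits of rate sets perturbed by their stated sds.
#'
#' @param obs named numeric c(r1, r2, noe).
#' @param sds named numeric of positive uncertainties, same order.
#' @param spin a \linkS4class{SpinParameters}.
#' @param tm global tumbling time (s).
#' @param model model id 1-5.
#' @param nReplicas Monte-Carlo replicas (0 to skip).
#' @param ciLevel confidence level for the reported sds.
#' @param seed integer seed, required when \code{nReplicas > 0}.
#' @return list with elements \code{params} (\code{\link{ModelFreeParams}}),
#'   \code{paramSDs}, \code{chi2}, \code{bic}, \code{k}, \code{n},
#'   \code{converged}.
#' @export
fitResidue <- function(obs, sds, spin, tm, model, nReplicas = 0L,
                       ciLevel = 0.68, seed = NULL) {
  stopifnot(all(c("r1", "r2", "noe") %in% names(obs)), all(sds > 0))
  obs <- obs[c("r1", "r2", "noe")]; sds <- sds[c("r1", "r2", "noe")]
  if (nReplicas > 0L && is.null(seed))
    stop("a seed is required for Monte-Carlo uncertainties")
  b <- .mfBounds(model, tm)
  ## parameter scales: without them the finite-difference steps of the
  ## bounded quasi-Newton exceed the whole te range (~1e-9 s)
  scales <- c(s2 = 0.1, te = tm / 20, rex = 5, s2f = 0.1, s2s = 0.1)
  pscale <- unname(scales[.mfModelPars[[as.character(model)]]])
  fitOnce <- function(y) {
    best <- NULL
    for (st in .mfStarts(model, tm)) {
      o <- try(stats::optim(st, .mfChi2, model = model, obs = y, sds = sds,
                            spin = spin, tm = tm, method = "L-BFGS-B",
                            lower = b$lower, upper = b$upper,
                            control = list(factr = 1e4,
                                           parscale = pscale)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  o <- fitOnce(obs)
  if (is.null(o))
    return(list(params = NULL, paramSDs = NULL, chi2 = NA_real_,
                bic = NA_real_, k = length(b$lower), n = 3L,
                converged = FALSE))
  k <- length(b$lower); n <- 3L
  sdsOut <- NULL
  if (nReplicas > 0L) {
    draws <- withSeed(seed, {
      t(vapply(seq_len(nReplicas), function(i) {
        y <- obs + stats::rnorm(3, sd = sds)
        r <- fitOnce(y)
        if (is.null(r)) rep(NA_real_, k) else r$par
      }, numeric(k)))
    })
    sdsOut <- apply(draws, 2, ciHalfWidth, ci = ciLevel)
    names(sdsOut) <- .mfModelPars[[as.character(model)]]
  }
  list(params = .mfThetaToParams(o$par, model, tm), paramSDs = sdsOut,
       chi2 = o$value, bic = o$value + k * log(n), k = k, n = n,
       converged = TRUE)
}

#' Select the best model-free model by BIC
#'
#' \code{BIC = chi2 + k log(n)} with \code{k} free parameters and
#' \code{n = 3} observables per field; ties break toward the model with
#' fewer parameters.
#'
#' @param fits list of results from \code{\link{fitResidue}} (one per
#'   candidate model).
#' @return the winning fit, with an added element \code{model}.
#' @export
selectModel <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$bic), fits)
  if (!length(fits)) stop("all candidate fits failed for this residue")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(bic, kk)   # deterministic tie-break toward smaller k
  win <- fits[[ord[1]]]
  win$model <- win$params$model
  win
}

#' Fit every residue of a dataset across candidate models
#'
#' Per-residue model-free fitting with BIC selection at a fixed tumbling
#' time.
#'
#' @param dataset a \linkS4class{RelaxationDataset}.
#' @param spin a \linkS4class{SpinParameters}.
#' @param tm global tumbling time (s).
#' @param models candidate model ids (default 1:5).
#' @param nReplicas,ciLevel,seed Monte-Carlo settings for the selected
#'   model's uncertainties (replicas run only on the winner).
#' @return data.frame with one row per residue: residue_id, model, s2,
#'   s2_sd, te, rex, rex_sd, chi2, bic.
#' @export
fitDataset <- function(dataset, spin, tm, models = 1:5, nReplicas = 0L,
                       ciLevel = 0.68, seed = 1L) {
  tab <- dataset@rates
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    obs <- c(r1 = tab$r1[i], r2 = tab$r2[i], noe = tab$noe[i])
    sds <- c(r1 = tab$r1_sd[i], r2 = tab$r2_sd[i], noe = tab$noe_sd[i])
    fits <- lapply(models, function(m)
      fitResidue(obs, sds, spin, tm, m))
    win <- tryCatch(selectModel(fits), error = function(e) NULL)
    if (is.null(win))
      return(data.frame(residue_id = tab$residue_id[i], model = NA_integer_,
                        s2 = NA_real_, s2_sd = NA_real_, te = NA_real_,
                        rex = NA_real_, rex_sd = NA_real_, chi2 = NA_real_,
                        bic = NA_real_))
    sdsOut <- c(s2 = NA_real_, rex = NA_real_)
    if (nReplicas > 0L) {
      ref <- fitResidue(obs, sds, spin, tm, win$model, nReplicas = nReplicas,
                        ciLevel = ciLevel, seed = seed + i)
      if (!is.null(ref$paramSDs)) {
        if ("s2" %in% names(ref$paramSDs)) sdsOut["s2"] <- ref$paramSDs["s2"]
        if ("rex" %in% names(ref$paramSDs)) sdsOut["rex"] <- ref$paramSDs["rex"]
      }
    }
    data.frame(residue_id = tab$residue_id[i], model = win$model,
               s2 = win$params$s2, s2_sd = sdsOut["s2"], te = win$params$te,
               rex = win$params$rex, rex_sd = sdsOut["rex"],
               chi2 = win$chi2, bic = win$bic, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Optimize the global tumbling time jointly with per-residue fits
#'
#' Alternates a 1-D refinement of the isotropic tumbling time (minimizing
#' the total chi2 with per-residue parameters refit at each candidate tm)
#' with per-residue BIC model selection, until tm changes by less than
#' \code{tolNs} nanoseconds. Isotropic diffusion only.
#'
#' @param dataset a \linkS4class{RelaxationDataset} with >= 5 residues.
#' @param spin a \linkS4class{SpinParameters}.
#' @param models candidate models for selection (default 1:5).
#' @param tmRange search interval in seconds (default 3-20 ns).
#' @param tolNs convergence tolerance on tm in ns (default 0.01).
#' @param maxIter iteration cap; oscillation past it aborts with a
#'   diagnostic.
#' @return list with \code{tm} (s), \code{fits} (the final per-residue
#'   table from \code{\link{fitDataset}}) and \code{iterations}.
#' @export
fitGlobalTm <- function(dataset, spin, models = 1:5,
                        tmRange = c(3e-9, 20e-9), tolNs = 0.01,
                        maxIter = 12L) {
  if (nrow(dataset@rates) < 5L)
    stop("at least 5 usable residues are required for a global tm fit")
  tab <- dataset@rates
  obsL <- lapply(seq_len(nrow(tab)), function(i)
    list(obs = c(r1 = tab$r1[i], r2 = tab$r2[i], noe = tab$noe[i]),
         sds = c(r1 = tab$r1_sd[i], r2 = tab$r2_sd[i], noe = tab$noe_sd[i])))
  totalChi2 <- function(tm, modelPerRes) {
    sum(vapply(seq_along(obsL), function(i) {
      f <- fitResidue(obsL[[i]]$obs, obsL[[i]]$sds, spin, tm,
                      modelPerRes[i])
      if (isTRUE(f$converged)) f$chi2 else 1e6
    }, numeric(1)))
  }
  ## initialize tm from the R2/R1 ratio of the cohort means
  tm <- tryCatch(estimateTcFromR2R1(mean(tab$r1), mean(tab$r2),
                                    dataset@field1H),
                 error = function(e) mean(tmRange))
  tm <- min(max(tm, tmRange[1]), tmRange[2])
  fits <- NULL
  for (it in seq_len(maxIter)) {
    fits <- fitDataset(dataset, spin, tm, models = models)
    modelPerRes <- ifelse(is.na(fits$model), 1L, fits$model)
    opt <- stats::optimize(totalChi2, interval = tmRange,
                           modelPerRes = modelPerRes, tol = 1e-12)
    tmNew <- opt$minimum
    if (abs(tmNew - tm) < tolNs * 1e-9) {
      tm <- tmNew
      fits <- fitDataset(dataset, spin, tm, models = models)
      return(list(tm = tm, fits = fits, iterations = it))
    }
    tm <- tmNew
  }
  stop("global tm fit did not settle within ", maxIter,
       " iterations (last tm = ", signif(tm * 1e9, 4), " ns); the tm/model ",
       "alternation is oscillating")
}
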