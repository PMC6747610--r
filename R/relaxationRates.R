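## Monoexponential relaxation-rate fitting, HetNOE ratios, and the single
## field R2/R1 estimate of the rotational correlation time.

## Least-squares fit of I(t) = A exp(-R t) by profiling out the amplitude:
## for fixed R the optimal A is closed-form, leaving a 1-D minimization in
## R. No baseline offset is fitted (fully relaxed signal decays to zero).
.monoexpLS <- function(delays, intensities, upper) {
  sse <- function(R) {
    e <- exp(-R * delays)
    A <- sum(intensities * e) / sum(e * e)
    sum((intensities - A * e)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, upper), tol = 1e-12)
  R <- opt$minimum
  ## refine near the lower boundary: optimize() never returns exactly 0
  if (sse(0) <= opt$objective) R <- 0
  e <- exp(-R * delays)
  list(rate = R, amplitude = sum(intensities * e) / sum(e * e))
}

#' Fit a monoexponential decay to a peak-intensity series
#'
#' Least-squares fit of \code{I(t) = A exp(-R t)} to a per-residue
#' intensity-versus-delay series, with the uncertainty of the rate taken
#' as the half-width of the central \code{ciLevel} interval over
#' \code{nReplicas} refits of the data perturbed by Gaussian noise of
#' standard deviation \code{noiseSD} (the spectral baseline noise).
#'
#' @param series An \linkS4class{IntensitySeries}.
#' @param nReplicas Monte-Carlo replicas (default 500).
#' @param ciLevel confidence level of the reported uncertainty (default 0.68).
#' @param seed integer seed; required whenever \code{nReplicas > 0}.
#' @return A \linkS4class{RateFit}. Non-convergence is flagged on the
#'   \code{converged} slot, never returned as a silent zero.
#' @examples
#' s <- IntensitySeries(1, c(0.1, 0.3, 0.5), exp(-2 * c(0.1, 0.3, 0.5)), 1e-3)
#' fitMonoexponential(s, nReplicas = 0)
#' @export
fitMonoexponential <- function(series, nReplicas = 500L, ciLevel = 0.68,
                               seed = NULL) {
  stopifnot(is(series, "IntensitySeries"))
  t <- series@delays; y <- series@intensities
  if (length(unique(t)) < 3L)
    stop("at least 3 distinct delays are required to fit a rate")
  if (!any(y > 3 * series@noiseSD))
    stop("no intensity above 3x the noise floor; series is unquantifiable")
  if (nReplicas > 0L && is.null(seed))
    stop("a seed is required for Monte-Carlo uncertainties")
  ## upper search bound: decay faster than this is indistinguishable from
  ## an instantaneous loss at the earliest delay
  upper <- 30 / min(t)
  fit <- .monoexpLS(t, y, upper)
  converged <- is.finite(fit$rate) && fit$rate < 0.999 * upper
  rateSD <- NA_real_
  if (nReplicas > 0L && converged) {
    rates <- withSeed(seed, {
      vapply(seq_len(nReplicas), function(i) {
        yi <- y + stats::rnorm(length(y), sd = series@noiseSD)
        .monoexpLS(t, yi, upper)$rate
      }, numeric(1))
    })
    rateSD <- ciHalfWidth(rates, ciLevel)
  }
  new("RateFit", rate = fit$rate, amplitude = fit$amplitude,
      rateSD = rateSD, nReplicas = as.integer(nReplicas),
      ciLevel = ciLevel, converged = converged)
}

#' Heteronuclear NOE from saturated/reference intensity pair
#'
#' The steady-state heteronuclear NOE is the ratio of peak intensities
#' measured with and without proton saturation; its uncertainty follows by
#' first-order propagation of the baseline noise on both intensities.
#' Negative values (flexible residues) pass through unclamped.
#'
#' @param iSat intensity with proton saturation.
#' @param iRef intensity without saturation.
#' @param noiseSD spectral baseline noise sd (same units).
#' @return list with elements \code{noe} and \code{noeSD}.
#' @export
computeHetNoe <- function(iSat, iRef, noiseSD) {
  if (iRef <= 0 || iRef <= 3 * noiseSD)
    stop("reference intensity at or below the noise floor; ratio undefined")
  noe <- iSat / iRef
  noeSD <- abs(noe) * sqrt((noiseSD / iSat)^2 + (noiseSD / iRef)^2)
  if (!is.finite(noeSD)) noeSD <- noiseSD / iRef
  list(noe = noe, noeSD = noeSD)
}

#' Rotational correlation time from the mean R2/R1 ratio
#'
#' Single-field estimator
#' \deqn{t_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7}}
#' with \eqn{\nu_N} the 15N Larmor frequency at the given proton field.
#' Valid for slow, isotropic tumbling where high-frequency spectral
#' density terms are negligible.
#'
#' @param meanR1 mean longitudinal rate (s^-1).
#' @param meanR2 mean transverse rate (s^-1).
#' @param field1H proton frequency (Hz), e.g. 700e6.
#' @return correlation time in seconds.
#' @examples
#' estimateTcFromR2R1(1.05, 17.3, 700e6) * 1e9  # ~10.7 ns
#' @export
estimateTcFromR2R1 <- function(meanR1, meanR2, field1H) {
  stopifnot(meanR1 > 0, meanR2 > 0, field1H > 0)
  ratio <- meanR2 / meanR1
  rad <- 6 * ratio - 7
  if (rad < 0)
    stop("R2/R1 = ", signif(ratio, 4),
         " is below the estimator's validity threshold of 7/6;",
         " the radicand 6*R2/R1 - 7 is negative")
  nuN <- larmorN(field1H)
  sqrt(rad) / (4 * pi * nuN)
}

#' Fit all relaxation series of a cohort into a per-residue rate table
#'
#' Convenience batch driver: fits R1 and R2 decay series and HetNOE pairs
#' residue by residue and assembles a \linkS4class{RelaxationDataset}.
#'
#' @param r1Series,r2Series lists of \linkS4class{IntensitySeries}.
#' @param noePairs data.frame with columns residue_id, i_sat, i_ref,
#'   noise_sd.
#' @param field1H proton frequency (Hz).
#' @param nReplicas,ciLevel,seed Monte-Carlo settings passed on to
#'   \code{\link{fitMonoexponential}}.
#' @return A \linkS4class{RelaxationDataset}.
#' @export
fitRelaxationDataset <- function(r1Series, r2Series, noePairs,
                                 field1H = 700e6, nReplicas = 500L,
                                 ciLevel = 0.68, seed = 1L) {
  fitOne <- function(s, k) {
    f <- fitMonoexponential(s, nReplicas, ciLevel, seed = seed + 7L * k)
    c(rate = f@rate, sd = f@rateSD)
  }
  ids1 <- vapply(r1Series, function(s) s@residueId, integer(1))
  ids2 <- vapply(r2Series, function(s) s@residueId, integer(1))
  ids <- sort(intersect(intersect(ids1, ids2), noePairs$residue_id))
  rows <- lapply(ids, function(id) {
    f1 <- fitOne(r1Series[[match(id, ids1)]], id)
    f2 <- fitOne(r2Series[[match(id, ids2)]], id + 100000L)
    np <- noePairs[match(id, noePairs$residue_id), ]
    hn <- computeHetNoe(np$i_sat, np$i_ref, np$noise_sd)
    data.frame(residue_id = id, r1 = f1["rate"], r1_sd = f1["sd"],
               r2 = f2["rate"], r2_sd = f2["sd"],
               noe = hn$noe, noe_sd = hn$noeSD, row.names = NULL)
  })
  RelaxationDataset(do.call(rbind, rows), field1H)
}
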