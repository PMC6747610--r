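#' @import methods
NULL

#' Peak-intensity decay series for one residue
#'
#' Container for a per-residue peak-intensity table versus relaxation delay,
#' the unit of input for monoexponential rate fitting. Delays are in seconds,
#' intensities in arbitrary spectrometer units, and \code{noiseSD} is the
#' standard deviation of the spectral baseline noise (taken as the
#' uncertainty of every peak height).
#'
#' @slot residueId integer, 1-based sequence position.
#' @slot delays numeric, strictly positive unique relaxation delays (s).
#' @slot intensities numeric, peak heights, same length as \code{delays}.
#' @slot noiseSD numeric(1), baseline noise standard deviation (> 0).
#' @export
setClass("IntensitySeries",
  representation(residueId = "integer", delays = "numeric",
                 intensities = "numeric", noiseSD = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@delays) != length(object@intensities))
      msg <- c(msg, "delays and intensities must have equal length")
    if (any(object@delays <= 0)) msg <- c(msg, "delays must be strictly positive")
    if (anyDuplicated(object@delays)) msg <- c(msg, "delays must be unique")
    if (!all(is.finite(object@intensities)))
      msg <- c(msg, "intensities must be finite")
    if (length(object@noiseSD) != 1L || !is.finite(object@noiseSD) ||
        object@noiseSD <= 0)
      msg <- c(msg, "noiseSD must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{IntensitySeries}
#' @param residueId integer sequence position.
#' @param delays relaxation delays (s).
#' @param intensities peak heights.
#' @param noiseSD spectral baseline noise sd.
#' @return An \linkS4class{IntensitySeries}.
#' @export
IntensitySeries <- function(residueId, delays, intensities, noiseSD) {
  new("IntensitySeries", residueId = as.integer(residueId),
      delays = as.numeric(delays), intensities = as.numeric(intensities),
      noiseSD = as.numeric(noiseSD))
}

#' Result of a monoexponential rate fit
#'
#' @slot rate fitted decay rate (s^-1).
#' @slot amplitude fitted initial intensity.
#' @slot rateSD Monte-Carlo uncertainty on the rate (s^-1).
#' @slot nReplicas number of Monte-Carlo replicas used.
#' @slot ciLevel central confidence level of the reported uncertainty.
#' @slot converged logical flag; FALSE marks a flagged failure, never a
#'   silent zero.
#' @export
setClass("RateFit",
  representation(rate = "numeric", amplitude = "numeric", rateSD = "numeric",
                 nReplicas = "integer", ciLevel = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@ciLevel) == 1L &&
        (object@ciLevel <= 0 || object@ciLevel >= 1))
      msg <- c(msg, "ciLevel must be in (0, 1)")
    if (length(object@rateSD) == 1L && is.finite(object@rateSD) &&
        object@rateSD < 0)
      msg <- c(msg, "rateSD must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Per-residue relaxation dataset (R1, R2, HetNOE at one field)
#'
#' The unit of model-free input: one row per residue with rates and
#' uncertainties measured at the stated spectrometer field.
#'
#' @slot rates data.frame with columns residue_id, r1, r1_sd, r2, r2_sd,
#'   noe, noe_sd.
#' @slot field1H proton frequency of the field (Hz).
#' @export
setClass("RelaxationDataset",
  representation(rates = "data.frame", field1H = "numeric"),
  validity = function(object) {
    need <- c("residue_id", "r1", "r1_sd", "r2", "r2_sd", "noe", "noe_sd")
    miss <- setdiff(need, names(object@rates))
    msg <- character()
    if (length(miss))
      msg <- c(msg, paste("rates is missing columns:", paste(miss, collapse = ", ")))
    if (length(object@field1H) != 1L || object@field1H <= 0)
      msg <- c(msg, "field1H must be a single positive frequency in Hz")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{RelaxationDataset}
#' @param rates data.frame of per-residue rates (see class docs).
#' @param field1H proton frequency in Hz.
#' @return A \linkS4class{RelaxationDataset}.
#' @export
RelaxationDataset <- function(rates, field1H) {
  new("RelaxationDataset", rates = as.data.frame(rates),
      field1H = as.numeric(field1H))
}

#' Spin-interaction parameters for 15N relaxation
#'
#' Field and interaction constants entering the dipolar and CSA relaxation
#' expressions.
#'
#' @slot field1H proton frequency (Hz), default 700e6.
#' @slot rNH N-H bond length (Angstrom), default 1.02.
#' @slot csa 15N chemical shift anisotropy (ppm), default -172.
#' @export
setClass("SpinParameters",
  representation(field1H = "numeric", rNH = "numeric", csa = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@field1H <= 0) msg <- c(msg, "field1H must be > 0")
    if (object@rNH <= 0) msg <- c(msg, "rNH must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{SpinParameters}
#' @param field1H proton frequency (Hz).
#' @param rNH N-H bond length (Angstrom).
#' @param csa 15N CSA (ppm).
#' @return A \linkS4class{SpinParameters}.
#' @export
SpinParameters <- function(field1H = 700e6, rNH = 1.02, csa = -172) {
  new("SpinParameters", field1H = as.numeric(field1H), rNH = as.numeric(rNH),
      csa = as.numeric(csa))
}

#' CPMG relaxation dispersion profile for one residue
#'
#' @slot residueId integer.
#' @slot nuCpmg refocusing frequencies (Hz), sorted unique after duplicate
#'   reduction.
#' @slot r2eff effective transverse rates (s^-1).
#' @slot r2effSD per-point uncertainties (s^-1), from duplicate points.
#' @slot field1H proton frequency (Hz).
#' @slot tRelax constant relaxation delay (s), default 0.030.
#' @export
setClass("DispersionProfile",
  representation(residueId = "integer", nuCpmg = "numeric", r2eff = "numeric",
                 r2effSD = "numeric", field1H = "numeric", tRelax = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@nuCpmg)
    if (length(object@r2eff) != n || length(object@r2effSD) != n)
      msg <- c(msg, "nuCpmg, r2eff and r2effSD must have equal length")
    if (any(object@nuCpmg <= 0)) msg <- c(msg, "nuCpmg must be positive")
    if (is.unsorted(object@nuCpmg, strictly = TRUE))
      msg <- c(msg, "nuCpmg must be sorted and unique")
    if (object@tRelax <= 0) msg <- c(msg, "tRelax must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{DispersionProfile}
#'
#' Repeated \code{nuCpmg} points are averaged; their half-range, floored by
#' \code{minSD}, becomes the per-point uncertainty (pairs of repeats drive
#' the error analysis).
#'
#' @param residueId integer.
#' @param nuCpmg refocusing frequencies (Hz); duplicates allowed.
#' @param r2eff effective rates (s^-1).
#' @param field1H proton frequency (Hz).
#' @param tRelax constant relaxation delay (s).
#' @param minSD floor for the per-point uncertainty (s^-1).
#' @return A \linkS4class{DispersionProfile}.
#' @export
DispersionProfile <- function(residueId, nuCpmg, r2eff, field1H = 700e6,
                              tRelax = 0.030, minSD = 0.1) {
  keep <- is.finite(r2eff)
  nuCpmg <- nuCpmg[keep]; r2eff <- r2eff[keep]
  key <- factor(nuCpmg, levels = sort(unique(nuCpmg)))
  mean_r <- tapply(r2eff, key, mean)
  half <- tapply(r2eff, key, function(x) diff(range(x)) / 2)
  sd <- pmax(half, minSD)
  new("DispersionProfile", residueId = as.integer(residueId),
      nuCpmg = as.numeric(levels(key)), r2eff = as.numeric(mean_r),
      r2effSD = as.numeric(sd), field1H = as.numeric(field1H),
      tRelax = as.numeric(tRelax))
}

#' Two-site exchange parameters
#'
#' Parameters of the two-site conformational exchange model: total exchange
#' rate kex = kAB + kBA, minor-state population pB, absolute 15N chemical
#' shift difference between the states (ppm) and the exchange-free
#' transverse rate. Canonical form: pB < 0.5, dw >= 0.
#'
#' @slot kex exchange rate (s^-1).
#' @slot pb minor-state population (fraction).
#' @slot dw |chemical shift difference| (ppm).
#' @slot r20 exchange-free transverse rate (s^-1).
#' @export
setClass("TwoSiteParams",
  representation(kex = "numeric", pb = "numeric", dw = "numeric",
                 r20 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@kex <= 0)) msg <- c(msg, "kex must be > 0")
    if (any(object@pb <= 0 | object@pb >= 0.5))
      msg <- c(msg, "pb must be in (0, 0.5)")
    if (any(object@dw < 0)) msg <- c(msg, "dw must be >= 0")
    if (any(object@r20 <= 0)) msg <- c(msg, "r20 must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{TwoSiteParams}
#' @param kex exchange rate (s^-1).
#' @param pb minor-state population, in (0, 0.5).
#' @param dw |chemical shift difference| (ppm).
#' @param r20 exchange-free transverse rate (s^-1).
#' @return A \linkS4class{TwoSiteParams}.
#' @export
TwoSiteParams <- function(kex, pb, dw, r20) {
  new("TwoSiteParams", kex = as.numeric(kex), pb = as.numeric(pb),
      dw = as.numeric(dw), r20 = as.numeric(r20))
}

#' Hydrogen-deuterium exchange intensity series for one residue
#'
#' @slot residueId integer.
#' @slot times exchange times since D2O exposure (s), increasing.
#' @slot intensities peak heights.
#' @slot mode "d2o_100" (decay to zero) or "d2o_50" (decay to half
#'   amplitude, the 50/50 H2O/D2O slow-exchange acquisition).
#' @slot firstPointTime earliest observable time (s).
#' @export
setClass("HdxSeries",
  representation(residueId = "integer", times = "numeric",
                 intensities = "numeric", mode = "character",
                 firstPointTime = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@intensities))
      msg <- c(msg, "times and intensities must have equal length")
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
    if (!object@mode %in% c("d2o_100", "d2o_50"))
      msg <- c(msg, "mode must be 'd2o_100' or 'd2o_50'")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{HdxSeries}
#' @param residueId integer.
#' @param times times since D2O exposure (s).
#' @param intensities peak heights.
#' @param mode "d2o_100" or "d2o_50".
#' @param firstPointTime earliest observable time (s); defaults to the
#'   first sampled time.
#' @return An \linkS4class{HdxSeries}.
#' @export
HdxSeries <- function(residueId, times, intensities, mode = "d2o_100",
                      firstPointTime = times[1]) {
  new("HdxSeries", residueId = as.integer(residueId),
      times = as.numeric(times), intensities = as.numeric(intensities),
      mode = mode, firstPointTime = as.numeric(firstPointTime))
}

#' Dynamic light scattering measurement
#'
#' Normalized intensity autocorrelation (g2 - 1) versus lag time together
#' with the optical and solvent constants needed to convert decay rates
#' into diffusion coefficients.
#'
#' @slot lagTimes lag times (s).
#' @slot g2Minus1 baseline-subtracted autocorrelation.
#' @slot wavelength laser wavelength (m), default 633e-9.
#' @slot refractiveIndex solvent refractive index, default 1.333.
#' @slot angle scattering angle (degrees), default 173.
#' @slot temperature K, default 298.15.
#' @slot viscosity Pa s, default 8.872e-4.
#' @export
setClass("DlsMeasurement",
  representation(lagTimes = "numeric", g2Minus1 = "numeric",
                 wavelength = "numeric", refractiveIndex = "numeric",
                 angle = "numeric", temperature = "numeric",
                 viscosity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@lagTimes) != length(object@g2Minus1))
      msg <- c(msg, "lagTimes and g2Minus1 must have equal length")
    if (object@wavelength <= 0 || object@refractiveIndex <= 0 ||
        object@temperature <= 0 || object@viscosity <= 0)
      msg <- c(msg, "physical constants must be positive")
    if (object@angle <= 0 || object@angle >= 180)
      msg <- c(msg, "angle must be in (0, 180) degrees")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{DlsMeasurement}
#' @param lagTimes lag times (s).
#' @param g2Minus1 baseline-subtracted autocorrelation values.
#' @param wavelength laser wavelength (m).
#' @param refractiveIndex solvent refractive index.
#' @param angle scattering angle (degrees).
#' @param temperature K.
#' @param viscosity Pa s.
#' @return A \linkS4class{DlsMeasurement}.
#' @export
DlsMeasurement <- function(lagTimes, g2Minus1, wavelength = 633e-9,
                           refractiveIndex = 1.333, angle = 173,
                           temperature = 298.15, viscosity = 8.872e-4) {
  new("DlsMeasurement", lagTimes = as.numeric(lagTimes),
      g2Minus1 = as.numeric(g2Minus1), wavelength = wavelength,
      refractiveIndex = refractiveIndex, angle = angle,
      temperature = temperature, viscosity = viscosity)
}

#' N-H unit-vector trajectory for one residue
#'
#' @slot residueId integer.
#' @slot frames numeric matrix, one row per frame, columns x, y, z;
#'   each row unit-norm within 1e-6.
#' @slot dt frame spacing (s).
#' @slot window analysis window length (s), default 2.5e-9.
#' @export
setClass("VectorTrajectory",
  representation(residueId = "integer", frames = "matrix", dt = "numeric",
                 window = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@frames) != 3L) msg <- c(msg, "frames must have 3 columns")
    nrm <- sqrt(rowSums(object@frames^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "frame vectors must be unit-norm within 1e-6")
    if (object@window < 10 * object@dt)
      msg <- c(msg, "window must be at least 10 frame spacings")
    if (length(msg)) msg else TRUE
  })

#' Constructor for \linkS4class{VectorTrajectory}
#' @param residueId integer.
#' @param frames n x 3 matrix of unit vectors.
#' @param dt frame spacing (s).
#' @param window window length (s).
#' @return A \linkS4class{VectorTrajectory}.
#' @export
VectorTrajectory <- function(residueId, frames, dt, window = 2.5e-9) {
  new("VectorTrajectory", residueId = as.integer(residueId),
      frames = as.matrix(frames), dt = as.numeric(dt),
      window = as.numeric(window))
}

#' Ground-truth scenario for the synthetic-data generators
#'
#' Defines the simulated experimental conditions all generators draw
#' from: cohort size,
#' tumbling time, order-parameter distribution, the exchanging fraction and
#' its shared excited-state parameters, the HDX lifetime distribution, the
#' variant contrast factors and the per-data-type noise levels. The
#' "germline" and "mutant" presets encode the two-variant comparison
#' conditions (mean S2 0.84 vs 0.88, kex 1175 vs 2008 s^-1, pB 15% vs 10%,
#' a ~6-fold HDX lifetime contrast).
#'
#' @slot seed integer, mandatory; every generator is deterministic given it.
#' @slot nResidues cohort size.
#' @slot tm global tumbling time (s).
#' @slot s2Mean,s2SD order-parameter distribution (truncated to [0, 1] and
#'   recentred so the cohort mean equals s2Mean).
#' @slot rexFraction fraction of residues with exchange broadening.
#' @slot exchange \linkS4class{TwoSiteParams} of the shared excited state
#'   (dw slot holds the mean of the per-residue dw draw).
#' @slot hdxMeanlog,hdxSdlog log-normal lifetime distribution (s).
#' @slot contrast named numeric multipliers applied to the second variant
#'   (kex, pb, lifetime, s2shift additive on S2).
#' @slot noise named numeric noise sds: intensity (fraction of amplitude),
#'   r1, r2, noe (rate units), r2eff (s^-1), hdx (fraction), dls (fraction).
#' @export
setClass("SyntheticScenario",
  representation(seed = "integer", nResidues = "integer", tm = "numeric",
                 s2Mean = "numeric", s2SD = "numeric", rexFraction = "numeric",
                 exchange = "TwoSiteParams", hdxMeanlog = "numeric",
                 hdxSdlog = "numeric", contrast = "numeric", noise = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@rexFraction < 0 || object@rexFraction > 1)
      msg <- c(msg, "rexFraction must be in [0, 1]")
    mult <- setdiff(names(object@contrast), "s2shift")
    if (length(mult) && any(object@contrast[mult] <= 0))
      msg <- c(msg, "multiplicative contrast factors must be positive")
    if (length(msg)) msg else TRUE
  })
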