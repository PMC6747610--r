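## Physical constants (SI) shared across the package.
.constants <- list(
  gammaH = 2.6752218744e8,   # 1H gyromagnetic ratio, rad s^-1 T^-1
  gammaN = -2.7126180e7,     # 15N gyromagnetic ratio, rad s^-1 T^-1
  hbar   = 1.054571817e-34,  # J s
  mu0    = 4 * pi * 1e-7,    # T^2 m^3 J^-1
  kB     = 1.380649e-23,     # J K^-1
  Rgas   = 8.314462618e-3    # kJ mol^-1 K^-1
)

#' 15N Larmor frequency from the 1H spectrometer frequency
#'
#' Converts the spectrometer proton frequency (e.g. 700e6 Hz) to the
#' magnitude of the 15N Larmor frequency via the gyromagnetic-ratio
#' quotient.
#'
#' @param field1H Proton Larmor frequency in Hz.
#' @return 15N Larmor frequency magnitude in Hz.
#' @export
larmorN <- function(field1H) {
  stopifnot(is.numeric(field1H), field1H > 0)
  field1H * abs(.constants$gammaN / .constants$gammaH)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Half-width of the central `ci` interval of a sample, used for all
## Monte-Carlo uncertainties (ci = 0.68 by default throughout).
ciHalfWidth <- function(x, ci = 0.68) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  qs <- stats::quantile(x, probs = c((1 - ci) / 2, 1 - (1 - ci) / 2),
                        names = FALSE, type = 7)
  unname(diff(qs)) / 2
}
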