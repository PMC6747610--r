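## Slow-timescale stability from hydrogen-deuterium exchange: decay
## fitting in both acquisition modes, intrinsic rates from the
## poly-DL-alanine reference scheme, protection factors, per-residue
## free energies and the germline-vs-mutant ddG comparison.

#' Lifetime class boundaries (seconds)
#'
#' Residues are binned by mean exchange lifetime tau = 1/ke into
#' \code{before_first_point} (already at plateau when first observed),
#' \code{lt_100s}, \code{100_600s} and \code{gt_600s}. Boundaries are
#' exactly 100 s and 600 s.
#'
#' @param lifetime lifetime(s) in seconds (vectorized).
#' @param beforeFirst logical flag(s) marking residues that exchanged
#'   before the first time point.
#' @return character vector of class labels.
#' @export
hdxLifetimeClass <- function(lifetime, beforeFirst = FALSE) {
  beforeFirst <- rep_len(beforeFirst, length(lifetime))
  out <- ifelse(beforeFirst, "before_first_point",
         ifelse(lifetime < 100, "lt_100s",
         ifelse(lifetime <= 600, "100_600s", "gt_600s")))
  out
}

## profiled least squares for A*(base + (1-base)*exp(-k t)):
## base = 0 (100% D2O) or 0.5 (50/50 solvent, plateau pinned at half
## amplitude). For fixed k the optimal A is closed-form.
.hdxLS <- function(times, y, base, upper) {
  sse <- function(k) {
    g <- base + (1 - base) * exp(-k * times)
    A <- sum(y * g) / sum(g * g)
    sum((y - A * g)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, upper), tol = 1e-12)
  k <- opt$minimum
  if (sse(0) <= opt$objective) k <- 0
  g <- base + (1 - base) * exp(-k * times)
  list(k = k, A = sum(y * g) / sum(g * g))
}

#' Fit an H/D exchange decay
#'
#' \code{d2o_100} series are fit to \code{A exp(-k t)}; \code{d2o_50}
#' series to \code{A [0.5 + 0.5 exp(-k t)]} (the 50/50 solvent pins the
#' equilibrium occupancy at one half, which stabilizes fits on coarse
#' grids). A series already at its plateau at the first point is
#' classified \code{before_first_point} and flagged censored: such
#' residues are later assigned the fastest rate measured in the dataset.
#'
#' @param series an \linkS4class{HdxSeries} with >= 4 points.
#' @param noiseSD intensity noise sd used for the plateau test and
#'   Monte-Carlo (default: sd of the last quarter of the series).
#' @param nReplicas Monte-Carlo replicas for the rate uncertainty.
#' @param ciLevel confidence level of the uncertainty.
#' @param seed integer seed, required when \code{nReplicas > 0}.
#' @return list with \code{ke}, \code{keSD}, \code{amplitude},
#'   \code{lifetime}, \code{censored} (TRUE when before_first_point),
#'   \code{lifetimeClass}.
#' @export
fitExchangeDecay <- function(series, noiseSD = NULL, nReplicas = 200L,
                             ciLevel = 0.68, seed = NULL) {
  stopifnot(is(series, "HdxSeries"))
  t <- series@times; y <- series@intensities
  if (length(t) < 4L) stop("at least 4 points are required")
  base <- if (series@mode == "d2o_100") 0 else 0.5
  if (is.null(noiseSD)) {
    tail <- y[t >= stats::quantile(t, 0.75)]
    noiseSD <- max(stats::sd(tail), 1e-12)
  }
  ## plateau test: early mean indistinguishable from late mean means the
  ## observable decay happened before the first sample
  early <- mean(y[seq_len(min(3L, length(y)))])
  late <- mean(y[t >= stats::quantile(t, 0.75)])
  atPlateau <- (early - late) < 3 * noiseSD
  if (atPlateau) {
    return(list(ke = NA_real_, keSD = NA_real_, amplitude = NA_real_,
                lifetime = NA_real_, censored = TRUE,
                lifetimeClass = "before_first_point"))
  }
  upper <- 30 / series@firstPointTime
  fit <- .hdxLS(t, y, base, upper)
  ## decay essentially complete before the first sample
  if (fit$k >= 0.999 * upper || 1 / max(fit$k, 1e-300) <
      series@firstPointTime / 3) {
    return(list(ke = NA_real_, keSD = NA_real_, amplitude = fit$A,
                lifetime = NA_real_, censored = TRUE,
                lifetimeClass = "before_first_point"))
  }
  keSD <- NA_real_
  if (nReplicas > 0L) {
    if (is.null(seed)) stop("a seed is required for Monte-Carlo uncertainties")
    ks <- withSeed(seed, {
      vapply(seq_len(nReplicas), function(i) {
        yi <- y + stats::rnorm(length(y), sd = noiseSD)
        .hdxLS(t, yi, base, upper)$k
      }, numeric(1))
    })
    keSD <- ciHalfWidth(ks, ciLevel)
  }
  lt <- 1 / fit$k
  list(ke = fit$k, keSD = keSD, amplitude = fit$A, lifetime = lt,
       censored = FALSE, lifetimeClass = hdxLifetimeClass(lt))
}

#' Merge fast (50/50) and slow (100% D2O) exchange series
#'
#' A single least-squares scale factor on the fitted amplitudes of
#' residues quantified in both sets maps the fast series onto the slow
#' series' intensity scale; per residue, the fast-mode rate is preferred
#' when the slow mode censored it. The effective earliest observable
#' time of the merged data is half the fast-mode first sampling time
#' (the 50% pre-exchange halves the decaying amplitude, pushing the
#' quantifiable onset earlier).
#'
#' @param fast list of \linkS4class{HdxSeries} in mode d2o_50.
#' @param slow list of \linkS4class{HdxSeries} in mode d2o_100.
#' @return list with \code{table} (residue_id, ke, ke_sd, lifetime,
#'   censored, lifetime_class, source), \code{scale},
#'   \code{effectiveEarliestTime} (s), \code{merged} logical.
#'   With no shared residues the two sets are returned unmerged with a
#'   warning.
#' @export
normalizeFastSeries <- function(fast, slow) {
  fitsF <- lapply(fast, fitExchangeDecay, nReplicas = 0L)
  fitsS <- lapply(slow, fitExchangeDecay, nReplicas = 0L)
  idF <- vapply(fast, function(s) s@residueId, integer(1))
  idS <- vapply(slow, function(s) s@residueId, integer(1))
  shared <- intersect(idF, idS)
  ampOk <- function(f) !isTRUE(f$censored) && is.finite(f$amplitude) &&
    f$amplitude > 0
  shared <- Filter(function(id) {
    ampOk(fitsF[[match(id, idF)]]) && ampOk(fitsS[[match(id, idS)]])
  }, shared)
  mkRow <- function(id, f, src) data.frame(
    residue_id = id, ke = f$ke, ke_sd = f$keSD, lifetime = f$lifetime,
    censored = f$censored, lifetime_class = f$lifetimeClass, source = src,
    stringsAsFactors = FALSE)
  if (length(shared) < 3L) {
    warning("fewer than 3 residues quantified in both modes; ",
            "returning the sets unmerged")
    tab <- rbind(
      do.call(rbind, Map(mkRow, idS, fitsS, "d2o_100")),
      do.call(rbind, Map(mkRow, idF, fitsF, "d2o_50")))
    return(list(table = tab, scale = NA_real_,
                effectiveEarliestTime = NA_real_, merged = FALSE))
  }
  aF <- vapply(shared, function(id) fitsF[[match(id, idF)]]$amplitude,
               numeric(1))
  aS <- vapply(shared, function(id) fitsS[[match(id, idS)]]$amplitude,
               numeric(1))
  scale <- sum(aS * aF) / sum(aF * aF)   # least squares aS ~ scale * aF
  rows <- lapply(union(idS, idF), function(id) {
    fS <- if (id %in% idS) fitsS[[match(id, idS)]] else NULL
    fF <- if (id %in% idF) fitsF[[match(id, idF)]] else NULL
    if (!is.null(fS) && !fS$censored) mkRow(id, fS, "d2o_100")
    else if (!is.null(fF) && !fF$censored) mkRow(id, fF, "d2o_50")
    else mkRow(id, if (!is.null(fS)) fS else fF,
               if (!is.null(fS)) "d2o_100" else "d2o_50")
  })
  firstFast <- min(vapply(fast, function(s) s@firstPointTime, numeric(1)))
  list(table = do.call(rbind, rows), scale = scale,
       effectiveEarliestTime = firstFast / 2, merged = TRUE)
}

.hdxFactors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "intrinsic_rate_factors.tsv",
                          package = "ProtDynamics")
      cache <<- utils::read.delim(path, comment.char = "#",
                                  stringsAsFactors = FALSE)
      rownames(cache) <<- cache$res
    }
    cache
  }
})

#' Intrinsic backbone amide exchange rate
#'
#' Sequence-dependent intrinsic exchange rate from the poly-DL-alanine
#' reference rates with nearest-neighbour, pH and temperature
#' corrections (Bai et al. 1993 scheme), for D2O solvent:
#' \deqn{k_{int} = k_A F_A 10^{-pD} + k_B F_B 10^{pD - pK_D} + k_W F_B}
#' where \eqn{F_A, F_B} collect the log-additive side-chain factors of
#' the residue itself and its predecessor, \eqn{pD = pH_{read} + 0.4},
#' and each reference rate carries an Arrhenius temperature correction
#' from the 293 K reference.
#'
#' @param sequence one-letter amino-acid string or character vector.
#' @param position 1-based index of the amide's residue; must not be the
#'   chain start or a proline (no backbone amide proton).
#' @param pH glass-electrode pH reading of the D2O buffer.
#' @param temperature K.
#' @return intrinsic rate in s^-1.
#' @export
intrinsicRate <- function(sequence, position, pH = 7.4,
                          temperature = 298.15) {
  seqv <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]]
          else sequence
  seqv <- toupper(seqv)
  if (position < 2L || position > length(seqv))
    stop("position must be an internal residue (the chain start has no ",
         "exchangeable backbone amide here)")
  res <- seqv[position]; prev <- seqv[position - 1L]
  if (res == "P")
    stop("proline has no backbone amide proton; no intrinsic rate")
  fac <- .hdxFactors()
  if (!res %in% rownames(fac) || !prev %in% rownames(fac))
    stop("unknown residue code: ", res, "/", prev)
  FA <- 10^(fac[prev, "acid_l"] + fac[res, "acid_r"])
  FB <- 10^(fac[prev, "base_l"] + fac[res, "base_r"])
  pD <- pH + 0.4
  ## poly-DL-alanine reference rates at 293 K (log10; min^-1 M^-1 scale
  ## for the catalyzed terms, min^-1 for water) and activation energies
  ## (kcal/mol) for the Arrhenius correction
  kA <- 10^1.62; kB <- 10^10.05; kW <- 10^(-1.5)
  Rcal <- 1.987204e-3
  arr <- function(Ea) exp(-Ea / Rcal * (1 / temperature - 1 / 293))
  kA <- kA * arr(14); kB <- kB * arr(17); kW <- kW * arr(19)
  pKD <- 15.05
  kmin <- kA * FA * 10^(-pD) + kB * FB * 10^(pD - pKD) + kW * FB
  kmin / 60
}

#' Protection factor and exchange free energy
#'
#' \deqn{\Delta G_{HD} = -RT \ln(P), \quad P = k_e / k_{int}}
#' The quotient convention \code{P = ke/kint} drives the free-energy
#' relation; the reciprocal \code{Pprime = kint/ke} (the common
#' protection-factor convention, > 1 for protected amides) is also
#' returned, labelled, to prevent sign errors downstream.
#'
#' @param ke observed exchange rate (s^-1), > 0.
#' @param kint intrinsic rate (s^-1), > 0.
#' @param temperature K.
#' @return list with \code{P} (ke/kint), \code{Pprime} (kint/ke),
#'   \code{dg} (kJ/mol), \code{convention = "ke_over_kint"}.
#' @export
protectionAndEnergy <- function(ke, kint, temperature = 298.15) {
  if (any(ke <= 0) || any(kint <= 0))
    stop("both rates must be positive")
  P <- ke / kint
  dg <- -.constants$Rgas * temperature * log(P)
  list(P = P, Pprime = kint / ke, dg = dg, convention = "ke_over_kint")
}

#' Stability difference between variants from protection factors
#'
#' \deqn{\Delta\Delta G = -RT \ln(P_{variant}/P_{reference})}
#' with both protection factors in the \code{ke/kint} convention. Under
#' this convention a destabilized variant (faster exchange, larger P)
#' gives a negative ddG. The result equals
#' \code{dg_variant - dg_reference} exactly.
#'
#' @param pVariant,pReference protection factors (ke/kint convention).
#' @param temperature K.
#' @param convention character tags carried on the inputs; both must be
#'   \code{"ke_over_kint"}.
#' @return ddG in kJ/mol.
#' @export
ddgBetweenVariants <- function(pVariant, pReference, temperature = 298.15,
                               convention = c("ke_over_kint",
                                              "ke_over_kint")) {
  if (length(unique(convention)) != 1L)
    stop("protection factors use different conventions; refusing to mix")
  if (any(pVariant <= 0) || any(pReference <= 0))
    stop("protection factors must be positive")
  -.constants$Rgas * temperature * log(pVariant / pReference)
}

#' Assemble the per-residue H/D exchange result table
#'
#' Drives the slow-timescale analysis end to end: rates from a merged (or
#' single-mode) fit table, intrinsic rates from the sequence, protection
#' factors and free energies, and lifetime classes. Residues that
#' exchanged before the first time point are assigned the fastest rate
#' measured in the dataset, as is conventional for censored amides.
#'
#' @param fitTable data.frame as returned in \code{normalizeFastSeries()$table}
#'   (columns residue_id, ke, ke_sd, lifetime, censored, lifetime_class).
#' @param sequence one-letter sequence of the construct (1-based residue
#'   ids index into it).
#' @param pH glass-electrode pH reading.
#' @param temperature K.
#' @return data.frame with columns residue_id, ke, ke_sd, lifetime, kint,
#'   protection (ke/kint), dg (kJ/mol), lifetime_class.
#' @export
hdxResultTable <- function(fitTable, sequence, pH = 7.4,
                           temperature = 298.15) {
  tab <- fitTable
  fastest <- suppressWarnings(max(tab$ke[!tab$censored], na.rm = TRUE))
  if (!is.finite(fastest))
    stop("no quantified residue from which to assign the fastest rate")
  cen <- which(tab$censored)
  tab$ke[cen] <- fastest
  tab$lifetime[cen] <- 1 / fastest
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$residue_id[i]
    kint <- tryCatch(intrinsicRate(sequence, id, pH, temperature),
                     error = function(e) NA_real_)
    if (is.finite(kint) && tab$ke[i] > 0) {
      pe <- protectionAndEnergy(tab$ke[i], kint, temperature)
      data.frame(residue_id = id, ke = tab$ke[i], ke_sd = tab$ke_sd[i],
                 lifetime = tab$lifetime[i], kint = kint,
                 protection = pe$P, dg = pe$dg,
                 lifetime_class = tab$lifetime_class[i],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(residue_id = id, ke = tab$ke[i], ke_sd = tab$ke_sd[i],
                 lifetime = tab$lifetime[i], kint = kint,
                 protection = NA_real_, dg = NA_real_,
                 lifetime_class = tab$lifetime_class[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
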