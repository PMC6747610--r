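setMethod("show", "IntensitySeries", function(object) {
  cat("IntensitySeries: residue", object@residueId, "|",
      length(object@delays), "delays spanning",
      signif(min(object@delays), 3), "-", signif(max(object@delays), 3),
      "s | noise sd", signif(object@noiseSD, 3), "\n")
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf("RateFit: rate = %.6g s^-1 (sd %.3g, %d replicas, %.0f%% CI)%s\n",
              object@rate, object@rateSD, object@nReplicas,
              100 * object@ciLevel,
              if (isTRUE(object@converged)) "" else " [NOT CONVERGED]"))
})

setMethod("show", "RelaxationDataset", function(object) {
  cat("RelaxationDataset:", nrow(object@rates), "residues at",
      object@field1H / 1e6, "MHz (1H)\n")
  cat(sprintf("  mean R1 = %.3g, R2 = %.3g s^-1, HetNOE = %.3g\n",
              mean(object@rates$r1, na.rm = TRUE),
              mean(object@rates$r2, na.rm = TRUE),
              mean(object@rates$noe, na.rm = TRUE)))
})

setMethod("show", "DispersionProfile", function(object) {
  cat("DispersionProfile: residue", object@residueId, "|",
      length(object@nuCpmg), "nu_CPMG points in [",
      min(object@nuCpmg), ",", max(object@nuCpmg), "] Hz at",
      object@field1H / 1e6, "MHz\n")
})

setMethod("show", "TwoSiteParams", function(object) {
  cat(sprintf(
    "TwoSiteParams: kex = %.4g s^-1, pB = %.3g, |dw| = %.3g ppm, R2_0 = %.4g s^-1\n",
    object@kex, object@pb, object@dw[1], object@r20[1]))
})

setMethod("show", "HdxSeries", function(object) {
  cat("HdxSeries: residue", object@residueId, "| mode", object@mode, "|",
      length(object@times), "points,",
      signif(object@times[1], 3), "-", signif(max(object@times), 3), "s\n")
})

setMethod("show", "DlsMeasurement", function(object) {
  cat("DlsMeasurement:", length(object@lagTimes), "lags,",
      "theta =", object@angle, "deg, lambda =", object@wavelength * 1e9,
      "nm, T =", object@temperature, "K\n")
})

setMethod("show", "VectorTrajectory", function(object) {
  cat("VectorTrajectory: residue", object@residueId, "|",
      nrow(object@frames), "frames, dt =", object@dt, "s, window =",
      object@window, "s\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", object@nResidues, "residues, tm =",
      object@tm * 1e9, "ns, mean S2 =", object@s2Mean,
      "| kex =", object@exchange@kex, "s^-1, pB =", object@exchange@pb,
      "| seed =", object@seed, "\n")
})
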