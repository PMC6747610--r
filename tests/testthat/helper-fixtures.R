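# shared fixtures: small deterministic series and profiles built in code

r1DelaysFx <- c(100, 900, 300, 2000, 500, 1500, 700, 1300, 200) / 1000
r2DelaysFx <- c(10, 250, 30, 210, 50, 150, 70, 130, 90) / 1000

noiselessSeries <- function(rate, delays = r1DelaysFx, amp = 1,
                            id = 1L, noiseSD = 1e-9) {
  IntensitySeries(id, delays, amp * exp(-rate * delays), noiseSD)
}

cleanProfile <- function(kex, pb, dw, r20, field1H = 700e6,
                         tRelax = 0.030, id = 1L) {
  nu <- ProtDynamics:::.nuGrid(tRelax)
  r2 <- carverRichardsR2eff(TwoSiteParams(kex, pb, dw, r20), nu,
                            field1H, tRelax)
  DispersionProfile(id, nu, r2, field1H = field1H, tRelax = tRelax,
                    minSD = 0.05)
}

# independent brute-force evaluation of the dipolar+CSA rate equations,
# written from the closed forms with its own constants handling
bruteForceRates <- function(s2, tm, field1H = 700e6, rNH = 1.02,
                            csaPpm = -172, rex = 0) {
  gH <- 2.6752218744e8; gN <- -2.7126180e7
  hbar <- 1.054571817e-34; mu0 <- 4 * pi * 1e-7
  r <- rNH * 1e-10
  d <- (mu0 / (4 * pi)) * abs(gH * gN) * hbar / r^3
  wH <- 2 * pi * field1H
  wN <- 2 * pi * field1H * abs(gN / gH)
  cc <- wN * csaPpm * 1e-6 / sqrt(3)
  J <- function(w) 0.4 * s2 * tm / (1 + (w * tm)^2)
  r1 <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) +
    cc^2 * J(wN)
  r2 <- (d^2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                       6 * J(wH + wN)) +
    (cc^2 / 6) * (4 * J(0) + 3 * J(wN)) + rex
  noe <- 1 + (d^2 / 4) * (gH / gN) * (6 * J(wH + wN) - J(wH - wN)) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

# rotation matrix about an arbitrary axis (Rodrigues)
rotMat <- function(ax, ang) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

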