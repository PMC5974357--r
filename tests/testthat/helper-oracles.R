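# Independent oracles used across test files.

# Closed-form solution of the LINEARIZED unorganized model (S << K_M for
# both species), derived independently of the finite-volume solver:
#   D lap(S1) = k1 S1            k1 = V1/K1
#   D lap(S2) = k2 S2 - k1 S1    k2 = V2/K2
# Regular solutions are A f(phi, r) with f = sinh(phi r)/r; the particular
# part of S2 rides on the S1 mode.  Robin membrane conditions close A, B.
linearized_unorganized_oracle <- function(spec) {
  stopifnot(spec$strategy == "none")
  Rb <- spec$geometry$R_b
  D <- spec$transport$D
  vol <- (4 / 3) * pi * Rb^3
  V1 <- spec$enzyme1$k_cat * spec$enzyme1$copies / (6.02214e23 * vol) * 1e9
  V2 <- spec$enzyme2$k_cat * spec$enzyme2$copies / (6.02214e23 * vol) * 1e9
  k1 <- V1 / spec$enzyme1$K_M
  k2 <- V2 / spec$enzyme2$K_M
  stopifnot(abs(k1 - k2) > 1e-12 * max(k1, k2))
  phi1 <- sqrt(k1 / D)
  phi2 <- sqrt(k2 / D)
  f <- function(phi, r) ifelse(r == 0, phi, sinh(phi * r) / r)
  fp <- function(phi, r) (phi * cosh(phi * r) * r - sinh(phi * r)) / r^2

  km1 <- spec$transport$k_m_S1
  km2 <- spec$transport$k_m_S2
  A <- km1 * spec$conditions$S1_out /
    (D * fp(phi1, Rb) + km1 * f(phi1, Rb))
  c1 <- k1 * A / (k2 - k1)
  B <- -(c1 * (D * fp(phi1, Rb) + km2 * f(phi1, Rb)) -
           km2 * spec$conditions$S2_out) /
    (D * fp(phi2, Rb) + km2 * f(phi2, Rb))

  S1 <- function(r) A * f(phi1, r)
  S2 <- function(r) B * f(phi2, r) + c1 * f(phi1, r)
  # product formation = integral of k2 S2 over the cell (numerical
  # quadrature of the closed form), in umol/cell/s
  integrand <- function(r) k2 * S2(r) * 4 * pi * r^2
  flux <- stats::integrate(integrand, 0, Rb, rel.tol = 1e-10)$value * 1e-3
  list(S1 = S1, S2 = S2, flux = flux)
}

# spec with kinetics in the linear regime for the oracle above
linear_regime_spec <- function() {
  sp <- preset("pdu", strategy = "none")
  sp$conditions$S1_out <- 1        # << K1 = 500 uM; S2 stays << K2
  sp
}

expect_rel_equal <- function(actual, expected, tol, info = NULL) {
  rel <- abs(actual - expected) /
    max(abs(expected), .Machine$double.xmin)
  expect_lt(rel, tol, label = paste0("relative error ", format(rel),
                                     if (!is.null(info)) paste0(" (", info, ")")))
}
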