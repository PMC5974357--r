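## Closed-form-plus-root-finding solver for the organized strategies.
##
## In the cytosol shell R_c <= r <= R_b there is no reaction, so each species
## obeys Laplace's equation and its radial profile is S(r) = a + b/r.  The
## total diffusive flow through any sphere in the shell is then constant
## (-4*pi*D*b), and the two Robin conditions (membrane at R_b, compartment
## boundary at R_c) combine with the shell into three resistances in series.
## For each species the flow between the medium and the well-mixed
## compartment is therefore
##
##   J = G * (S_out - S_compartment),
##   1/G = 1/(4 pi R_b^2 k_m) + (1/R_c - 1/R_b)/(4 pi D) + 1/(4 pi R_c^2 k_c)
##
## in uM cm^3 / s.  Steady state closes the system: substrate inflow equals
## compartment consumption V_c * R1(S1_c), and intermediate outflow equals
## net production V_c * (R1 - R2(S2_c)).  With irreversible kinetics R1
## depends only on S1_c, so the system is triangular and each balance is a
## strictly monotone scalar equation solved by bracketed root finding
## (Brent).  The reversible rate law couples the two balances; a nested
## bracketed root find (outer in S2_c, inner in S1_c) handles that case.

#' Shell conductance between medium and compartment for one species
#'
#' Series resistances: cell membrane, cytosol shell diffusion, compartment
#' boundary, and the intra-compartment spreading resistance 1/(20 pi D R_c)
#' of a uniformly reacting sphere (the parabolic-profile correction relating
#' the volume-mean concentration to the inner-surface value).  The last term
#' is negligible when the boundary permeability is limiting (organelles) but
#' keeps the solution accurate in the free-diffusion scaffold limit.
#' @noRd
shell_conductance <- function(geom, D, k_m, k_c) {
  r_mem <- 1 / (4 * pi * geom$R_b^2 * k_m)
  r_shell <- (1 / geom$R_c - 1 / geom$R_b) / (4 * pi * D)
  r_comp <- 1 / (4 * pi * geom$R_c^2 * k_c)
  r_internal <- 1 / (20 * pi * D * geom$R_c)
  1 / (r_mem + r_shell + r_comp + r_internal)
}

#' Bracketed root of a decreasing function on [lower, inf)
#'
#' f must be continuous and eventually negative; returns `lower` when
#' f(lower) <= 0 (the physical clamp at the boundary of the bracket).
#' @noRd
solve_decreasing_root <- function(f, lower, upper0, tol) {
  f_lo <- f(lower)
  if (f_lo <= 0) return(list(root = lower, f_root = f_lo, iter = 0L))
  upper <- max(upper0, lower + 1)
  n_expand <- 0L
  while (f(upper) > 0) {
    upper <- upper * 4
    n_expand <- n_expand + 1L
    if (n_expand > 300L)
      stop("root bracket expansion failed; system appears unbounded")
  }
  res <- stats::uniroot(f, c(lower, upper), tol = tol * max(upper, 1),
                        maxiter = 1000L)
  list(root = res$root, f_root = res$f.root, iter = res$iter + n_expand)
}

#' Steady state of an organized (organelle or scaffold) system
#'
#' Solves the steady-state reaction-diffusion model under the well-mixed
#' compartment assumption: concentrations inside the organizing volume are
#' spatially constant, the cytosol shell carries pure diffusion (profiles
#' `a + b/r`), and Robin conditions link the shell to the medium (membrane
#' permeability k_m) and to the compartment (boundary permeability k_c).
#' The compartment concentrations are found by bracketed root finding on the
#' steady-state mass balances; see Details.
#'
#' @details
#' Substrate balance: shell inflow `G1 (S1_out - S1_c)` equals compartment
#' consumption `V_c R1(S1_c)`.  Intermediate balance: shell outflow
#' `G2 (S2_c - S2_out)` equals net production `V_c (R1 - R2(S2_c))`, with
#' `G` the series conductance of membrane, shell diffusion, and compartment
#' boundary.  Both balances are strictly monotone in their unknown, so the
#' bracketed solve converges for all physical parameters, independent of
#' initialization.
#'
#' @param spec A [system_spec()] with strategy `"organelle"` or
#'   `"scaffold"`.
#' @param tol Relative residual tolerance on the mass balances.
#' @param max_iter Maximum root-finder iterations per balance.
#' @return An object of class `steady_state_solution` with compartment
#'   concentrations (uM), cytosol profile coefficients, boundary values,
#'   `pathway_flux` and `intermediate_leakage` (umol/cell/s), and
#'   convergence diagnostics.
#' @examples
#' sol <- solve_organized(preset("pdu"))
#' sol$pathway_flux
#' @seealso [solve_organized_numeric()] for the full finite-volume solution
#'   of the same system, [solve_unorganized()] for free enzymes.
#' @export
solve_organized <- function(spec, tol = 1e-10, max_iter = 200) {
  validate_spec(spec)
  if (!spec$strategy %in% c("organelle", "scaffold"))
    stop_invalid("solve_organized requires strategy organelle or scaffold")
  geom <- spec$geometry
  tr <- spec$transport
  vm <- spec_vmax(spec)
  V_c <- vm$volume
  G1 <- shell_conductance(geom, tr$D, tr$k_m_S1, tr$k_c_S1)
  G2 <- shell_conductance(geom, tr$D, tr$k_m_S2, tr$k_c_S2)
  S1_out <- spec$conditions$S1_out
  S2_out <- spec$conditions$S2_out

  scale1 <- max(G1 * max(S1_out, 1), V_c * max(vm$V1, 1))
  scale2 <- max(G2 * max(S2_out, 1), V_c * max(vm$V1, vm$V2, 1))

  iters <- 0L
  if (spec$rate_law == "irreversible_mm") {
    f1 <- function(x) G1 * (S1_out - x) - V_c * rate1(spec, vm, x, 0)
    r1 <- solve_decreasing_root(f1, 0, S1_out, tol)
    S1_c <- r1$root
    consumption <- V_c * rate1(spec, vm, S1_c, 0)
    f2 <- function(y)
      consumption - V_c * rate2(spec, vm, y) - G2 * (y - S2_out)
    r2 <- solve_decreasing_root(f2, max(S2_out, 0),
                                max(S2_out, spec$enzyme2$K_M), tol)
    S2_c <- r2$root
    iters <- r1$iter + r2$iter
    resid <- max(abs(f1(S1_c)) / scale1, abs(f2(S2_c)) / scale2)
  } else {
    ## reversible interconversion couples the balances: nested root find
    inner_S1 <- function(y) {
      f1 <- function(x) G1 * (S1_out - x) - V_c * rate1(spec, vm, x, y)
      solve_decreasing_root(f1, 0, S1_out + spec$enzyme1$K_M, tol)$root
    }
    f2 <- function(y) {
      x <- inner_S1(y)
      V_c * (rate1(spec, vm, x, y) - rate2(spec, vm, y)) - G2 * (y - S2_out)
    }
    r2 <- solve_decreasing_root(f2, max(S2_out, 0),
                                max(S2_out, spec$enzyme2$K_M), tol)
    S2_c <- r2$root
    S1_c <- inner_S1(S2_c)
    consumption <- V_c * rate1(spec, vm, S1_c, S2_c)
    iters <- r2$iter
    resid <- abs(f2(S2_c)) / scale2
  }
  if (iters >= max_iter)
    warning("root finder used ", iters, " iterations (max_iter = ",
            max_iter, ")")

  ## reconstruct the cytosol a + b/r profiles from the converged flows
  J1 <- G1 * (S1_out - S1_c)          # inward flow of substrate
  J2 <- G2 * (S2_out - S2_c)          # inward flow of intermediate (<0 leak)
  prof <- function(J, S_out, k_m) {
    b <- -J / (4 * pi * tr$D)
    S_Rb <- S_out - J / (4 * pi * geom$R_b^2 * k_m)
    a <- S_Rb - b / geom$R_b
    c(a = a, b = b)
  }
  p1 <- prof(J1, S1_out, tr$k_m_S1)
  p2 <- prof(J2, S2_out, tr$k_m_S2)

  production <- V_c * rate2(spec, vm, S2_c)

  solution <- structure(list(
    strategy = spec$strategy,
    method = "analytic",
    converged = resid <= tol * 1e3,   # uniroot meets x-tol; residual scaled
    S1_compartment = S1_c,
    S2_compartment = S2_c,
    cytosol_profile_coefficients = list(S1 = p1, S2 = p2),
    S1_at_Rb = unname(p1["a"] + p1["b"] / geom$R_b),
    S2_at_Rb = unname(p2["a"] + p2["b"] / geom$R_b),
    S1_at_Rc = unname(p1["a"] + p1["b"] / geom$R_c),
    S2_at_Rc = unname(p2["a"] + p2["b"] / geom$R_c),
    pathway_flux = production * UMOL_PER_UM_CM3,
    substrate_uptake = consumption * UMOL_PER_UM_CM3,
    intermediate_leakage = -J2 * UMOL_PER_UM_CM3,
    residual_norm = resid,
    solver_iterations = iters,
    spec = spec
  ), class = "steady_state_solution")
  if (min(S1_c, S2_c, solution$S1_at_Rb, solution$S2_at_Rb) < -tol)
    stop("negative concentration at convergence; check parameters")
  solution
}

#' Evaluate a cytosol concentration profile
#'
#' For analytic solutions, evaluates the Laplace profile `a + b/r` of the
#' requested species at radius `r` (cm); for finite-volume solutions,
#' interpolates the stored cytosol-side radial profile.
#'
#' @param solution A `steady_state_solution`.
#' @param species `"S1"` or `"S2"`.
#' @param r Radius or radii in cm, within `[R_c, R_b]`.
#' @return Concentration(s) in uM.
#' @export
cytosol_concentration <- function(solution, species = c("S1", "S2"), r) {
  species <- match.arg(species)
  geom <- solution$spec$geometry
  if (any(r < geom$R_c * (1 - 1e-12)) || any(r > geom$R_b * (1 + 1e-12)))
    stop_invalid("r outside the cytosol shell [R_c, R_b]")
  co <- solution$cytosol_profile_coefficients
  if (!is.null(co)) {
    p <- co[[species]]
    return(unname(p["a"] + p["b"] / r))
  }
  prof <- solution$profile
  if (is.null(prof)) stop_invalid("solution carries no cytosol profile")
  cyto <- prof[prof$r_cm >= geom$R_c, ]
  col <- paste0(species, "_uM")
  ## cytosol side of a duplicated interface node is the later row
  cyto <- cyto[!duplicated(cyto$r_cm, fromLast = TRUE), ]
  stats::approx(cyto$r_cm, cyto[[col]], xout = r, rule = 2)$y
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat("<steady_state_solution> strategy:", x$strategy,
      " method:", x$method,
      " converged:", x$converged, "\n")
  if (!is.na(x$S1_compartment))
    cat(sprintf("  compartment: S1 = %.6g uM, S2 = %.6g uM\n",
                x$S1_compartment, x$S2_compartment))
  cat(sprintf("  at membrane: S1 = %.6g uM, S2 = %.6g uM\n",
              x$S1_at_Rb, x$S2_at_Rb))
  cat(sprintf("  pathway flux:         %.6g umol/cell/s\n", x$pathway_flux))
  cat(sprintf("  intermediate leakage: %.6g umol/cell/s\n",
              x$intermediate_leakage))
  cat(sprintf("  residual: %.2e after %d iterations\n",
              x$residual_norm, x$solver_iterations))
  invisible(x)
}
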