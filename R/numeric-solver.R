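## Conservative finite-volume boundary-value solver on a radial grid.
##
## Vertex-centred finite volumes: unknowns sit at nodes r_1 = 0 < ... <
## r_n = R_b; the control volume of node j spans the face midpoints
## [r_{j-1/2}, r_{j+1/2}] with the first face at 0 and the last at R_b.
## Diffusive face flow between neighbours is D * 4 pi r_face^2 * dS/dr; the
## membrane Robin condition enters as the outer-face flow
## 4 pi R_b^2 k_m (S_out - S_n), and (in the organized case) the compartment
## boundary as an interface flow 4 pi R_c^2 k_c (S_cyt - S_comp) between the
## duplicated nodes at R_c.  Because every internal flow appears with
## opposite signs in exactly two control volumes, summing the converged
## residuals telescopes: boundary flows balance volume-integrated reaction
## rates to solver tolerance, not merely to discretization error.
##
## The reaction terms are diagonal, so the Newton system is
## (A + diag(dR/dS * Vol)) delta = -F with A the constant transport
## operator; with irreversible kinetics S1 decouples from S2 and the two
## species are solved sequentially.

#' Radial grid for the finite-volume solver
#'
#' Node radii from 0 to R_b with a node placed exactly at R_c.  Spacing is
#' uniform within the compartment and within the cytosol shell; the number
#' of interior nodes is allocated proportionally to R_c/R_b (at least 10
#' inside).
#'
#' @param geometry A [geometry()].
#' @param n_points Total number of nodes, >= 50.
#' @return An object of class `radial_grid` with fields `radii` (cm),
#'   `n_points`, and `i_c` (index of the node at R_c).
#' @examples
#' g <- make_grid(geometry(R_b = 5e-5, R_c = 1e-5), 200)
#' g$radii[g$i_c]  # exactly 1e-5
#' @export
make_grid <- function(geometry, n_points = 400) {
  stopifnot(inherits(geometry, "geometry"))
  if (!is.numeric(n_points) || n_points < 50)
    stop_invalid("n_points must be >= 50")
  n_points <- as.integer(n_points)
  n_in <- max(10L, as.integer(round(n_points * geometry$R_c / geometry$R_b)))
  n_out <- n_points - n_in
  if (n_out < 10L) stop_invalid("n_points too small for this geometry")
  radii <- c(seq(0, geometry$R_c, length.out = n_in),
             seq(geometry$R_c, geometry$R_b, length.out = n_out + 1L)[-1L])
  structure(list(radii = radii, n_points = n_points, i_c = n_in),
            class = "radial_grid")
}

#' Transport operator, control volumes and boundary terms for one species
#'
#' Returns A (n x n flow matrix, uM cm^3/s per uM), the constant vector c0
#' from the external bath, the control volumes, and the indices of reaction
#' nodes.  `interface = TRUE` duplicates the node at R_c and couples the two
#' copies through the compartment-boundary permeability k_c.
#' @noRd
build_transport <- function(radii, i_c, D, k_m, S_out, k_c = NULL,
                            interface = FALSE) {
  if (interface) {
    r <- c(radii[seq_len(i_c)], radii[i_c:length(radii)])
    n <- length(r)
    i_in <- i_c          # inside copy of the interface node
    i_out <- i_c + 1L    # cytosol copy
    ## faces: midpoints, except the compartment boundary between the copies
    faces <- (r[-1] + r[-n]) / 2
    faces[i_in] <- r[i_in]  # face between the duplicated nodes sits at R_c
    react_nodes <- seq_len(i_in)
  } else {
    r <- radii
    n <- length(r)
    faces <- (r[-1] + r[-n]) / 2
    react_nodes <- seq_len(n)
    i_in <- i_out <- NA_integer_
  }
  face_area <- 4 * pi * faces^2
  h <- r[-1] - r[-n]
  g <- D * face_area / ifelse(h > 0, h, 1)    # diffusive face conductance
  if (interface) g[i_in] <- 4 * pi * r[i_in]^2 * k_c  # permeability barrier

  A <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) {
    A[j, j] <- A[j, j] - g[j];      A[j, j + 1L] <- A[j, j + 1L] + g[j]
    A[j + 1L, j + 1L] <- A[j + 1L, j + 1L] - g[j]
    A[j + 1L, j] <- A[j + 1L, j] + g[j]
  }
  ## membrane Robin flow at the outer face
  g_mem <- 4 * pi * r[n]^2 * k_m
  A[n, n] <- A[n, n] - g_mem

  bounds <- c(0, faces, r[n])
  vol <- (4 * pi / 3) * (bounds[-1]^3 - bounds[-length(bounds)]^3)
  list(A = A, g = g, S_out = S_out, src = numeric(n), vol = vol, r = r,
       react_nodes = react_nodes, i_in = i_in, i_out = i_out, g_mem = g_mem,
       ref = rep(S_out, n))
}

#' Damped Newton iteration for the finite-volume balance equations
#'
#' Residuals are assembled from face flows (each internal flow is computed
#' once and enters two control volumes with opposite signs), so at
#' convergence the boundary flows balance the volume-integrated reaction
#' rates to the residual floor rather than to discretization error.  The
#' Newton step is limited so no concentration drops by more than 90% per
#' iteration (positivity safeguard for saturated Michaelis-Menten terms)
#' and halved while the residual fails to decrease.
#' @noRd
newton_fv <- function(op, react, dreact, S0, tol, max_iter) {
  n <- length(S0)
  ## solve in deviations u = ref - S from a per-node reference (the bath
  ## value by default), so that face flows g * (u_j - u_{j+1}) retain full
  ## precision even when the concentration field is a large constant with
  ## tiny gradients; across a reference jump (a re-referenced compartment)
  ## the flow uses the concentrations directly, which differ by orders of
  ## magnitude there
  ref <- op$ref
  same_ref <- ref[-1] == ref[-n]
  if (ref[n] != op$S_out)
    stop("outermost reference must be the bath concentration")
  u <- ref - S0
  resid_fun <- function(u) {
    S <- ref - u
    w <- ifelse(same_ref,
                op$g * (u[-n] - u[-1]),       # inward flow across face j
                op$g * (S[-1] - S[-n]))
    w_mem <- op$g_mem * u[n]
    F <- c(w, w_mem) - c(0, w) + op$src
    F[op$react_nodes] <- F[op$react_nodes] +
      react(S[op$react_nodes]) * op$vol[op$react_nodes]
    list(F = F, S = S, scale = max(abs(w), abs(w_mem), abs(op$src),
                                   abs(F), .Machine$double.xmin))
  }
  rs <- resid_fun(u)
  S <- rs$S
  history <- numeric(0)
  stall <- 0L
  for (it in seq_len(max_iter)) {
    rn <- max(abs(rs$F)) / rs$scale
    history <- c(history, rn)
    if (rn <= tol || stall >= 6L) break
    J <- op$A
    dj <- numeric(n)
    dj[op$react_nodes] <- dreact(S[op$react_nodes]) * op$vol[op$react_nodes]
    diag(J) <- diag(J) + dj
    delta <- solve(J, -rs$F)                  # step in S; u steps by -delta
    ## positivity safeguard: cap the fractional decrease at 99% per step
    drop_frac <- max(-delta / pmax(S, .Machine$double.xmin * 1e10), 0)
    lambda <- min(1, 0.99 / max(drop_frac, 1e-30))
    best <- max(abs(rs$F))
    repeat {
      u_new <- pmin(u - lambda * delta, ref)   # keeps S >= 0
      rs_new <- resid_fun(u_new)
      if (max(abs(rs_new$F)) < best || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    ## near the residual floor progress stops; count consecutive slow steps
    stall <- if (max(abs(rs_new$F)) > 0.9 * best) stall + 1L else 0L
    u <- u_new
    rs <- rs_new
    S <- rs$S
  }
  rn <- max(abs(rs$F)) / rs$scale
  if (rn > 1e-6) {
    cond <- structure(
      class = c("orgflux_convergence_error", "error", "condition"),
      list(message = sprintf(
        "Newton iteration did not converge: residual %.3e after %d iterations",
        rn, length(history)), call = sys.call(-1), residual = rn,
        history = history))
    stop(cond)
  }
  list(S = S, residual = rn, iterations = length(history) - 1L,
       converged = TRUE, history = history)
}

#' Assemble a steady_state_solution from finite-volume fields
#' @noRd
fv_solution <- function(spec, op1, op2, S1, S2, vm, diag1, diag2,
                        organized) {
  n <- length(op1$r)
  geom <- spec$geometry
  influx1 <- op1$g_mem * (spec$conditions$S1_out - S1[n])
  leak2 <- op2$g_mem * (S2[n] - spec$conditions$S2_out)
  R1_int <- sum(rate1(spec, vm, S1[op1$react_nodes],
                      S2[op1$react_nodes]) * op1$vol[op1$react_nodes])
  R2_int <- sum(rate2(spec, vm, S2[op2$react_nodes]) *
                  op2$vol[op2$react_nodes])
  if (organized) {
    inside <- seq_len(op1$i_in)
    w <- op1$vol[inside]
    S1_c <- sum(S1[inside] * w) / sum(w)
    S2_c <- sum(S2[inside] * w) / sum(w)
    S1_Rc <- S1[op1$i_out]
    S2_Rc <- S2[op1$i_out]
  } else {
    inside <- which(op1$r <= geom$R_c)
    w <- op1$vol[inside]
    S1_c <- sum(S1[inside] * w) / sum(w)
    S2_c <- sum(S2[inside] * w) / sum(w)
    S1_Rc <- stats::approx(op1$r, S1, xout = geom$R_c)$y
    S2_Rc <- stats::approx(op1$r, S2, xout = geom$R_c)$y
  }
  structure(list(
    strategy = spec$strategy,
    method = "finite_volume",
    converged = TRUE,
    S1_compartment = S1_c,
    S2_compartment = S2_c,
    cytosol_profile_coefficients = NULL,
    S1_at_Rb = S1[n], S2_at_Rb = S2[n],
    S1_at_Rc = S1_Rc, S2_at_Rc = S2_Rc,
    pathway_flux = R2_int * UMOL_PER_UM_CM3,
    substrate_uptake = influx1 * UMOL_PER_UM_CM3,
    intermediate_leakage = leak2 * UMOL_PER_UM_CM3,
    residual_norm = max(diag1$residual, diag2$residual),
    solver_iterations = diag1$iterations + diag2$iterations,
    profile = data.frame(r_cm = op1$r, S1_uM = S1, S2_uM = S2),
    grid_warning = FALSE,
    spec = spec
  ), class = "steady_state_solution")
}

#' Steady state with enzymes free in the cytosol
#'
#' Finite-volume solution of the reaction-diffusion equations with both
#' enzymes distributed uniformly over the whole cell: `D lap(S1) = R1(S1)`
#' and `D lap(S2) = R2(S2) - R1(S1)` on `0 <= r <= R_b`, with the symmetry
#' condition at the origin and Robin membrane conditions at R_b.  V_max for
#' both enzymes is computed over the cell volume.
#'
#' @param spec A [system_spec()] with `strategy = "none"`.
#' @param grid A [make_grid()] grid; defaults to `n_points` nodes.
#' @param tol Relative residual tolerance for the Newton iteration.
#' @param max_iter Maximum Newton iterations per species.
#' @param n_points Grid size used when `grid` is NULL.
#' @param check_grid If TRUE, re-solve on a halved-spacing grid and flag the
#'   solution (`grid_warning`) if the pathway flux moves by more than 1%.
#' @return A `steady_state_solution` including the radial `profile`
#'   data frame (columns `r_cm`, `S1_uM`, `S2_uM`).
#' @export
solve_unorganized <- function(spec, grid = NULL, tol = 1e-10,
                              max_iter = 60, n_points = 400,
                              check_grid = FALSE) {
  validate_spec(spec)
  if (spec$strategy != "none")
    stop_invalid("solve_unorganized requires strategy = 'none'")
  if (spec$rate_law != "irreversible_mm")
    stop_invalid("the finite-volume solvers support irreversible kinetics")
  if (is.null(grid)) grid <- make_grid(spec$geometry, n_points)
  tr <- spec$transport
  vm <- spec_vmax(spec)
  cond <- spec$conditions

  op1 <- build_transport(grid$radii, grid$i_c, tr$D, tr$k_m_S1, cond$S1_out)
  op2 <- build_transport(grid$radii, grid$i_c, tr$D, tr$k_m_S2, cond$S2_out)

  d1 <- newton_fv(op1,
                  react = function(s) -michaelis_menten_rate(s, vm$V1, spec$enzyme1$K_M),
                  dreact = function(s) -mm_rate_deriv(s, vm$V1, spec$enzyme1$K_M),
                  S0 = rep(cond$S1_out, length(op1$r)),
                  tol = tol, max_iter = max_iter)
  S1 <- d1$S
  op2$src <- michaelis_menten_rate(S1, vm$V1, spec$enzyme1$K_M) * op2$vol
  d2 <- newton_fv(op2,
                  react = function(s) -michaelis_menten_rate(s, vm$V2, spec$enzyme2$K_M),
                  dreact = function(s) -mm_rate_deriv(s, vm$V2, spec$enzyme2$K_M),
                  S0 = rep(cond$S2_out, length(op2$r)),
                  tol = tol, max_iter = max_iter)
  sol <- fv_solution(spec, op1, op2, S1, d2$S, vm, d1, d2, organized = FALSE)
  if (check_grid) {
    fine <- solve_unorganized(spec, grid = make_grid(spec$geometry,
                                                     2L * grid$n_points),
                              tol = tol, max_iter = max_iter)
    rel <- abs(fine$pathway_flux - sol$pathway_flux) /
      max(abs(fine$pathway_flux), .Machine$double.xmin)
    sol$grid_warning <- rel > 0.01
    if (sol$grid_warning)
      warning(sprintf("grid too coarse: flux changes %.2f%% on refinement",
                      100 * rel))
  }
  sol
}

#' Full spatial steady state of an organized system
#'
#' Finite-volume solution of the organized (organelle or scaffold) model
#' without the well-mixed assumption: reactions are active only inside the
#' compartment (`r < R_c`), the compartment boundary enters as a
#' permeability jump (the concentration is discontinuous across R_c), and
#' the cytosol shell is reaction-free.  Serves as the full-resolution
#' validation oracle for [solve_organized()].
#'
#' @inheritParams solve_unorganized
#' @param spec A [system_spec()] with strategy `"organelle"` or
#'   `"scaffold"`.
#' @return A `steady_state_solution`; the `profile` data frame contains the
#'   node at R_c twice (compartment side first, cytosol side second).
#' @export
solve_organized_numeric <- function(spec, grid = NULL, tol = 1e-10,
                                    max_iter = 60, n_points = 400) {
  validate_spec(spec)
  if (!spec$strategy %in% c("organelle", "scaffold"))
    stop_invalid("solve_organized_numeric requires an organized strategy")
  if (spec$rate_law != "irreversible_mm")
    stop_invalid("the finite-volume solvers support irreversible kinetics")
  if (is.null(grid)) grid <- make_grid(spec$geometry, n_points)
  tr <- spec$transport
  vm <- spec_vmax(spec)
  cond <- spec$conditions

  op1 <- build_transport(grid$radii, grid$i_c, tr$D, tr$k_m_S1, cond$S1_out,
                         k_c = tr$k_c_S1, interface = TRUE)
  op2 <- build_transport(grid$radii, grid$i_c, tr$D, tr$k_m_S2, cond$S2_out,
                         k_c = tr$k_c_S2, interface = TRUE)

  ## a nearly sealed compartment decouples the interior from the bath; if
  ## the bath-referenced iteration hits its precision floor, re-reference
  ## the interior to zero and retry
  newton_retry <- function(op, ...) {
    tryCatch(newton_fv(op, ...), orgflux_convergence_error = function(e) {
      op$ref[seq_len(op$i_in)] <- 0
      newton_fv(op, ...)
    })
  }

  d1 <- newton_retry(op1,
                  react = function(s) -michaelis_menten_rate(s, vm$V1, spec$enzyme1$K_M),
                  dreact = function(s) -mm_rate_deriv(s, vm$V1, spec$enzyme1$K_M),
                  S0 = rep(cond$S1_out, length(op1$r)),
                  tol = tol, max_iter = max_iter)
  S1 <- d1$S
  op2$src[op2$react_nodes] <-
    michaelis_menten_rate(S1[op1$react_nodes], vm$V1, spec$enzyme1$K_M) *
    op2$vol[op2$react_nodes]
  d2 <- newton_retry(op2,
                  react = function(s) -michaelis_menten_rate(s, vm$V2, spec$enzyme2$K_M),
                  dreact = function(s) -mm_rate_deriv(s, vm$V2, spec$enzyme2$K_M),
                  S0 = rep(cond$S2_out, length(op2$r)),
                  tol = tol, max_iter = max_iter)
  fv_solution(spec, op1, op2, S1, d2$S, vm, d1, d2, organized = TRUE)
}

#' Solve a system spec with the appropriate solver
#'
#' Dispatches on the spec's strategy: organized strategies go to the
#' closed-form [solve_organized()] solver (or to
#' [solve_organized_numeric()] with `method = "numeric"`); the unorganized
#' strategy always uses the finite-volume [solve_unorganized()] solver.
#'
#' @param spec A [system_spec()].
#' @param method `"auto"` (analytic for organized strategies),
#'   `"analytic"`, or `"numeric"`.
#' @param ... Passed to the underlying solver.
#' @return A `steady_state_solution`.
#' @export
solve_steady_state <- function(spec, method = c("auto", "analytic",
                                                "numeric"), ...) {
  method <- match.arg(method)
  if (spec$strategy == "none") {
    if (method == "analytic")
      stop_invalid("no closed-form solution for the unorganized case")
    solve_unorganized(spec, ...)
  } else if (method == "numeric") {
    solve_organized_numeric(spec, ...)
  } else {
    solve_organized(spec, ...)
  }
}
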