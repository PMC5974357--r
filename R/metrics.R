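#' Per-cell pathway flux
#'
#' Total steady-state rate of the second reaction (product formation) for a
#' converged solution, in umol/cell/s: the compartment-volume rate
#' `V_c R2(S2_c)` for well-mixed solutions or the volume integral of R2 for
#' finite-volume solutions.
#'
#' @param solution A converged `steady_state_solution`.
#' @param spec The [system_spec()] that produced it (defaults to the spec
#'   stored on the solution).
#' @return Flux in umol/cell/s.
#' @export
pathway_flux <- function(solution, spec = solution$spec) {
  require_converged(solution)
  solution$pathway_flux
}

#' Per-cell intermediate leakage
#'
#' Steady-state efflux of the intermediate across the cell membrane,
#' `4 pi R_b^2 k_m_S2 (S2(R_b) - S2_out)`, in umol/cell/s.
#'
#' @inheritParams pathway_flux
#' @return Leakage in umol/cell/s (non-negative whenever `S2_out = 0`).
#' @export
intermediate_leakage <- function(solution, spec = solution$spec) {
  require_converged(solution)
  solution$intermediate_leakage
}

require_converged <- function(solution) {
  if (!inherits(solution, "steady_state_solution"))
    stop_invalid("expected a steady_state_solution")
  if (!isTRUE(solution$converged))
    stop("solution is not converged (residual ",
         format(solution$residual_norm), "); refusing to report metrics")
  invisible(solution)
}

#' Relative cytosol concentration gradient
#'
#' Diagnostic for the constant-far-field assumption: the relative drop of
#' each species across the cytosol shell,
#' `(S(R_b) - S(R_c)) / max(S(R_b), eps)`.
#'
#' @inheritParams pathway_flux
#' @param eps Guard for division by ~zero concentrations.
#' @return Named numeric vector with elements `S1` and `S2` (dimensionless).
#' @export
cytosol_gradient <- function(solution, eps = 1e-12) {
  require_converged(solution)
  c(S1 = (solution$S1_at_Rb - solution$S1_at_Rc) /
      max(solution$S1_at_Rb, eps),
    S2 = (solution$S2_at_Rb - solution$S2_at_Rc) /
      max(solution$S2_at_Rb, eps))
}

#' Steady-state mass-conservation residuals
#'
#' The three-way balances any converged solution must satisfy, reported as
#' relative mismatches:
#' \describe{
#'   \item{substrate}{membrane influx of S1 = compartment-boundary influx
#'     (organized, analytic only) = total consumption by reaction 1.}
#'   \item{intermediate}{total production by reaction 1 = total consumption
#'     by reaction 2 + membrane efflux of S2.}
#'   \item{overall}{substrate influx = pathway flux + intermediate
#'     leakage.}
#' }
#'
#' @inheritParams pathway_flux
#' @return Named numeric vector of relative residuals.
#' @export
conservation_residuals <- function(solution, spec = solution$spec) {
  require_converged(solution)
  geom <- spec$geometry
  tr <- spec$transport
  influx1 <- 4 * pi * geom$R_b^2 * tr$k_m_S1 *
    (spec$conditions$S1_out - solution$S1_at_Rb) * UMOL_PER_UM_CM3
  uptake <- solution$substrate_uptake
  leak <- solution$intermediate_leakage
  flux <- solution$pathway_flux
  scale <- max(abs(influx1), abs(uptake), abs(flux) + abs(leak),
               .Machine$double.xmin)
  out <- c(substrate = abs(influx1 - uptake) / scale,
           intermediate = abs(uptake - flux - leak) / scale,
           overall = abs(influx1 - flux - leak) / scale)
  if (!is.null(solution$cytosol_profile_coefficients)) {
    ## analytic route: also check the compartment-boundary flow, through the
    ## boundary permeability in series with the intra-compartment spreading
    ## resistance (the solver's interface law; see shell_conductance)
    g_c <- 1 / (1 / (4 * pi * geom$R_c^2 * tr$k_c_S1) +
                  1 / (20 * pi * tr$D * geom$R_c))
    comp_in <- g_c * (solution$S1_at_Rc - solution$S1_compartment) *
      UMOL_PER_UM_CM3
    out <- c(out, compartment = abs(comp_in - uptake) / scale)
  }
  out
}

#' Compare the three organization strategies on one objective
#'
#' Solves the system under each strategy (organelle and scaffold via
#' [solve_organized()], none via [solve_unorganized()]) with otherwise
#' shared parameters, evaluates the objective, and selects the best
#' strategy.  Ties within `tie_tol` relative are broken in favour of the
#' least engineering effort: none, then scaffold, then organelle.
#'
#' @param spec A [system_spec()]; its own strategy field is ignored.
#' @param objective `"max_flux"` or `"min_leakage"`.
#' @param tie_tol Relative tolerance under which objectives count as tied.
#' @param n_points Grid size for the unorganized finite-volume solve.
#' @param tol Solver tolerance.
#' @return An object of class `strategy_comparison`: per-strategy `flux` and
#'   `leakage` (umol/cell/s), `objective`, `best`, `tie`, and a `partial`
#'   flag when a strategy failed to converge (that strategy is excluded with
#'   a warning).
#' @examples
#' compare_strategies(preset("pdu"), "max_flux")$best  # "organelle"
#' @export
compare_strategies <- function(spec, objective = c("max_flux",
                                                   "min_leakage"),
                               tie_tol = 1e-3, n_points = 400,
                               tol = 1e-10) {
  objective <- match.arg(objective)
  flux <- leakage <- stats::setNames(rep(NA_real_, 3), STRATEGIES)
  ok <- stats::setNames(rep(FALSE, 3), STRATEGIES)
  for (s in STRATEGIES) {
    sp <- set_strategy(spec, s)
    sol <- tryCatch(
      if (s == "none") solve_unorganized(sp, tol = tol, n_points = n_points)
      else solve_organized(sp, tol = tol),
      error = function(e) e)
    if (inherits(sol, "error")) {
      warning("strategy '", s, "' failed to converge and is excluded: ",
              conditionMessage(sol))
      next
    }
    flux[s] <- pathway_flux(sol)
    leakage[s] <- intermediate_leakage(sol)
    ok[s] <- TRUE
  }
  vals <- if (objective == "max_flux") flux else leakage
  better <- if (objective == "max_flux") `>` else `<`
  ## tie-break preference: least engineering effort first
  pref <- c("none", "scaffold", "organelle")
  cand <- pref[ok[pref]]
  if (length(cand) == 0L) stop("no strategy converged")
  best <- cand[1]
  for (s in cand[-1]) {
    rel <- abs(vals[s] - vals[best]) /
      max(abs(vals[s]), abs(vals[best]), .Machine$double.xmin)
    if (rel > tie_tol && better(vals[s], vals[best])) best <- s
  }
  opt <- vals[best]
  tie <- any(vapply(setdiff(cand, best), function(s) {
    abs(vals[s] - opt) / max(abs(vals[s]), abs(opt),
                             .Machine$double.xmin) <= tie_tol
  }, logical(1)))
  structure(list(objective = objective, flux = flux, leakage = leakage,
                 values = vals, best = unname(best), tie = tie,
                 partial = !all(ok), converged = ok, tie_tol = tie_tol),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison> objective:", x$objective, "\n")
  for (s in STRATEGIES)
    cat(sprintf("  %-10s flux %.6g  leakage %.6g umol/cell/s%s\n", s,
                x$flux[s], x$leakage[s],
                if (!x$converged[s]) "  [not converged]" else ""))
  cat("  best:", x$best, if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' Serialize a strategy comparison
#'
#' @param x A `strategy_comparison`.
#' @param path Output file; format chosen by extension (.json or .csv).
#' @return `path`, invisibly.
#' @export
write_strategy_comparison <- function(x, path) {
  stopifnot(inherits(x, "strategy_comparison"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(objective = x$objective,
                              flux = as.list(x$flux),
                              leakage = as.list(x$leakage),
                              best = x$best, tie = x$tie),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(objective = x$objective, best = x$best, tie = x$tie,
                     t(stats::setNames(x$flux, paste0("flux_", names(x$flux)))),
                     t(stats::setNames(x$leakage,
                                       paste0("leak_", names(x$leakage)))))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
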