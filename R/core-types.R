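## Domain types: plain validated lists with S3 classes, base-R style.

stop_invalid <- function(...) {
  stop(structure(
    class = c("orgflux_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  as.numeric(x)
}

#' Enzyme kinetic parameters
#'
#' Turnover number, Michaelis constant and per-cell copy number for one
#' enzyme of the pathway.  Together with the volume over which the enzyme is
#' distributed these determine the maximum volumetric rate V_max (see
#' [vmax_from_copies()]).
#'
#' @param k_cat Turnover rate of one active site (1/s), >= 0.
#' @param K_M Michaelis constant (uM), > 0.
#' @param copies Enzyme molecules per cell, >= 0.
#' @return An object of class `enzyme_kinetics`.
#' @examples
#' enzyme_kinetics(k_cat = 300, K_M = 500, copies = 1500) # PduCDE
#' @export
enzyme_kinetics <- function(k_cat, K_M, copies) {
  k_cat <- check_scalar(k_cat, "k_cat")
  K_M <- check_scalar(K_M, "K_M")
  copies <- check_scalar(copies, "copies")
  if (k_cat < 0) stop_invalid("k_cat must be >= 0")
  if (K_M <= 0) stop_invalid("K_M must be > 0")
  if (copies < 0) stop_invalid("copies must be >= 0")
  structure(list(k_cat = k_cat, K_M = K_M, copies = copies),
            class = "enzyme_kinetics")
}

#' Metabolite transport parameters
#'
#' Cytosolic diffusivity plus mass-transfer coefficients at the cell membrane
#' (k_m) and at the compartment boundary (k_c), per species.  The scaffold
#' strategy is represented by k_c values large enough to approximate free
#' diffusion (see [preset()]).
#'
#' @param D Metabolite diffusivity in the cytosol (cm^2/s), > 0.
#' @param k_m_S1,k_m_S2 Cell-membrane permeability to substrate/intermediate
#'   (cm/s), > 0.
#' @param k_c_S1,k_c_S2 Compartment-boundary permeability to
#'   substrate/intermediate (cm/s), > 0.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D, k_m_S1, k_m_S2, k_c_S1, k_c_S2) {
  vals <- list(D = check_scalar(D, "D"),
               k_m_S1 = check_scalar(k_m_S1, "k_m_S1"),
               k_m_S2 = check_scalar(k_m_S2, "k_m_S2"),
               k_c_S1 = check_scalar(k_c_S1, "k_c_S1"),
               k_c_S2 = check_scalar(k_c_S2, "k_c_S2"))
  if (any(unlist(vals) <= 0))
    stop_invalid("all transport parameters must be > 0")
  structure(vals, class = "transport_params")
}

#' Cell and compartment geometry
#'
#' @param R_b Cell radius (cm), > 0.
#' @param R_c Radius of the organizing volume (organelle or scaffold
#'   region; cm), 0 < R_c < R_b.
#' @return An object of class `geometry`.
#' @export
geometry <- function(R_b, R_c) {
  R_b <- check_scalar(R_b, "R_b")
  R_c <- check_scalar(R_c, "R_c")
  if (!(R_c > 0 && R_c < R_b))
    stop_invalid("geometry requires 0 < R_c < R_b")
  structure(list(R_b = R_b, R_c = R_c), class = "geometry")
}

#' External (culture-medium) conditions
#'
#' Concentrations of substrate and intermediate in the medium, held constant
#' (the cell is assumed small relative to the culture volume).
#'
#' @param S1_out External substrate concentration (uM), >= 0.
#' @param S2_out External intermediate concentration (uM), >= 0.
#' @return An object of class `external_conditions`.
#' @export
external_conditions <- function(S1_out, S2_out = 0) {
  S1_out <- check_scalar(S1_out, "S1_out")
  S2_out <- check_scalar(S2_out, "S2_out")
  if (S1_out < 0 || S2_out < 0)
    stop_invalid("external concentrations must be >= 0")
  structure(list(S1_out = S1_out, S2_out = S2_out),
            class = "external_conditions")
}

#' @noRd
STRATEGIES <- c("organelle", "scaffold", "none")

check_strategy <- function(strategy) {
  match.arg(strategy, STRATEGIES)
}

#' Full model specification
#'
#' Bundles kinetics, transport, geometry, external conditions and an
#' organization strategy into one solvable model instance.
#'
#' Strategies: `"organelle"` places all enzyme copies in a well-mixed sphere
#' of radius R_c bounded by a permeability barrier k_c; `"scaffold"` is the
#' same geometry with the boundary permeability set to approximate free
#' diffusion; `"none"` distributes the enzymes uniformly over the whole cell.
#'
#' The default rate law is irreversible Michaelis-Menten for both steps.
#' With `rate_law = "reversible_mm"` the first step becomes a reversible
#' interconversion S1 <-> S2 whose net rate is the forward Michaelis-Menten
#' term on S1 minus a reverse term on S2 (`reverse1`); this caps the
#' intermediate concentration a compartment can accumulate.
#'
#' @param enzyme1,enzyme2 [enzyme_kinetics()] for the first and second step.
#' @param transport [transport_params()].
#' @param geometry [geometry()].
#' @param conditions [external_conditions()].
#' @param strategy One of `"organelle"`, `"scaffold"`, `"none"`.
#' @param rate_law `"irreversible_mm"` (default) or `"reversible_mm"`.
#' @param reverse1 [enzyme_kinetics()] of the reverse reaction of step 1;
#'   required when `rate_law = "reversible_mm"`.
#' @return An object of class `system_spec`.
#' @seealso [preset()] for ready-made parameterizations.
#' @export
system_spec <- function(enzyme1, enzyme2, transport, geometry, conditions,
                        strategy = "organelle",
                        rate_law = c("irreversible_mm", "reversible_mm"),
                        reverse1 = NULL) {
  stopifnot(inherits(enzyme1, "enzyme_kinetics"),
            inherits(enzyme2, "enzyme_kinetics"),
            inherits(transport, "transport_params"),
            inherits(geometry, "geometry"),
            inherits(conditions, "external_conditions"))
  rate_law <- match.arg(rate_law)
  strategy <- check_strategy(strategy)
  if (rate_law == "reversible_mm") {
    if (is.null(reverse1))
      stop_invalid("reversible_mm requires reverse1 kinetics")
    stopifnot(inherits(reverse1, "enzyme_kinetics"))
  }
  structure(list(enzyme1 = enzyme1, enzyme2 = enzyme2,
                 transport = transport, geometry = geometry,
                 conditions = conditions, strategy = strategy,
                 rate_law = rate_law, reverse1 = reverse1),
            class = "system_spec")
}

#' Volume of a sphere (cm^3)
#' @noRd
sphere_volume <- function(r) (4 / 3) * pi * r^3

#' Volume over which the enzymes are distributed for a given strategy
#' @noRd
enzyme_volume <- function(spec) {
  if (spec$strategy == "none") sphere_volume(spec$geometry$R_b)
  else sphere_volume(spec$geometry$R_c)
}

#' Set the organization strategy of a spec
#'
#' Returns a copy of `spec` with the strategy replaced; all other parameters
#' (including compartment-boundary permeabilities) are unchanged, except that
#' `"scaffold"` sets k_c for both species to the free-diffusion surrogate
#' value 1e3 cm/s.
#'
#' @param spec A [system_spec()].
#' @param strategy New strategy.
#' @param k_c_scaffold Boundary permeability used for scaffolds (cm/s).
#' @return A modified `system_spec`.
#' @export
set_strategy <- function(spec, strategy, k_c_scaffold = 1e3) {
  strategy <- check_strategy(strategy)
  spec$strategy <- strategy
  if (strategy == "scaffold") {
    spec$transport$k_c_S1 <- k_c_scaffold
    spec$transport$k_c_S2 <- k_c_scaffold
  }
  spec
}

#' @export
print.system_spec <- function(x, ...) {
  cat("<system_spec>  strategy:", x$strategy, " rate law:", x$rate_law, "\n")
  cat(sprintf("  enzyme1: k_cat=%.4g /s  K_M=%.4g uM  copies=%.4g\n",
              x$enzyme1$k_cat, x$enzyme1$K_M, x$enzyme1$copies))
  cat(sprintf("  enzyme2: k_cat=%.4g /s  K_M=%.4g uM  copies=%.4g\n",
              x$enzyme2$k_cat, x$enzyme2$K_M, x$enzyme2$copies))
  cat(sprintf("  transport: D=%.3g cm2/s  k_m=(%.3g, %.3g)  k_c=(%.3g, %.3g) cm/s\n",
              x$transport$D, x$transport$k_m_S1, x$transport$k_m_S2,
              x$transport$k_c_S1, x$transport$k_c_S2))
  cat(sprintf("  geometry: R_b=%.3g cm  R_c=%.3g cm\n",
              x$geometry$R_b, x$geometry$R_c))
  cat(sprintf("  medium: S1_out=%.4g uM  S2_out=%.4g uM\n",
              x$conditions$S1_out, x$conditions$S2_out))
  invisible(x)
}

#' Validate a system spec, returning it invisibly or erroring
#' @noRd
validate_spec <- function(spec) {
  if (!inherits(spec, "system_spec")) stop_invalid("not a system_spec")
  ## reconstruct components through their constructors to re-run invariants
  enzyme_kinetics(spec$enzyme1$k_cat, spec$enzyme1$K_M, spec$enzyme1$copies)
  enzyme_kinetics(spec$enzyme2$k_cat, spec$enzyme2$K_M, spec$enzyme2$copies)
  do.call(transport_params, unclass(spec$transport))
  geometry(spec$geometry$R_b, spec$geometry$R_c)
  external_conditions(spec$conditions$S1_out, spec$conditions$S2_out)
  check_strategy(spec$strategy)
  invisible(spec)
}
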