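## Parameter paths ----------------------------------------------------------

#' Read a scalar parameter from a spec by dotted path
#'
#' Paths mirror the spec structure, e.g. `"conditions.S1_out"`,
#' `"enzyme2.k_cat"`, `"transport.k_c_S1"`, `"geometry.R_b"`.  The composite
#' paths `"enzyme1.k_cat_E0"` / `"enzyme2.k_cat_E0"` address the activity
#' product k_cat*E0 (see [kcatE0_path()]).
#'
#' @param spec A [system_spec()].
#' @param path Dotted parameter path.
#' @return The scalar value.
#' @export
get_param <- function(spec, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[2] == "k_cat_E0")
    return(kcat_e0(spec, enzyme_index(parts[1])))
  x <- spec
  for (p in parts) {
    if (is.null(x[[p]])) stop_invalid("unresolvable parameter path: ", path)
    x <- x[[p]]
  }
  if (!is.numeric(x) || length(x) != 1L)
    stop_invalid("path does not resolve to a scalar: ", path)
  x
}

#' Set a scalar parameter on a spec by dotted path
#'
#' @inheritParams get_param
#' @param value New value.
#' @return A modified copy of `spec`.
#' @export
set_param <- function(spec, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[2] == "k_cat_E0")
    return(kcatE0_path(spec, enzyme_index(parts[1]), value))
  get_param(spec, path)  # validates the path
  expr <- paste0("spec", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- ", deparse(value))))
  validate_spec(spec)
  spec
}

enzyme_index <- function(name) {
  if (name == "enzyme1") 1L
  else if (name == "enzyme2") 2L
  else stop_invalid("invalid enzyme selector: ", name)
}

#' Enzyme activity k_cat*E0
#'
#' The activity product used as a design-space axis: turnover number times
#' enzyme concentration, with E0 referred to the organizing volume
#' (4/3 pi R_c^3), in uM/s.
#'
#' @param spec A [system_spec()].
#' @param enzyme 1 or 2.
#' @return Activity in uM/s.
#' @export
kcat_e0 <- function(spec, enzyme) {
  enz <- if (enzyme == 1L) spec$enzyme1 else if (enzyme == 2L) spec$enzyme2
  else stop_invalid("enzyme must be 1 or 2")
  vmax_from_copies(enz$k_cat, enz$copies, sphere_volume(spec$geometry$R_c))
}

#' Set the activity product k_cat*E0 of one enzyme
#'
#' Scales k_cat at fixed copy number so that [kcat_e0()] equals `value`
#' (uM/s over the organizing volume).  The scaling is exactly proportional:
#' doubling `value` doubles the enzyme's V_max under every strategy.
#'
#' @param spec A [system_spec()].
#' @param enzyme 1 or 2.
#' @param value Target activity (uM/s), > 0.
#' @return A modified copy of `spec`.
#' @export
kcatE0_path <- function(spec, enzyme, value) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop_invalid("value must be a positive scalar")
  current <- kcat_e0(spec, enzyme)
  field <- if (enzyme == 1L) "enzyme1" else "enzyme2"
  spec[[field]]$k_cat <- spec[[field]]$k_cat * (value / current)
  spec
}

## Sweeps and maps ----------------------------------------------------------

#' 1D parameter sweep over all three strategies
#'
#' Evaluates flux and leakage under each organization strategy at every
#' value of one parameter, holding everything else fixed.
#'
#' @param spec Baseline [system_spec()].
#' @param parameter Dotted parameter path (see [get_param()]).
#' @param values Ordered positive parameter values.
#' @param n_points Grid size for unorganized solves.
#' @param tol Solver tolerance.
#' @return An object of class `sweep_result`: a data frame with columns
#'   `value`, `flux_<strategy>`, `leak_<strategy>`,
#'   `converged_<strategy>`, plus attributes `parameter` and `spec`.
#' @examples
#' \donttest{
#' sw <- sweep_1d(preset("pdu"), "conditions.S1_out",
#'                10^seq(2, 5, length.out = 4))
#' }
#' @export
sweep_1d <- function(spec, parameter, values, n_points = 400, tol = 1e-10) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop_invalid("sweep values must be positive")
  get_param(spec, parameter)  # validate path up front
  rows <- lapply(values, function(v) {
    cmp <- compare_strategies(set_param(spec, parameter, v),
                              objective = "max_flux",
                              n_points = n_points, tol = tol)
    data.frame(value = v,
               flux_organelle = cmp$flux["organelle"],
               flux_scaffold = cmp$flux["scaffold"],
               flux_none = cmp$flux["none"],
               leak_organelle = cmp$leakage["organelle"],
               leak_scaffold = cmp$leakage["scaffold"],
               leak_none = cmp$leakage["none"],
               converged_organelle = cmp$converged["organelle"],
               converged_scaffold = cmp$converged["scaffold"],
               converged_none = cmp$converged["none"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' 2D optimal-strategy map
#'
#' Evaluates [compare_strategies()] on every cell of a 2D parameter grid
#' and records which strategy optimizes the objective there.  This is the
#' design-space analysis: regions of parameter space are labelled by the
#' flux-maximizing (or leakage-minimizing) organization strategy.
#'
#' @param spec Baseline [system_spec()].
#' @param x,y Lists `list(path = <dotted path>, values = <numeric grid>)`;
#'   grids are typically log-spaced.
#' @param objective `"max_flux"` or `"min_leakage"`.
#' @param n_points Grid size for unorganized solves.
#' @param tol Solver tolerance.
#' @return An object of class `strategy_map`: a long-format data frame with
#'   columns `x_value`, `y_value`, `best_strategy` (`"unconverged"` for
#'   cells where no strategy converged), per-strategy `flux_*` and `leak_*`,
#'   plus attributes `x_path`, `y_path`, `objective`.
#' @export
optimal_strategy_map <- function(spec, x, y,
                                 objective = c("max_flux", "min_leakage"),
                                 n_points = 400, tol = 1e-10) {
  objective <- match.arg(objective)
  stopifnot(is.list(x), is.list(y),
            all(c("path", "values") %in% names(x)),
            all(c("path", "values") %in% names(y)))
  if (any(x$values <= 0) || any(y$values <= 0))
    stop_invalid("map grids must be positive")
  cells <- expand.grid(x_value = x$values, y_value = y$values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- set_param(spec, x$path, cells$x_value[i])
    sp <- set_param(sp, y$path, cells$y_value[i])
    cmp <- tryCatch(
      suppressWarnings(compare_strategies(sp, objective,
                                          n_points = n_points, tol = tol)),
      error = function(e) NULL)
    if (is.null(cmp)) {
      return(data.frame(x_value = cells$x_value[i],
                        y_value = cells$y_value[i],
                        best_strategy = "unconverged",
                        flux_organelle = NA_real_, flux_scaffold = NA_real_,
                        flux_none = NA_real_, leak_organelle = NA_real_,
                        leak_scaffold = NA_real_, leak_none = NA_real_))
    }
    data.frame(x_value = cells$x_value[i], y_value = cells$y_value[i],
               best_strategy = cmp$best,
               flux_organelle = cmp$flux["organelle"],
               flux_scaffold = cmp$flux["scaffold"],
               flux_none = cmp$flux["none"],
               leak_organelle = cmp$leakage["organelle"],
               leak_scaffold = cmp$leakage["scaffold"],
               leak_none = cmp$leakage["none"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "x_path") <- x$path
  attr(out, "y_path") <- y$path
  attr(out, "objective") <- objective
  attr(out, "spec") <- spec
  class(out) <- c("strategy_map", "data.frame")
  out
}

#' Default log-spaced grid around a baseline value
#'
#' @param baseline Centre value.
#' @param decades Half-width of the grid in decades.
#' @param n Number of grid points.
#' @return Numeric vector of length `n`.
#' @export
log_grid <- function(baseline, decades = 3, n = 25) {
  10^seq(log10(baseline) - decades, log10(baseline) + decades,
         length.out = n)
}
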