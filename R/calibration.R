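## Calibration: converting literature-style culture observations into
## per-cell steady-state fluxes, for comparison with model predictions.

#' Growth observation
#'
#' Exponential-phase growth on the pathway substrate as the sole carbon
#' source, summarized by a doubling time.  The conversion assumes a fixed
#' cell dry mass and a fixed fraction of the pathway's mass flux routed to
#' growth.
#'
#' @param doubling_time Doubling time (s), > 0.
#' @param cell_mass Cell mass (g), > 0.  Default 0.3 pg.
#' @param flux_mass_fraction_to_growth Fraction of pathway mass flux usable
#'   for growth, in (0, 1].  Default 0.5.
#' @param substrate_molar_mass Substrate molar mass (g/mol), > 0.  Default
#'   76.09 (1,2-propanediol).
#' @return An object of class `growth_observation`.
#' @export
growth_observation <- function(doubling_time, cell_mass = 0.3e-12,
                               flux_mass_fraction_to_growth = 0.5,
                               substrate_molar_mass = 76.09) {
  vals <- list(doubling_time = check_scalar(doubling_time, "doubling_time"),
               cell_mass = check_scalar(cell_mass, "cell_mass"),
               flux_mass_fraction_to_growth =
                 check_scalar(flux_mass_fraction_to_growth,
                              "flux_mass_fraction_to_growth"),
               substrate_molar_mass =
                 check_scalar(substrate_molar_mass, "substrate_molar_mass"))
  if (any(unlist(vals) <= 0) || vals$flux_mass_fraction_to_growth > 1)
    stop_invalid("growth_observation fields must be positive (fraction <= 1)")
  structure(vals, class = "growth_observation")
}

#' Titer observation
#'
#' A product titer accumulated over a culture of known cell density,
#' assuming constant volumetric production over the duration.
#'
#' @param titer Final product concentration (uM), >= 0.
#' @param duration Culture duration (s), > 0.
#' @param cell_density Cells per cm^3 of culture, > 0.
#' @return An object of class `titer_observation`.
#' @export
titer_observation <- function(titer, duration, cell_density) {
  vals <- list(titer = check_scalar(titer, "titer"),
               duration = check_scalar(duration, "duration"),
               cell_density = check_scalar(cell_density, "cell_density"))
  if (vals$titer < 0 || vals$duration <= 0 || vals$cell_density <= 0)
    stop_invalid("titer_observation requires titer >= 0 and positive duration/density")
  structure(vals, class = "titer_observation")
}

#' Per-cell flux implied by a growth observation
#'
#' Converts a doubling time into a steady-state pathway flux: the cell
#' accumulates its own mass once per doubling time
#' (`mass rate = cell_mass / doubling_time`), of which
#' `flux_mass_fraction_to_growth` came through the pathway; dividing by the
#' substrate molar mass gives moles per cell per second.
#'
#' @param obs A [growth_observation()].
#' @return Flux in umol/cell/s; exactly proportional to
#'   `1/doubling_time`.
#' @examples
#' # 7.5 h doubling on 1,2-propanediol, 0.3 pg cells, half of flux to growth
#' flux_from_growth(growth_observation(doubling_time = 7.5 * 3600))
#' @export
flux_from_growth <- function(obs) {
  stopifnot(inherits(obs, "growth_observation"))
  mass_rate <- obs$cell_mass / obs$doubling_time            # g/cell/s
  mol_rate <- mass_rate / obs$flux_mass_fraction_to_growth /
    obs$substrate_molar_mass                                # mol/cell/s
  mol_rate * 1e6                                            # umol/cell/s
}

#' Per-cell flux implied by a titer observation
#'
#' `flux = titer / (duration * cell_density)`, unit-converted from
#' uM per cell-per-cm3 to umol/cell/s.
#'
#' @param obs A [titer_observation()].
#' @return Flux in umol/cell/s; exactly proportional to `titer`.
#' @examples
#' # 10 mM product after 2 days at 2e9 cells/mL
#' flux_from_titer(titer_observation(1e4, 2 * 86400, 2e9))
#' @export
flux_from_titer <- function(obs) {
  stopifnot(inherits(obs, "titer_observation"))
  ## titer uM = 1e-9 mol/cm^3 -> mol per cell: / density; per s: / duration
  mol_per_cell_s <- obs$titer * 1e-9 / (obs$duration * obs$cell_density)
  mol_per_cell_s * 1e6
}
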