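## Configuration files mirror system_spec field-for-field, with an optional
## `preset:` key plus override blocks.  YAML is the primary format; JSON is
## accepted.  All values are in the package unit system (cm, s, uM).

#' Convert a spec to a plain nested list (config form)
#'
#' @param spec A [system_spec()].
#' @return A nested list suitable for [write_config()].
#' @export
spec_to_config <- function(spec) {
  out <- list(
    strategy = spec$strategy,
    rate_law = spec$rate_law,
    enzyme1 = unclass(spec$enzyme1),
    enzyme2 = unclass(spec$enzyme2),
    transport = unclass(spec$transport),
    geometry = unclass(spec$geometry),
    conditions = unclass(spec$conditions)
  )
  if (!is.null(spec$reverse1)) out$reverse1 <- unclass(spec$reverse1)
  out
}

#' Build a spec from a config list
#'
#' The list may name a `preset` ("pdu" or "mevalonate") and override any
#' subset of fields, or define every block in full.
#'
#' @param config Nested list, as produced by [read_config()] or
#'   [spec_to_config()].
#' @return A validated [system_spec()].
#' @export
config_to_spec <- function(config) {
  base <- if (!is.null(config$preset)) spec_to_config(preset(config$preset))
  else NULL
  merged <- modify_nested(base, config[setdiff(names(config), "preset")])
  needed <- c("enzyme1", "enzyme2", "transport", "geometry", "conditions")
  missing <- setdiff(needed, names(merged))
  if (length(missing))
    stop_invalid("config is missing blocks: ", paste(missing, collapse = ", "))
  spec <- system_spec(
    enzyme1 = do.call(enzyme_kinetics, merged$enzyme1),
    enzyme2 = do.call(enzyme_kinetics, merged$enzyme2),
    transport = do.call(transport_params, merged$transport),
    geometry = do.call(geometry, merged$geometry),
    conditions = do.call(external_conditions, merged$conditions),
    strategy = if (is.null(merged$strategy)) "organelle" else merged$strategy,
    rate_law = if (is.null(merged$rate_law)) "irreversible_mm"
    else merged$rate_law,
    reverse1 = if (!is.null(merged$reverse1))
      do.call(enzyme_kinetics, merged$reverse1) else NULL
  )
  if (spec$strategy == "scaffold") spec <- set_strategy(spec, "scaffold")
  validate_spec(spec)
}

modify_nested <- function(base, overrides) {
  if (is.null(base)) return(overrides)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_nested(base[[nm]], overrides[[nm]])
    else base[[nm]] <- overrides[[nm]]
  }
  base
}

#' Write a spec (or config list) to YAML or JSON
#'
#' @param x A [system_spec()] or a config list.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  cfg <- if (inherits(x, "system_spec")) spec_to_config(x) else x
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15L)
  }
  invisible(path)
}

#' Read a YAML or JSON model configuration
#'
#' @param path Config file path.
#' @return The config list (not yet validated; pass to [config_to_spec()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

## ---- output writers ------------------------------------------------------

fmt_num <- function(x) formatC(x, format = "e", digits = 8)

provenance_header <- function(spec, extra = character()) {
  cfg <- spec_to_config(spec)
  flat <- unlist(cfg)
  c("# orgflux output",
    paste0("# ", names(flat), " = ", vapply(flat, function(v)
      if (is.numeric(v)) fmt_num(v) else as.character(v), character(1))),
    extra)
}

#' Write a solution's radial profile as CSV
#'
#' Columns `r_cm`, `S1_uM`, `S2_uM`; analytic solutions are evaluated on a
#' uniform 200-point cytosol grid.  A provenance header with the full
#' resolved parameter set is embedded as comment lines.
#'
#' @param solution A `steady_state_solution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(solution, path) {
  prof <- solution$profile
  if (is.null(prof)) {
    geom <- solution$spec$geometry
    r <- seq(geom$R_c, geom$R_b, length.out = 200)
    prof <- data.frame(r_cm = r,
                       S1_uM = cytosol_concentration(solution, "S1", r),
                       S2_uM = cytosol_concentration(solution, "S2", r))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(solution$spec), con)
  writeLines("r_cm,S1_uM,S2_uM", con)
  writeLines(paste(fmt_num(prof$r_cm), fmt_num(prof$S1_uM),
                   fmt_num(prof$S2_uM), sep = ","), con)
  invisible(path)
}

#' Serialize a solution to JSON
#'
#' @param solution A `steady_state_solution`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  out <- unclass(solution)
  out$spec <- spec_to_config(solution$spec)
  out$profile <- NULL
  out$cytosol_profile_coefficients <-
    lapply(out$cytosol_profile_coefficients, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a sweep result as CSV with provenance header
#'
#' @param sweep A `sweep_result` from [sweep_1d()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write_table_csv(sweep, path, attr(sweep, "spec"),
                  extra = paste0("# parameter = ", attr(sweep, "parameter")))
}

#' Write a strategy map as long-format CSV with provenance header
#'
#' @param map A `strategy_map` from [optimal_strategy_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  write_table_csv(map, path, attr(map, "spec"),
                  extra = c(paste0("# x = ", attr(map, "x_path")),
                            paste0("# y = ", attr(map, "y_path")),
                            paste0("# objective = ", attr(map, "objective"))))
}

write_table_csv <- function(df, path, spec, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(spec, extra), con)
  cols <- lapply(df, function(col)
    if (is.numeric(col)) fmt_num(col) else as.character(col))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}
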