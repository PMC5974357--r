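#' Built-in parameter presets
#'
#' Returns a complete [system_spec()] for one of the two reference systems:
#'
#' \describe{
#'   \item{`"pdu"`}{Native 1,2-propanediol utilization (Pdu) microcompartment
#'     metabolism of enteric bacteria.  Enzyme 1 is PduCDE (diol dehydratase,
#'     k_cat = 300/s, K_M = 500 uM, 1500 copies/cell); enzyme 2 is PduP/Q
#'     (aldehyde dehydrogenase, k_cat = 55/s, K_M = 1.5e4 uM, 2500
#'     copies/cell).  Shell permeability k_c = 1e-5 cm/s, membrane
#'     permeability k_m = 1e-2 cm/s, cell radius 5e-7 m, compartment radius
#'     1e-7 m, D = 1e-5 cm^2/s, external 1,2-PD 5.5e4 uM, external
#'     propionaldehyde 0.}
#'   \item{`"mevalonate"`}{Heterologous mevalonate biosynthesis: enzyme 1 is
#'     HMGS (k_cat = 1.83/s, K_M = 5 uM), enzyme 2 HMGR (k_cat = 0.023/s,
#'     K_M = 100 uM), 5e5 copies each; membrane permeability k_m = 1e-4 cm/s
#'     for the CoA-bound species.  Geometry, diffusivity, shell permeability
#'     and external concentrations inherit the `"pdu"` values.}
#' }
#'
#' @param name `"pdu"` or `"mevalonate"`.
#' @param strategy Organization strategy for the returned spec.
#' @return A [system_spec()].
#' @examples
#' preset("pdu")
#' preset("mevalonate", strategy = "scaffold")
#' @export
preset <- function(name = c("pdu", "mevalonate"),
                   strategy = c("organelle", "scaffold", "none")) {
  name <- match.arg(name)
  strategy <- match.arg(strategy)
  spec <- system_spec(
    enzyme1 = enzyme_kinetics(k_cat = 3e2, K_M = 5e2, copies = 1.5e3),
    enzyme2 = enzyme_kinetics(k_cat = 55, K_M = 1.5e4, copies = 2.5e3),
    transport = transport_params(D = 1e-5,
                                 k_m_S1 = 1e-2, k_m_S2 = 1e-2,
                                 k_c_S1 = 1e-5, k_c_S2 = 1e-5),
    geometry = geometry(R_b = 5e-5, R_c = 1e-5),
    conditions = external_conditions(S1_out = 5.5e4, S2_out = 0),
    strategy = "organelle"
  )
  if (name == "mevalonate") {
    spec$transport$k_m_S1 <- 1e-4
    spec$transport$k_m_S2 <- 1e-4
    spec$enzyme1 <- enzyme_kinetics(k_cat = 1.83, K_M = 5, copies = 5e5)
    spec$enzyme2 <- enzyme_kinetics(k_cat = 0.023, K_M = 1e2, copies = 5e5)
  }
  set_strategy(spec, strategy)
}

## targets understood by apply_fold_change
FOLD_TARGETS <- c("k_cat_both", "K_M_both",
                  "k_cat_enzyme1", "k_cat_enzyme2",
                  "K_M_enzyme1", "K_M_enzyme2",
                  "k_cat_E0_enzyme1", "k_cat_E0_enzyme2")

#' Apply a fold-change "improvement" to kinetic parameters
#'
#' Returns a new spec with the named kinetic parameter(s) improved by
#' `factor`: k_cat-type targets are multiplied (a faster enzyme), K_M-type
#' targets are divided (a lower Michaelis constant is the improvement).
#' `k_cat_E0_*` targets scale k_cat at fixed copy number, i.e. they scale
#' the activity product k_cat*E0.
#'
#' @param spec A [system_spec()].
#' @param target One of `"k_cat_both"`, `"K_M_both"`, `"k_cat_enzyme1"`,
#'   `"k_cat_enzyme2"`, `"K_M_enzyme1"`, `"K_M_enzyme2"`,
#'   `"k_cat_E0_enzyme1"`, `"k_cat_E0_enzyme2"`.
#' @param factor Positive improvement factor; 1 leaves the spec unchanged.
#' @return A modified copy of `spec` (the input is not altered).
#' @examples
#' sp <- preset("pdu")
#' apply_fold_change(sp, "K_M_both", 100)$enzyme1$K_M  # 5 uM
#' @export
apply_fold_change <- function(spec, target, factor) {
  validate_spec(spec)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop_invalid("factor must be a positive scalar")
  if (!target %in% FOLD_TARGETS)
    stop_invalid("unknown fold-change target: ", target)
  bump <- function(enz, field, up) {
    enz[[field]] <- if (up) enz[[field]] * factor else enz[[field]] / factor
    enz
  }
  if (target %in% c("k_cat_both", "k_cat_enzyme1", "k_cat_E0_enzyme1"))
    spec$enzyme1 <- bump(spec$enzyme1, "k_cat", TRUE)
  if (target %in% c("k_cat_both", "k_cat_enzyme2", "k_cat_E0_enzyme2"))
    spec$enzyme2 <- bump(spec$enzyme2, "k_cat", TRUE)
  if (target %in% c("K_M_both", "K_M_enzyme1"))
    spec$enzyme1 <- bump(spec$enzyme1, "K_M", FALSE)
  if (target %in% c("K_M_both", "K_M_enzyme2"))
    spec$enzyme2 <- bump(spec$enzyme2, "K_M", FALSE)
  spec
}
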