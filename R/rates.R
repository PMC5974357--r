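#' Michaelis-Menten rate
#'
#' Volumetric rate of an irreversible Michaelis-Menten reaction,
#' `V_max * S / (K_M + S)`.
#'
#' @param S Substrate concentration (uM), >= 0.  Vectorized.
#' @param V_max Maximum volumetric rate (uM/s), >= 0.
#' @param K_M Michaelis constant (uM), > 0.
#' @return Rate in uM/s, in `[0, V_max)` for finite `S`.
#' @examples
#' michaelis_menten_rate(S = 500, V_max = 100, K_M = 500)  # half saturation
#' @export
michaelis_menten_rate <- function(S, V_max, K_M) {
  if (any(!is.finite(S)) || any(S < 0)) stop_invalid("S must be finite and >= 0")
  if (!is.numeric(V_max) || any(V_max < 0)) stop_invalid("V_max must be >= 0")
  if (!is.numeric(K_M) || any(K_M <= 0)) stop_invalid("K_M must be > 0")
  V_max * S / (K_M + S)
}

#' Net rate of a reversible interconversion
#'
#' Net volumetric rate of a reversible enzymatic interconversion S1 <-> S2,
#' modeled as opposing Michaelis-Menten terms: the forward rate on S1 minus
#' the reverse rate on S2.  With a zero reverse V_max this reduces exactly to
#' [michaelis_menten_rate()].  The net rate vanishes where the two terms
#' balance, which bounds the product concentration an enzyme running against
#' its own back-reaction can sustain (the situation of the carboxysome's
#' CO2/HCO3- interconversion).
#'
#' @param S1,S2 Concentrations (uM), >= 0.  Vectorized.
#' @param forward,reverse Lists with elements `V_max` (uM/s) and `K_M` (uM).
#' @return Net rate in uM/s (negative when the back reaction dominates).
#' @export
reversible_interconversion_rate <- function(S1, S2, forward, reverse) {
  fwd <- michaelis_menten_rate(S1, forward$V_max, forward$K_M)
  if (reverse$V_max == 0) return(fwd)
  fwd - michaelis_menten_rate(S2, reverse$V_max, reverse$K_M)
}

#' Maximum volumetric rate from enzyme copy number
#'
#' Converts a turnover number and a per-cell copy number into the maximum
#' volumetric rate over the volume the enzymes occupy:
#' `V_max = k_cat * copies / (N_A * volume)`, in uM/s.
#'
#' @param k_cat Turnover rate (1/s).
#' @param copies Enzyme molecules in the volume.
#' @param volume Volume the enzymes are distributed over (cm^3), > 0.
#' @return V_max in uM/s.  Linear in `k_cat` and `copies`, inverse in
#'   `volume`.
#' @examples
#' # 1500 copies of a 300/s enzyme in a 100 nm-scale compartment
#' vmax_from_copies(300, 1500, (4 / 3) * pi * (1e-5)^3)
#' @export
vmax_from_copies <- function(k_cat, copies, volume) {
  if (!is.numeric(volume) || any(volume <= 0))
    stop_invalid("volume must be > 0")
  if (any(k_cat < 0) || any(copies < 0))
    stop_invalid("k_cat and copies must be >= 0")
  k_cat * copies / (N_AVOGADRO * volume) * UM_PER_MOL_CM3
}

#' Strategy-resolved V_max for both enzymes (uM/s over the enzyme volume)
#' @noRd
spec_vmax <- function(spec) {
  vol <- enzyme_volume(spec)
  list(V1 = vmax_from_copies(spec$enzyme1$k_cat, spec$enzyme1$copies, vol),
       V2 = vmax_from_copies(spec$enzyme2$k_cat, spec$enzyme2$copies, vol),
       V1_rev = if (!is.null(spec$reverse1))
         vmax_from_copies(spec$reverse1$k_cat, spec$reverse1$copies, vol)
       else 0,
       volume = vol)
}

#' Net rate of reaction 1 under the spec's rate law (uM/s)
#' @noRd
rate1 <- function(spec, vm, S1, S2) {
  r <- michaelis_menten_rate(S1, vm$V1, spec$enzyme1$K_M)
  if (spec$rate_law == "reversible_mm" && vm$V1_rev > 0)
    r <- r - michaelis_menten_rate(S2, vm$V1_rev, spec$reverse1$K_M)
  r
}

#' Rate of reaction 2 (uM/s)
#' @noRd
rate2 <- function(spec, vm, S2) {
  michaelis_menten_rate(S2, vm$V2, spec$enzyme2$K_M)
}

#' d/dS of the Michaelis-Menten rate
#' @noRd
mm_rate_deriv <- function(S, V_max, K_M) {
  V_max * K_M / (K_M + S)^2
}
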