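test_that("domain type constructors enforce their invariants", {
  expect_s3_class(enzyme_kinetics(300, 500, 1500), "enzyme_kinetics")
  expect_error(enzyme_kinetics(-1, 500, 10), "k_cat")
  expect_error(enzyme_kinetics(1, 0, 10), "K_M")
  expect_error(enzyme_kinetics(1, 500, -5), "copies")
  expect_error(transport_params(0, 1, 1, 1, 1), "> 0")
  expect_error(geometry(1e-5, 5e-5), "R_c < R_b")
  expect_error(external_conditions(-1), ">= 0")
  expect_error(preset("unknown_system"))
})

test_that("Michaelis-Menten rate matches its defining identities", {
  expect_identical(michaelis_menten_rate(0, 123, 45), 0)
  expect_equal(michaelis_menten_rate(500, 100, 500), 50)   # S = K_M
  # PduP/Q half-saturation at its own K_M of 1.5e4 uM
  expect_equal(michaelis_menten_rate(1.5e4, 100, 1.5e4), 50)
  expect_error(michaelis_menten_rate(-1, 1, 1), "S must")
  expect_error(michaelis_menten_rate(1, 1, 0), "K_M")
  # bounded by V_max and strictly increasing in S
  S <- 10^seq(-3, 8, length.out = 50)
  r <- michaelis_menten_rate(S, 7, 250)
  expect_true(all(r >= 0 & r < 7))
  expect_true(all(diff(r) > 0))
})

test_that("reversible interconversion reduces to the irreversible law and balances", {
  fwd <- list(V_max = 10, K_M = 100)
  rev <- list(V_max = 4, K_M = 50)
  # zero reverse V_max: exact reduction
  expect_identical(
    reversible_interconversion_rate(77, 31, fwd, list(V_max = 0, K_M = 50)),
    michaelis_menten_rate(77, 10, 100))
  # S2 = 0: identical to the forward rate
  expect_equal(reversible_interconversion_rate(77, 0, fwd, rev),
               michaelis_menten_rate(77, 10, 100))
  # pure back-reaction is negative
  expect_lt(reversible_interconversion_rate(0, 10, fwd, rev), 0)
  # detailed-balance point: opposing terms cancel
  # forward at S1: 10*50/150 = 10/3; choose S2 with 4*S2/(50+S2) = 10/3
  S2_eq <- 50 * (10 / 3) / (4 - 10 / 3)
  expect_equal(reversible_interconversion_rate(50, S2_eq, fwd, rev), 0,
               tolerance = 1e-12)
})

test_that("vmax_from_copies is the Avogadro unit bridge and exactly linear", {
  vol <- (4 / 3) * pi * (1e-5)^3
  # hand arithmetic: 300 * 1500 / (6.02214e23 * vol) mol/cm3/s -> uM/s
  expect_rel_equal(vmax_from_copies(300, 1500, vol),
                   300 * 1500 / (6.02214e23 * vol) * 1e9, 1e-12)
  expect_rel_equal(vmax_from_copies(300, 1500, vol), 1.78e5, 0.01)
  expect_identical(vmax_from_copies(300, 0, vol), 0)
  expect_equal(vmax_from_copies(300, 3000, vol),
               2 * vmax_from_copies(300, 1500, vol))
  expect_equal(vmax_from_copies(600, 1500, vol),
               2 * vmax_from_copies(300, 1500, vol))
  expect_equal(vmax_from_copies(300, 1500, 2 * vol),
               vmax_from_copies(300, 1500, vol) / 2)
  expect_error(vmax_from_copies(1, 1, 0), "volume")
})

test_that("presets reproduce the published parameter tables", {
  pdu <- preset("pdu")
  expect_equal(pdu$enzyme1$k_cat, 3e2)
  expect_equal(pdu$enzyme1$K_M, 5e2)
  expect_equal(pdu$enzyme1$copies, 1.5e3)
  expect_equal(pdu$enzyme2$k_cat, 55)
  expect_equal(pdu$enzyme2$K_M, 1.5e4)
  expect_equal(pdu$enzyme2$copies, 2.5e3)
  expect_equal(pdu$transport$D, 1e-5)
  expect_equal(pdu$transport$k_m_S1, 1e-2)
  expect_equal(pdu$transport$k_c_S1, 1e-5)
  expect_equal(pdu$geometry$R_b, 5e-5)
  expect_equal(pdu$geometry$R_c, 1e-5)
  expect_equal(pdu$conditions$S1_out, 5.5e4)
  expect_equal(pdu$conditions$S2_out, 0)
  mev <- preset("mevalonate")
  expect_equal(mev$enzyme1$k_cat, 1.83)
  expect_equal(mev$enzyme1$K_M, 5)
  expect_equal(mev$enzyme1$copies, 5e5)
  expect_equal(mev$enzyme2$k_cat, 0.023)
  expect_equal(mev$enzyme2$K_M, 1e2)
  expect_equal(mev$transport$k_m_S1, 1e-4)
  # geometry and shell permeability carry over from the Pdu system
  expect_equal(mev$geometry$R_c, 1e-5)
  expect_equal(mev$transport$k_c_S2, 1e-5)
})

test_that("scaffold strategy substitutes the free-diffusion boundary permeability", {
  sc <- preset("pdu", strategy = "scaffold")
  expect_equal(sc$transport$k_c_S1, 1e3)
  expect_equal(sc$transport$k_c_S2, 1e3)
  expect_equal(set_strategy(sc, "none")$strategy, "none")
})

test_that("apply_fold_change multiplies k_cat and divides K_M, leaving the input untouched", {
  sp <- preset("pdu")
  up <- apply_fold_change(sp, "K_M_both", 100)
  expect_equal(up$enzyme1$K_M, 5)
  expect_equal(up$enzyme2$K_M, 150)
  expect_equal(sp$enzyme1$K_M, 500)  # original unchanged
  fast <- apply_fold_change(sp, "k_cat_both", 100)
  expect_equal(fast$enzyme1$k_cat, 3e4)
  expect_equal(fast$enzyme2$k_cat, 5500)
  # identity and inverse
  expect_equal(apply_fold_change(sp, "k_cat_both", 1), sp)
  back <- apply_fold_change(apply_fold_change(sp, "k_cat_both", 7),
                            "k_cat_both", 1 / 7)
  expect_equal(back$enzyme1$k_cat, sp$enzyme1$k_cat)
  expect_error(apply_fold_change(sp, "nonsense", 2), "unknown")
  expect_error(apply_fold_change(sp, "k_cat_both", -1), "positive")
})

test_that("presets round-trip through YAML and JSON configs", {
  for (ext in c("yaml", "json")) {
    for (nm in c("pdu", "mevalonate")) {
      sp <- preset(nm)
      path <- file.path(tempdir(), paste0("cfg.", ext))
      write_config(sp, path)
      back <- config_to_spec(read_config(path))
      expect_equal(back, sp, tolerance = 1e-12,
                   info = paste(nm, ext))
    }
  }
})

test_that("config preset key with override blocks merges field-wise", {
  cfg <- list(preset = "pdu", strategy = "scaffold",
              conditions = list(S1_out = 500))
  sp <- config_to_spec(cfg)
  expect_equal(sp$conditions$S1_out, 500)
  expect_equal(sp$conditions$S2_out, 0)          # inherited
  expect_equal(sp$transport$k_c_S1, 1e3)         # scaffold substitution
  expect_equal(sp$enzyme1$k_cat, 300)            # inherited
  expect_error(config_to_spec(list(strategy = "none")), "missing blocks")
})
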