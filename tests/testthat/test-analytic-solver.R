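test_that("empty medium gives the zero fixed point", {
  sp <- preset("pdu")
  sp$conditions$S1_out <- 0
  sol <- solve_organized(sp)
  expect_equal(sol$S1_compartment, 0)
  expect_equal(sol$S2_compartment, 0)
  expect_equal(sol$pathway_flux, 0)
  expect_equal(sol$intermediate_leakage, 0)
})

test_that("organized steady states satisfy the three-way mass balances", {
  for (nm in c("pdu", "mevalonate")) {
    for (strat in c("organelle", "scaffold")) {
      sol <- solve_organized(preset(nm, strategy = strat))
      expect_true(sol$converged)
      res <- conservation_residuals(sol)
      expect_true(all(res < 1e-6), info = paste(nm, strat, "residuals",
                                                paste(format(res), collapse = " ")))
    }
  }
})

test_that("cytosol profile evaluation is consistent with stored boundary values", {
  sol <- solve_organized(preset("pdu"))
  geom <- sol$spec$geometry
  expect_equal(cytosol_concentration(sol, "S1", geom$R_b), sol$S1_at_Rb)
  expect_equal(cytosol_concentration(sol, "S1", geom$R_c), sol$S1_at_Rc)
  expect_equal(cytosol_concentration(sol, "S2", geom$R_b), sol$S2_at_Rb)
  expect_error(cytosol_concentration(sol, "S1", geom$R_b * 2), "shell")
  expect_error(cytosol_concentration(sol, "S1", geom$R_c / 2), "shell")
  # a no-flux species has a flat profile: with zero enzyme 1 activity the
  # substrate equilibrates with the bath everywhere
  sp0 <- preset("pdu")
  sp0$enzyme1$copies <- 0
  sp0$enzyme2$copies <- 0
  flat <- solve_organized(sp0)
  r <- seq(sp0$geometry$R_c, sp0$geometry$R_b, length.out = 7)
  expect_equal(cytosol_concentration(flat, "S1", r),
               rep(sp0$conditions$S1_out, 7), tolerance = 1e-9)
})

test_that("analytic cytosol profiles match the finite-volume profiles", {
  sp <- preset("pdu")
  a <- solve_organized(sp)
  n <- solve_organized_numeric(sp)
  r <- seq(sp$geometry$R_c, sp$geometry$R_b, length.out = 100)
  for (species in c("S1", "S2")) {
    pa <- cytosol_concentration(a, species, r)
    pn <- cytosol_concentration(n, species, r)
    expect_true(all(abs(pa - pn) <= 0.01 * pmax(abs(pn), 1e-9)),
                info = species)
  }
})

test_that("pathway flux rises monotonically with external substrate", {
  sp <- preset("pdu")
  ladder <- 10^seq(1, 5, length.out = 10)
  flux <- vapply(ladder, function(sx) {
    sp$conditions$S1_out <- sx
    solve_organized(sp)$pathway_flux
  }, numeric(1))
  expect_true(all(diff(flux) > 0))
})

test_that("fluxes never exceed enzyme capacity", {
  for (nm in c("pdu", "mevalonate")) {
    sp <- preset(nm)
    sp$conditions$S1_out <- 1e7   # push hard
    sol <- solve_organized(sp)
    cap2 <- sp$enzyme2$k_cat * sp$enzyme2$copies / 6.02214e23 * 1e6
    cap1 <- sp$enzyme1$k_cat * sp$enzyme1$copies / 6.02214e23 * 1e6
    expect_lte(sol$pathway_flux, cap2)
    expect_lte(sol$substrate_uptake, cap1)
  }
  # the Pdu organelle capacity in absolute terms
  sol <- solve_organized(preset("pdu"))
  expect_lte(sol$pathway_flux, 2.284e-13)
})

test_that("the scaffold limit agrees with the free-diffusion finite-volume solution", {
  for (nm in c("pdu", "mevalonate")) {
    sp <- preset(nm, strategy = "scaffold")   # k_c = 1e3 cm/s
    a <- solve_organized(sp)
    n <- solve_organized_numeric(sp)
    expect_rel_equal(a$pathway_flux, n$pathway_flux, 0.01, info = nm)
    expect_rel_equal(a$S1_compartment, n$S1_compartment, 0.01, info = nm)
    expect_rel_equal(a$S2_compartment, n$S2_compartment, 0.01, info = nm)
  }
})

test_that("organelle flux is insulated from cell-size changes", {
  sp <- preset("pdu")
  f0 <- solve_organized(sp)$pathway_flux
  for (fac in c(0.5, 1.5)) {
    sp2 <- sp
    sp2$geometry$R_b <- 5e-5 * fac
    f <- solve_organized(sp2)$pathway_flux
    expect_lt(abs(f - f0) / f0, 0.05)
  }
})

test_that("reversible kinetics reduce to irreversible at zero reverse rate", {
  sp <- preset("pdu")
  rev0 <- system_spec(sp$enzyme1, sp$enzyme2, sp$transport, sp$geometry,
                      sp$conditions, strategy = "organelle",
                      rate_law = "reversible_mm",
                      reverse1 = enzyme_kinetics(0, 500, 1500))
  a <- solve_organized(sp)
  b <- solve_organized(rev0)
  expect_equal(b$S1_compartment, a$S1_compartment, tolerance = 1e-8)
  expect_equal(b$pathway_flux, a$pathway_flux, tolerance = 1e-8)
})

test_that("a reversible first step caps the intermediate a sealed compartment can accumulate", {
  ## trapping the intermediate (tiny shell permeability to S2) drives its
  ## compartment concentration enormous under irreversible kinetics, but the
  ## back-reaction bounds it near the balance point of the two MM terms
  sp <- preset("pdu")
  sp$transport$k_c_S2 <- 1e-9
  irr <- solve_organized(sp)
  rev <- system_spec(sp$enzyme1, sp$enzyme2, sp$transport, sp$geometry,
                     sp$conditions, strategy = "organelle",
                     rate_law = "reversible_mm",
                     reverse1 = enzyme_kinetics(300, 500, 1500))
  rv <- solve_organized(rev)
  expect_lt(rv$S2_compartment, 0.01 * irr$S2_compartment)
  # bounded by the detailed-balance concentration of the opposing terms:
  # forward at S1_c vs reverse at S2 equal when the net rate is zero
  vm_fwd <- 300 * 1500
  vm_rev <- 300 * 1500
  frac <- rv$S1_compartment / (500 + rv$S1_compartment)
  S2_bal <- 500 * frac / (1 - frac) * (vm_fwd / vm_rev)
  expect_lt(rv$S2_compartment, S2_bal * 1.001)
})

test_that("solver errors on invalid strategies and reports iteration counts", {
  expect_error(solve_organized(preset("pdu", strategy = "none")),
               "organelle or scaffold")
  sol <- solve_organized(preset("pdu"))
  expect_gt(sol$solver_iterations, 0)
  expect_lt(sol$residual_norm, 1e-7)
})
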