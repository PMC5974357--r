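test_that("parameter paths resolve, set and validate", {
  sp <- preset("pdu")
  expect_equal(get_param(sp, "conditions.S1_out"), 5.5e4)
  expect_equal(get_param(sp, "enzyme2.k_cat"), 55)
  sp2 <- set_param(sp, "transport.k_m_S2", 1e-3)
  expect_equal(sp2$transport$k_m_S2, 1e-3)
  expect_equal(sp$transport$k_m_S2, 1e-2)  # copy semantics
  expect_error(get_param(sp, "enzyme3.k_cat"), "unresolvable")
  expect_error(set_param(sp, "geometry.R_c", 1), "R_c < R_b")
})

test_that("k_cat*E0 composite path scales activity exactly proportionally", {
  sp <- preset("pdu")
  a0 <- kcat_e0(sp, 2)
  expect_equal(kcatE0_path(sp, 2, a0), sp)          # identity
  doubled <- kcatE0_path(sp, 2, 2 * a0)
  expect_equal(doubled$enzyme2$k_cat, 110)          # copies fixed
  expect_equal(doubled$enzyme2$copies, 2500)
  expect_equal(kcat_e0(doubled, 2), 2 * a0)
  expect_equal(get_param(sp, "enzyme2.k_cat_E0"), a0)
  sp3 <- set_param(sp, "enzyme1.k_cat_E0", 3 * kcat_e0(sp, 1))
  expect_equal(sp3$enzyme1$k_cat, 900)
  expect_error(kcatE0_path(sp, 3, 1), "enzyme")
  # matches a plain k_cat sweep: scaling activity == scaling k_cat
  f1 <- solve_organized(kcatE0_path(sp, 2, 2 * a0))$pathway_flux
  f2 <- solve_organized(set_param(sp, "enzyme2.k_cat", 110))$pathway_flux
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("a degenerate one-point sweep equals a direct strategy comparison", {
  sp <- preset("pdu")
  sw <- sweep_1d(sp, "conditions.S1_out", 5.5e4, n_points = 200)
  cmp <- compare_strategies(sp, "max_flux", n_points = 200)
  expect_equal(nrow(sw), 1L)
  expect_rel_equal(sw$flux_organelle, cmp$flux[["organelle"]], 1e-12)
  expect_rel_equal(sw$flux_none, cmp$flux[["none"]], 1e-12)
  expect_rel_equal(sw$leak_scaffold, cmp$leakage[["scaffold"]], 1e-12)
})

test_that("Pdu organelle dominates scaffold across an external-substrate ladder", {
  ladder <- 10^seq(log10(5e2), log10(5.5e4), length.out = 6)
  sw <- sweep_1d(preset("pdu"), "conditions.S1_out", ladder, n_points = 200)
  expect_true(all(diff(sw$flux_organelle) > 0))            # monotone
  expect_true(all(sw$flux_organelle >= sw$flux_scaffold))
  expect_true(all(sw$flux_scaffold >= sw$flux_none))
})

test_that("organelle flux is buffered against cell-radius variation in a sweep", {
  sw <- sweep_1d(preset("pdu"), "geometry.R_b", c(2.5e-5, 5e-5, 1e-4),
                 n_points = 200)
  spread <- diff(range(sw$flux_organelle)) / max(sw$flux_organelle)
  expect_lt(spread, 0.05)
  # the unorganized and scaffold systems are NOT buffered
  spread_none <- diff(range(sw$flux_none)) / max(sw$flux_none)
  expect_gt(spread_none, 0.5)
})

test_that("a 1x1 strategy map reproduces compare_strategies", {
  sp <- preset("pdu")
  m <- optimal_strategy_map(sp, x = list(path = "conditions.S1_out",
                                         values = 5.5e4),
                            y = list(path = "enzyme2.k_cat", values = 55),
                            n_points = 200)
  cmp <- compare_strategies(sp, "max_flux", n_points = 200)
  expect_equal(nrow(m), 1L)
  expect_equal(m$best_strategy, cmp$best)
  expect_rel_equal(m$flux_organelle, cmp$flux[["organelle"]], 1e-12)
})

test_that("the mevalonate design space switches from scaffold to organelle with S_ext", {
  m <- optimal_strategy_map(
    preset("mevalonate"),
    x = list(path = "enzyme2.k_cat_E0",
             values = kcat_e0(preset("mevalonate"), 2)),
    y = list(path = "conditions.S1_out", values = c(5e2, 5e4)),
    objective = "max_flux", n_points = 200)
  expect_equal(m$best_strategy[m$y_value == 5e4], "organelle")
  ## at 0.5 mM the organelle loses its advantage: restricted substrate entry
  ## caps its flux below the scaffold's, and the scaffold is within the tie
  ## tolerance of no organization, so the least-effort rule reports none
  lo <- m[m$y_value == 5e2, ]
  expect_true(lo$best_strategy != "organelle")
  expect_gt(lo$flux_scaffold, lo$flux_organelle)
  expect_equal(nrow(m), 2L)
})

test_that("weak enzymes favor no organization for minimizing leakage", {
  sp <- apply_fold_change(apply_fold_change(preset("pdu"),
                                            "k_cat_E0_enzyme1", 1e-4),
                          "k_cat_E0_enzyme2", 1e-4)
  cmp <- compare_strategies(sp, "min_leakage", n_points = 200)
  expect_equal(cmp$best, "none")
})

test_that("organelle-over-scaffold flux advantage is an up-set along S_ext", {
  ## the region where the organelle beats the scaffold has a single lower
  ## boundary in S_ext for both pathways (one sign change at most, from
  ## scaffold-favored to organelle-favored)
  ladder <- 10^seq(2, 5, length.out = 7)
  for (nm in c("pdu", "mevalonate")) {
    sw <- sweep_1d(preset(nm), "conditions.S1_out", ladder, n_points = 200)
    wins <- sw$flux_organelle > sw$flux_scaffold
    expect_lte(sum(diff(wins) != 0), 1L)
    if (any(!wins)) expect_false(wins[1])  # losses only at the low end
  }
})

test_that("map cells are independent of evaluation order", {
  sp <- preset("pdu")
  xs <- c(5e3, 5.5e4)
  m1 <- optimal_strategy_map(sp, x = list(path = "conditions.S1_out",
                                          values = xs),
                             y = list(path = "enzyme2.k_cat", values = 55),
                             n_points = 200)
  m2 <- optimal_strategy_map(sp, x = list(path = "conditions.S1_out",
                                          values = rev(xs)),
                             y = list(path = "enzyme2.k_cat", values = 55),
                             n_points = 200)
  m2s <- m2[order(m2$x_value), ]
  rownames(m2s) <- NULL
  m1s <- m1[order(m1$x_value), ]
  rownames(m1s) <- NULL
  expect_equal(m1s$flux_organelle, m2s$flux_organelle)
  expect_equal(m1s$best_strategy, m2s$best_strategy)
})
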