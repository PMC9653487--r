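canonical <- msck_parameters()

test_that("the canonical parameter set reproduces the printed midpoint", {
  expect_equal(canonical$R_c, 54 / (2 * pi * 1.1), tolerance = 1e-12)
  expect_equal(round(midpoint_tension(canonical), 2), 0.16)
  expect_equal(midpoint_tension(canonical), 0.15869, tolerance = 1e-4)
  # an order of magnitude below the MscL literature midpoint
  expect_gt(2.5 / midpoint_tension(canonical), 10)
})

test_that("bending energy follows its closed form and limits", {
  expect_equal(bending_energy(canonical, 0), 0)
  expect_equal(bending_energy(canonical, 0.05), 4.810, tolerance = 1e-3)
  flat <- gating_parameters(theta_c = 0.4, theta_o = 0.4, R_c = 8, delta_R = 0,
                            delta_A = 1)
  expect_equal(bending_energy(flat, c(0, 0.1, 1)), rep(0, 3))
  expect_error(bending_energy(canonical, -0.1), class = "mechgate_domain_error")
})

test_that("gating energy balances at the midpoint and is asymptotically open", {
  expect_equal(gating_energy(canonical, 0, dG0 = 3), 3)
  expect_equal(gating_energy(canonical, 0.1587), 0, tolerance = 1e-2)
  expect_lt(gating_energy(canonical, 10), 0)
  # with dG0 = 0, dG > 0 below the midpoint and < 0 above, one sign change
  sh <- midpoint_tension_root(canonical)
  grid <- seq(1e-4, 5 * sh, length.out = 400)
  signs <- sign(gating_energy(canonical, grid))
  expect_equal(sum(diff(signs) != 0), 1)
  expect_true(all(signs[grid < sh * 0.999] > 0))
  expect_true(all(signs[grid > sh * 1.001] < 0))
})

test_that("closed-form and root-found midpoints agree over random valid sets", {
  withr::with_seed(123, {
    checked <- 0
    while (checked < 1000) {
      theta_c <- runif(1, 0.15, 0.9)
      theta_o <- theta_c * runif(1, 0, 0.9)
      R_c <- runif(1, 2, 15)
      delta_R <- runif(1, 0.1, 3)
      K_b <- runif(1, 5, 40)
      gp <- gating_parameters(theta_c, theta_o, R_c = R_c, delta_R = delta_R,
                              K_b = K_b)
      if (!gp$well_posed) next
      cf <- midpoint_tension(gp)
      rt <- midpoint_tension_root(gp)
      expect_lt(abs(cf - rt) / cf, 1e-8)
      checked <- checked + 1
    }
  })
})

test_that("midpoint tension scales linearly in Kb and as 1/s^2 in lengths", {
  expect_equal(midpoint_tension(msck_parameters(K_b = 40)),
               2 * midpoint_tension(msck_parameters(K_b = 20)),
               tolerance = 1e-12)
  gp <- gating_parameters(theta_c = 0.5, theta_o = 0.2, R_c = 6, delta_R = 1)
  for (s in c(0.5, 2, 3)) {
    scaled <- gating_parameters(theta_c = 0.5, theta_o = 0.2, R_c = 6 * s,
                                delta_R = 1 * s)
    expect_equal(midpoint_tension(scaled), midpoint_tension(gp) / s^2,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and ill-posed parameter sets are refused", {
  same <- gating_parameters(theta_c = 0.5, theta_o = 0.5, R_c = 8, delta_R = 0,
                            delta_A = 2 * pi * 8 * 0.5)
  expect_equal(bending_energy(same, 0.2), 0)   # identical states bend nothing
  inverted <- gating_parameters(theta_c = 0.2, theta_o = 0.19, R_c = 3,
                                delta_R = 3)
  expect_false(inverted$well_posed)
  expect_error(midpoint_tension(inverted), class = "mechgate_midpoint_error")
  expect_error(midpoint_tension_root(inverted), class = "mechgate_midpoint_error")
})

test_that("open probability is a bounded logistic hitting 0.5 at the midpoint", {
  sh <- midpoint_tension_root(canonical)
  expect_equal(open_probability(canonical, sh), 0.5, tolerance = 1e-12)
  expect_equal(open_probability(canonical, 0.05), 1 / (1 + exp(2.110)),
               tolerance = 1e-3)
  expect_equal(open_probability(canonical, 100), 1, tolerance = 1e-6)
  grid <- seq(0, 1, length.out = 200)
  p <- open_probability(canonical, grid)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[grid >= sh] >= 0.5))
  # note P(0) = 0.5 too: the bending term vanishes with sigma, so dG(0) = dG0
  expect_true(all(p[grid > 0 & grid < sh * 0.999] < 0.5))
})

test_that("parameters rebuilt from state deltas close the loop", {
  delta <- tibble::tibble(theta_c_rad = pi / 6, theta_o_rad = pi / 12,
                          R_c_nm = 7.8131, R_o_nm = 8.9131,
                          delta_R_nm = 1.1, delta_A_nm2 = 54,
                          delta_height_A = 19)
  gp <- params_from_states(delta)
  expect_equal(round(midpoint_tension(gp), 2), 0.16)
  expect_true(gp$annular_consistent)
  # identity delta: flagged as having no positive midpoint
  flat <- tibble::tibble(theta_c_rad = pi / 6, theta_o_rad = pi / 6,
                         R_c_nm = 7.8, R_o_nm = 7.8, delta_R_nm = 0,
                         delta_A_nm2 = 1e-9, delta_height_A = 0)
  flat_gp <- suppressWarnings(params_from_states(flat))
  expect_false(flat_gp$well_posed)
  expect_error(midpoint_tension(flat_gp), class = "mechgate_midpoint_error")
  expect_error(params_from_states(delta[, 1:2]),
               class = "mechgate_incomplete_delta")
  # full pipeline closure on the synthetic mimic is covered in test-pipeline
})

test_that("tidy and glance expose the fitted quantities", {
  td <- tidy(canonical)
  expect_equal(td$value[td$term == "delta_A"], 54)
  expect_true(all(c("term", "value", "unit") %in% names(td)))
  gl <- glance(canonical)
  expect_equal(round(gl$sigma_half_kBT_nm2, 2), 0.16)
  expect_equal(gl$sigma_half_mN_m, 0.1587 * 4.114, tolerance = 1e-2)
  expect_true(gl$well_posed)
})

test_that("energetics curves carry the midpoint and respect bounds", {
  curve <- energetics_curve(canonical, n = 101)
  expect_equal(attr(curve, "sigma_half"), midpoint_tension(canonical),
               tolerance = 1e-8)
  expect_true(all(curve$P_open >= 0 & curve$P_open <= 1))
  expect_equal(curve$dG_total, curve$dG_bending - curve$sigma * 54)
  expect_s3_class(autoplot(curve), "ggplot")
})
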