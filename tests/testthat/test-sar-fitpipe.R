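test_that("noiseless SAR curves give back their generating parameters exactly", {
  cu <- gen_sar_curve(synthetic_spec(3, "none"), ref_sar_params())
  ft <- fit_sar_curve(cu, fit_config(Ms_vol = 93.4 * 5180,
                                     condition = "water"))
  expect_equal(ft$D, 18e-9, tolerance = 0.01)
  expect_equal(ft$C, 3, tolerance = 0.01)
  expect_equal(ft$tau_N0, 3e-5, tolerance = 0.01)
  expect_equal(ft$Gamma, ref_gamma_true(), tolerance = 0.01)
  expect_gt(ft$r_squared, 0.999)
})

test_that("viscosity surrogate and explicit Brown-disabled flag agree", {
  cu <- gen_sar_curve(synthetic_spec(4, "none"),
                      ref_sar_params(brown_disabled = TRUE),
                      condition = "solid_random")
  f1 <- fit_sar_curve(cu, fit_config(Ms_vol = 93.4 * 5180,
                                     condition = "solid_random"))  # eta 1e100
  f2 <- fit_sar_curve(cu, fit_config(Ms_vol = 93.4 * 5180,
                                     condition = "solid_random",
                                     eta = 1e-3, brown_disabled = TRUE))
  expect_equal(f1$D, f2$D, tolerance = 1e-9)
  expect_equal(f1$C, f2$C, tolerance = 1e-9)
  expect_equal(f1$Gamma, f2$Gamma, tolerance = 1e-9)
})

test_that("strict-xi and fixed-H-power modes coincide at C = 3", {
  cu <- gen_sar_curve(synthetic_spec(8, "none"), ref_sar_params())
  f_h3 <- fit_sar_curve(cu, fit_config(Ms_vol = 93.4 * 5180,
                                       condition = "water",
                                       h_power = "h3"))
  f_strict <- fit_sar_curve(cu, fit_config(Ms_vol = 93.4 * 5180,
                                           condition = "water",
                                           h_power = "strict"))
  expect_equal(f_h3$D, f_strict$D, tolerance = 1e-4)
  expect_equal(f_h3$C, f_strict$C, tolerance = 1e-4)
})

test_that("recovered C stays near 3 under 3% noise (small replicate set)", {
  # the acceptance suite runs the full 50-seed study; this is a smoke
  # version over 8 seeds
  cfg <- fit_config(Ms_vol = 93.4 * 5180, condition = "water")
  Cs <- vapply(1:8, function(s) {
    cu <- gen_sar_curve(synthetic_spec(s, "multiplicative", 0.03),
                        ref_sar_params())
    fit_sar_curve(cu, cfg)$C
  }, 0)
  expect_gt(stats::median(Cs), 2.5)
  expect_lt(stats::median(Cs), 3.5)
})

test_that("quadratic-region fit isolates the linear-response regime", {
  H <- seq(5e3, 65e3, by = 5e3)
  exact <- sar_curve(H, 2e-6 * H^2, condition = "water")
  q <- quadratic_region_fit(exact)
  expect_equal(q$a, 2e-6, tolerance = 1e-12)
  expect_equal(q$rel_residual, 0, tolerance = 1e-12)
  # model data confined to the linear-response window stay quadratic
  # to < 2%
  p <- ref_particle()
  H_xi03 <- 0.3 / langevin_argument(p$Ms_vol, p$D, 1, p$T)
  cu <- gen_sar_curve(synthetic_spec(2, "none"), ref_sar_params(),
                      H_grid = seq(0.1, 1, length.out = 8) * H_xi03)
  q2 <- quadratic_region_fit(cu, h_cut = H_xi03)
  expect_lt(q2$rel_residual, 0.02)
  # including the saturating region degrades the fit by > 5x
  full <- gen_sar_curve(synthetic_spec(2, "none"), ref_sar_params())
  q_low <- quadratic_region_fit(full, h_cut = 20e3)
  q_high <- quadratic_region_fit(full, h_cut = 65e3)
  expect_gt(q_high$rel_residual, 5 * q_low$rel_residual)
  expect_error(quadratic_region_fit(exact, h_cut = 6e3), "at least 3")
})

test_that("plateau SAR estimator is exact on tails and robust to duplicates", {
  H <- c(10e3, 30e3, 50e3, 55e3, 60e3, 65e3)
  cu <- sar_curve(H, c(100, 300, 500, 500, 500, 500), condition = "water")
  expect_equal(saturation_sar(cu)$sar, 500)
  dup <- sar_curve(c(H, 60e3), c(100, 300, 500, 500, 500, 500, 500),
                   condition = "water")
  expect_equal(saturation_sar(dup)$sar, 500)
  # on a monotone saturating model curve the plateau mean sits within 3%
  # of the model value at the top field
  cu2 <- gen_sar_curve(synthetic_spec(6, "none"), ref_sar_params())
  top <- cu2$SAR[which.max(cu2$H)]
  expect_equal(saturation_sar(cu2)$sar, top, tolerance = 0.03)
  low <- sar_curve(seq(5e3, 45e3, by = 10e3), 1:5, condition = "water")
  expect_error(saturation_sar(low), "plateau")
})

test_that("condition comparison returns signed percentages", {
  sat <- c(water = 1000, solid_random = 700, solid_aligned = 980)
  cc <- compare_conditions(sat)
  expect_equal(cc$immobilization_pct, -30)
  expect_equal(cc$alignment_pct, 40)
  same <- compare_conditions(c(water = 5, solid_random = 5))
  expect_equal(same$immobilization_pct, 0)
  expect_true(is.na(same$alignment_pct))
  expect_error(compare_conditions(c(water = 1)), "required")
})

test_that("SAR-Gamma correlation and SAR-Ms regressions behave", {
  g <- c(1e6, 2e6, 3e6, 4e6)
  s <- 2 + 5e-4 * g
  r <- correlate_sar_gamma(g, s)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 5e-4, tolerance = 1e-10)
  expect_equal(correlate_sar_gamma(rev(g), rev(s))$slope, r$slope,
               tolerance = 1e-12)
  expect_error(correlate_sar_gamma(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(correlate_sar_gamma(1:2, 1:2), "at least 3")

  ms <- c(65.9, 78.5, 93.4, 82.1)
  reg <- sar_vs_ms_regression(10 * ms, ms)
  expect_equal(reg$r, 1, tolerance = 1e-12)
  expect_equal(reg$slope, 10, tolerance = 1e-10)
  per <- sar_vs_ms_regression(c(10 * ms, 7 * ms), rep(ms, 2),
                              condition = rep(c("water", "solid_random"),
                                              each = 4))
  expect_equal(per$slope[per$condition == "water"], 10, tolerance = 1e-10)
  expect_equal(per$slope[per$condition == "solid_random"], 7,
               tolerance = 1e-10)
})
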