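test_that("zero-field Brown time follows the rotational-diffusion arithmetic", {
  p <- particle_model(16e-9, shell = 10e-9, eta = 1e-3, T = 310)
  # 3 * 1e-3 * (pi/6)(36 nm)^3 / (kB * 310) = 1.712e-5 s
  expect_equal(brown_time_zero_field(p), 1.712e-5, tolerance = 1e-3)
  # doubling the hydrodynamic diameter multiplies by 8
  p2 <- particle_model(32e-9, shell = 20e-9, eta = 1e-3, T = 310)
  expect_equal(brown_time_zero_field(p2) / brown_time_zero_field(p), 8,
               tolerance = 1e-12)
  # huge-viscosity surrogate effectively disables the channel
  psolid <- particle_model(16e-9, shell = 10e-9, eta = 1e100, T = 310)
  expect_gt(brown_time_zero_field(psolid), 1e70)
  pflag <- particle_model(16e-9, shell = 10e-9, brown_disabled = TRUE)
  expect_identical(brown_time_zero_field(pflag), Inf)
})

test_that("zero-field Neel time follows the Arrhenius barrier", {
  p <- particle_model(16e-9, K = 2e4, T = 300, tau0 = 1e-9)
  # sigma = 10.36, tau0 * exp(sigma)/2 = 1.57e-5 s
  expect_equal(neel_time_zero_field(p), 1.572e-5, tolerance = 1e-3)
  p0 <- particle_model(16e-9, K = 0, tau0 = 1e-9)
  expect_equal(neel_time_zero_field(p0), 0.5e-9, tolerance = 1e-12)
  Ds <- seq(8e-9, 24e-9, length.out = 10)
  taus <- vapply(Ds, function(D)
    neel_time_zero_field(particle_model(D, K = 2e4, T = 300)), 0)
  expect_true(all(diff(taus) > 0))
  expect_warning(
    expect_identical(
      neel_time_zero_field(particle_model(60e-9, K = 5e4, T = 300)), Inf),
    "overflow")
})

test_that("field-dependent Neel escape expression is consistent and guarded", {
  p <- particle_model(16e-9, K = 2e4, T = 300, Ms_vol = 4.5e5)
  expect_equal(neel_time_field_brown(p, 0), neel_time_zero_field(p),
               tolerance = 1e-12)
  # term-by-term oracle at h = 0.2, sigma = sigma_a(p)
  s <- p$K * p$Vm / (1.380649e-23 * 300)
  h <- 0.2
  H <- h * anisotropy_field(p)
  rate <- 1e9 * (1 - h^2) * ((1 + h) * exp(-s * (1 + h)^2) +
                             (1 - h) * exp(-s * (1 - h)^2))
  expect_equal(neel_time_field_brown(p, H), 1 / rate, tolerance = 1e-10)
  # monotone decreasing over the valid range for a sizeable barrier
  hs <- seq(0, 0.39, by = 0.01)
  taus <- vapply(hs, function(hh)
    suppressWarnings(neel_time_field_brown(p, hh * anisotropy_field(p))), 0)
  expect_true(all(diff(taus) < 0))
  expect_warning(neel_time_field_brown(p, 0.45 * anisotropy_field(p)),
                 "validity")
  expect_error(neel_time_field_brown(p, 1.0 * anisotropy_field(p)),
               "singular")
})

test_that("field-dependent Brown time has the stated closed-form points", {
  p <- particle_model(16e-9, shell = 2e-9, Ms_vol = 4.5e5, T = 300,
                      eta = 1e-3)
  tb0 <- brown_time_zero_field(p)
  expect_equal(brown_time_field(p, 0), tb0)
  # xi = sqrt(1/0.07) halves the squared denominator: tau = tau_B0/sqrt(2)
  xi_target <- sqrt(1 / 0.07)
  H <- xi_target / langevin_argument(p$Ms_vol, p$D, 1, p$T)
  expect_equal(brown_time_field(p, H), tb0 / sqrt(2), tolerance = 1e-10)
  expect_warning(brown_time_field(p, 1e6), "validity")
})

test_that("empirical Neel field dependence matches its algebra in both forms", {
  expect_equal(neel_time_field_empirical(2e-5, 0), 2e-5)
  # reported AC-susceptibility parameters: A = 1.97, C = 3.18 at xi = 1
  expect_equal(neel_time_field_empirical(1, 1, A = 1.97, C = 3.18),
               1 / sqrt(2.97), tolerance = 1e-12)
  expect_equal(neel_time_field_empirical(1, 1, A = 1.97, C = 3.18,
                                         form = "literal"),
               2.97, tolerance = 1e-12)
  expect_true(all(diff(neel_time_field_empirical(1, seq(0, 10, 0.5))) < 0))
})

test_that("asymptotic log-log slopes are -1 (Brown) and -1.5 (Neel, C = 3)", {
  p <- particle_model(16e-9, shell = 2e-9, Ms_vol = 4.5e5, T = 300)
  H <- 10^seq(log10(100e3), log10(1e7), length.out = 60)
  xi <- langevin_argument(p$Ms_vol, p$D, H, p$T)
  tb <- suppressWarnings(brown_time_field(p, H))
  slope_b <- stats::coef(stats::lm(log(tb) ~ log(H)))[2]
  expect_equal(unname(slope_b), -1, tolerance = 0.02)
  tn <- neel_time_field_empirical(1e-5, xi, A = 2, C = 3)
  slope_n <- stats::coef(stats::lm(log(tn) ~ log(H)))[2]
  expect_equal(unname(slope_n), -1.5, tolerance = 0.02)
})

test_that("effective time is the harmonic combination with Inf pass-through", {
  expect_equal(effective_time(2, 2), 1)
  expect_equal(effective_time(3e-5, Inf), 3e-5)
  expect_equal(effective_time(Inf, 4e-6), 4e-6)
  set.seed(11)
  a <- stats::rlnorm(200, -10, 3); b <- stats::rlnorm(200, -10, 3)
  eff <- effective_time(a, b)
  expect_equal(eff, a * b / (a + b), tolerance = 1e-12)
  expect_true(all(eff <= pmin(a, b)))
})

test_that("anisotropy field matches 2K/(mu0 Ms) and the quoted magnitude", {
  p <- particle_model(16e-9, K = 1.6e4, Ms_vol = 4.5e5)
  expect_equal(anisotropy_field(p), 56.6e3, tolerance = 1e-3)
  p2 <- particle_model(16e-9, K = 3.2e4, Ms_vol = 4.5e5)
  expect_equal(anisotropy_field(p2) / anisotropy_field(p), 2,
               tolerance = 1e-12)
  # with K = 2e4 the same formula gives ~70.7 kA/m
  expect_equal(anisotropy_field(particle_model(16e-9, K = 2e4,
                                               Ms_vol = 4.5e5)),
               70.7e3, tolerance = 1e-3)
})

test_that("relaxation map shows the classical crossover and field reversal", {
  p <- particle_model(16e-9, shell = 2e-9, Ms_vol = 4.5e5, K = 2e4,
                      T = 300, eta = 1e-3)
  D_grid <- seq(5e-9, 40e-9, by = 1e-9)
  map0 <- relaxation_map(p, D_grid, 0)
  # Neel dominates small sizes, Brown large ones, crossover at 15-20 nm
  expect_equal(map0$regime[map0$D_m == 10e-9], "neel")
  expect_equal(map0$regime[map0$D_m == 25e-9], "brown")
  cross <- D_grid[which(map0$tau_N_s > map0$tau_B_s)[1]]
  expect_gte(cross, 15e-9); expect_lte(cross, 20e-9)
  # at high amplitude the Neel channel prevails even at 35 nm
  map60 <- relaxation_map(p, 35e-9, 60e3)
  expect_equal(map60$regime, "neel")
  # invariant: effective time never exceeds either channel
  mapg <- relaxation_map(p, c(8e-9, 16e-9, 24e-9, 35e-9),
                         c(0, 10e3, 30e3, 60e3))
  ok <- !is.na(mapg$tau_eff_s)
  expect_true(all(mapg$tau_eff_s[ok] <=
                  pmin(mapg$tau_N_s[ok], mapg$tau_B_s[ok]) + 1e-30))
  # cells beyond the h = 1 singularity are NA rather than nonsense
  map_h1 <- relaxation_map(p, 35e-9, 80e3)
  expect_true(is.na(map_h1$tau_N_s))
})
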