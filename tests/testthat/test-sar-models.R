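test_that("static susceptibility follows its defining arithmetic", {
  p <- particle_model(16e-9, Ms_vol = 4.5e5, T = 300)
  # mu0 * (4.5e5)^2 * (pi/6)(16 nm)^3 / (3 kB 300) = 43.92
  expect_equal(static_susceptibility(p), 43.92, tolerance = 1e-3)
  p2 <- particle_model(16e-9, Ms_vol = 9e5, T = 300)
  expect_equal(static_susceptibility(p2) / static_susceptibility(p), 4,
               tolerance = 1e-12)
  pT <- particle_model(16e-9, Ms_vol = 4.5e5, T = 3e6)
  expect_lt(static_susceptibility(pT), 0.01)
})

test_that("out-of-phase susceptibility peaks at omega*tau = 1 with value chi0/2", {
  chi0 <- 43.9
  expect_equal(chi_imaginary(chi0, 1, 1), chi0 / 2)
  wt <- 10^seq(-3, 3, length.out = 301)
  vals <- chi_imaginary(chi0, wt, 1)
  expect_equal(max(vals), chi0 / 2, tolerance = 1e-6)
  expect_equal(wt[which.max(vals)], 1, tolerance = 0.03)
  # algebraic symmetry under omega*tau -> 1/(omega*tau)
  expect_equal(chi_imaginary(chi0, 7.3, 1), chi_imaginary(chi0, 1 / 7.3, 1),
               tolerance = 1e-12)
  expect_equal(chi_imaginary(chi0, 1e-9, 1), 0, tolerance = 1e-7)
})

test_that("linear-response power is quadratic in amplitude and matches arithmetic", {
  # mu0*pi*0.1*355 kHz*(20 kA/m)^2 = 5.61e7 W/m^3
  expect_equal(lrt_volumetric_power(driving_field(355e3, 20e3), 0.1),
               5.606e7, tolerance = 1e-3)
  p1 <- lrt_volumetric_power(driving_field(355e3, 10e3), 0.1)
  p2 <- lrt_volumetric_power(driving_field(355e3, 20e3), 0.1)
  expect_equal(p2 / p1, 4, tolerance = 1e-12)
  expect_equal(lrt_volumetric_power(driving_field(355e3, 20e3), 0), 0)
})

test_that("Gamma prefactor matches arithmetic and is linear in each factor", {
  # pi*mu0*355 kHz*35 kA/m*4.5e5/5180 = 4.261e6 W/kg
  expect_equal(gamma_coefficient(driving_field(355e3, 35e3), 4.5e5, 5180),
               4.261e6, tolerance = 1e-3)
  expect_equal(gamma_coefficient(driving_field(355e3, 0), 4.5e5, 5180), 0)
  g1 <- gamma_coefficient(driving_field(355e3, 35e3), 4.5e5, 5180)
  expect_equal(gamma_coefficient(driving_field(710e3, 35e3), 4.5e5, 5180),
               2 * g1, tolerance = 1e-12)
  expect_equal(gamma_coefficient(driving_field(355e3, 70e3), 4.5e5, 5180),
               2 * g1, tolerance = 1e-12)
})

test_that("saturation SAR model is zero at H = 0 and nonnegative", {
  pars <- ref_sar_params()
  H <- c(0, seq(1e3, 65e3, by = 2e3))
  sar <- sar_saturation_model(driving_field(355e3, H), pars)
  expect_equal(sar[1], 0)
  expect_true(all(sar >= 0))
  # Gamma = 0 kills the output everywhere
  pars0 <- sar_model_params(ref_particle(), tau_N0 = 3e-5, Gamma = 0)
  expect_equal(sar_saturation_model(driving_field(355e3, H), pars0),
               rep(0, length(H)))
})

test_that("saturation model reduces to linear response at small field", {
  p <- ref_particle()
  pars <- ref_sar_params()                # Gamma from eq9 constants
  f <- 355e3; H <- 1                      # xi ~ 4e-4: deep linear regime
  sar <- sar_saturation_model(driving_field(f, H), pars)
  chi0 <- static_susceptibility(p)
  tau0_eff <- effective_time(3e-5, brown_time_zero_field(p))
  chi2 <- chi_imaginary(chi0, 2 * pi * f, tau0_eff)
  lrt <- lrt_volumetric_power(driving_field(f, H), chi2) / 5180
  expect_equal(sar, lrt, tolerance = 1e-6)
})

test_that("saturation model flattens at high field", {
  pars <- ref_sar_params()
  f <- driving_field(355e3, c(19.9e3, 20.1e3, 59.9e3, 60.1e3))
  s <- sar_saturation_model(f, pars)
  slope20 <- (s[2] - s[1]) / 200
  slope60 <- (s[4] - s[3]) / 200
  expect_lt(slope60, 0.2 * slope20)
})

test_that("SAR is quadratic in the linear-response window xi <= 0.3", {
  pars <- ref_sar_params()
  p <- pars$particle
  H_xi03 <- 0.3 / langevin_argument(p$Ms_vol, p$D, 1, p$T)
  H <- seq(0.1, 1, length.out = 7) * H_xi03
  s <- sar_saturation_model(driving_field(355e3, H), pars)
  a <- sum(s * H^2) / sum(H^4)
  rel <- sqrt(mean((s - a * H^2)^2)) / sqrt(mean(s^2))
  expect_lt(rel, 0.02)
})

test_that("above the linear-response window SAR grows faster than H^2 before saturating", {
  # omega*tau starts well above 1 here, so the falling relaxation time
  # first boosts the absorption (superquadratic), then the Langevin and
  # Debye factors cap it: SAR/H^2 rises to a maximum and falls
  pars <- ref_sar_params()
  H <- seq(1e3, 65e3, by = 2e3)
  ratio <- sar_saturation_model(driving_field(355e3, H), pars) / H^2
  imax <- which.max(ratio)
  expect_gt(imax, 3); expect_lt(imax, length(H) - 3)
  expect_true(all(diff(ratio[1:imax]) > 0))
  expect_true(all(diff(ratio[imax:length(H)]) < 0))
})
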