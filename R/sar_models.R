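# Linear-response heating model and the Langevin-saturation SAR model.

#' Alternating driving field
#'
#' @param f frequency, Hz (> 0).
#' @param Hmax field amplitude(s), A/m (>= 0; may be a vector).
#' @return Object of class `driving_field` with the angular frequency
#'   `omega = 2*pi*f` precomputed.
#' @export
driving_field <- function(f, Hmax) {
  stopifnot(f > 0, all(Hmax >= 0))
  structure(list(f = f, Hmax = Hmax, omega = 2 * pi * f),
            class = "driving_field")
}

#' Static (equilibrium) susceptibility of a superparamagnetic particle
#'
#' chi0 = mu0 * Ms_vol^2 * V_m / (3 * kB * T).
#'
#' @param p a [particle_model()].
#' @return Dimensionless susceptibility.
#' @export
static_susceptibility <- function(p) {
  stopifnot(inherits(p, "particle_model"))
  mnp_constants$mu0 * p$Ms_vol^2 * p$Vm / (3 * mnp_constants$kB * p$T)
}

#' Imaginary (out-of-phase) part of the Debye susceptibility
#'
#' chi'' = chi0 * omega*tau / (1 + (omega*tau)^2); maximal, equal to
#' chi0/2, at omega*tau = 1.
#'
#' @param chi0 static susceptibility.
#' @param omega angular frequency, rad/s.
#' @param tau relaxation time, s.
#' @return Dimensionless chi'' (vectorized over any argument).
#' @export
chi_imaginary <- function(chi0, omega, tau) {
  wt <- omega * tau
  chi0 * wt / (1 + wt^2)
}

#' Linear-response volumetric heating power
#'
#' P = mu0 * pi * chi'' * f * Hmax^2 — the small-field dissipation rate,
#' quadratic in the field amplitude.
#'
#' @param field a [driving_field()].
#' @param chi_imag out-of-phase susceptibility.
#' @return Power density, W/m^3.
#' @export
lrt_volumetric_power <- function(field, chi_imag) {
  stopifnot(inherits(field, "driving_field"))
  mnp_constants$mu0 * pi * chi_imag * field$f * field$Hmax^2
}

#' Saturation-model prefactor Gamma
#'
#' Gamma = pi * mu0 * f * H * Ms_vol / rho, in W/kg.  In the saturated
#' model this replaces the chi0*H^2 factor of linear response: one power
#' of H stays explicit here, the other is absorbed into the Langevin
#' term.
#'
#' @param field a [driving_field()] (its `Hmax` supplies H).
#' @param Ms_vol volume saturation magnetization, A/m.
#' @param density particle density, kg/m^3.
#' @return Gamma in W/kg (vectorized along `Hmax`).
#' @export
gamma_coefficient <- function(field, Ms_vol, density = 5180) {
  stopifnot(inherits(field, "driving_field"))
  if (density <= 0) stop("density must be positive")
  pi * mnp_constants$mu0 * field$f * field$Hmax * Ms_vol / density
}

#' Parameter bundle for the Langevin-saturation SAR model
#'
#' @param particle a [particle_model()]; supplies D, Ms_vol, T, eta,
#'   shell (hydrodynamic size) and the Brown channel.
#' @param density particle density, kg/m^3.
#' @param tau_N0 zero-field Neel time, s; defaults to the Arrhenius
#'   value [neel_time_zero_field()] of `particle`.
#' @param A,C empirical field-dependence parameters of the Neel time.
#' @param Gamma optional fitted prefactor, W/kg, interpreted as the
#'   value of Gamma at the reference amplitude `H_ref` (the model scales
#'   it linearly in H).  When `NULL`, Gamma is computed from frequency,
#'   Ms_vol and density at each field point.
#' @param H_ref reference amplitude for `Gamma`, A/m.
#' @return Object of class `sar_model_params`.
#' @export
sar_model_params <- function(particle, density = 5180, tau_N0 = NULL,
                             A = 2, C = 3, Gamma = NULL, H_ref = 65e3) {
  stopifnot(inherits(particle, "particle_model"))
  if (is.null(tau_N0)) tau_N0 <- neel_time_zero_field(particle)
  stopifnot(tau_N0 > 0, A >= 0, C > 0, is.null(Gamma) || Gamma >= 0)
  structure(list(particle = particle, density = density, tau_N0 = tau_N0,
                 A = A, C = C, Gamma = Gamma, H_ref = H_ref),
            class = "sar_model_params")
}

#' Langevin-saturation SAR model
#'
#' SAR(H) = Gamma(H) * L(xi) * omega*tau / (1 + (omega*tau)^2), where
#' xi = mu0*Ms_vol*V_m*H/(kB*T) uses the field amplitude, L is the
#' Langevin function replacing the linear static susceptibility, and
#' tau(H) is the effective relaxation time combining the empirical
#' field-dependent Neel time with the field-dependent Brown time (the
#' latter infinite for immobilized particles).  Gamma(H) scales linearly
#' in H, so the low-field limit is quadratic in H and coincides with
#' linear response.
#'
#' @param field a [driving_field()]; `Hmax` may be a vector.
#' @param params a [sar_model_params()].
#' @return SAR in W/kg of particle mass, one value per field amplitude.
#' @examples
#' p <- particle_model(18e-9, shell = 10e-9, Ms_vol = 4.8e5, T = 310)
#' sar_saturation_model(driving_field(355e3, c(1e4, 3e4, 6e4)),
#'                      sar_model_params(p, tau_N0 = 3e-5))
#' @export
sar_saturation_model <- function(field, params) {
  stopifnot(inherits(field, "driving_field"),
            inherits(params, "sar_model_params"))
  p <- params$particle
  H <- field$Hmax
  xi <- langevin_argument(p$Ms_vol, p$D, H, p$T)
  tau_N <- neel_time_field_empirical(params$tau_N0, xi,
                                     A = params$A, C = params$C)
  tau_B <- brown_time_field(p, H, warn = FALSE)
  tau <- effective_time(tau_N, tau_B)
  gam <- if (is.null(params$Gamma)) {
    gamma_coefficient(field, p$Ms_vol, params$density)
  } else {
    params$Gamma * H / params$H_ref
  }
  wt <- field$omega * tau
  gam * langevin(xi) * wt / (1 + wt^2)
}
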