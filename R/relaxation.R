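# Neel and Brown relaxation times, zero-field and field-dependent forms,
# and (D, H) relaxation-regime maps.

#' Physical model of one nanoparticle population
#'
#' @param D magnetic core diameter, m.
#' @param shell nonmagnetic/coating layer thickness, m; the hydrodynamic
#'   diameter is D + 2*shell.
#' @param Ms_vol volume saturation magnetization, A/m.
#' @param K effective uniaxial anisotropy constant, J/m^3.
#' @param tau0 Neel attempt time, s (order 1e-9 to 1e-10).
#' @param T absolute temperature, K.
#' @param eta solvent dynamic viscosity, Pa*s.  A frozen matrix can be
#'   represented either by a huge surrogate viscosity (1e100 Pa*s) or by
#'   `brown_disabled = TRUE`; the two are exactly equivalent downstream.
#' @param brown_disabled logical; force an infinite Brown time.
#' @return Object of class `particle_model` with derived volumes `Vm`
#'   (magnetic) and `Vh` (hydrodynamic).
#' @examples
#' p <- particle_model(D = 16e-9, shell = 2e-9)
#' neel_time_zero_field(p)
#' @export
particle_model <- function(D, shell = 2e-9, Ms_vol = 4.5e5, K = 2e4,
                           tau0 = 1e-9, T = 300, eta = 1e-3,
                           brown_disabled = FALSE) {
  stopifnot(D > 0, shell >= 0, Ms_vol > 0, K >= 0, tau0 > 0, T > 0, eta > 0)
  Dh <- D + 2 * shell
  structure(list(D = D, shell = shell, Ms_vol = Ms_vol, K = K,
                 tau0 = tau0, T = T, eta = eta,
                 brown_disabled = isTRUE(brown_disabled),
                 Dh = Dh, Vm = pi * D^3 / 6, Vh = pi * Dh^3 / 6),
            class = "particle_model")
}

# reduced anisotropy barrier sigma = K Vm / kB T
.sigma_a <- function(p) p$K * p$Vm / (mnp_constants$kB * p$T)

#' Zero-field Brown relaxation time
#'
#' tau_B0 = 3 * eta * V_h / (kB * T): rotational diffusion of the whole
#' particle in the solvent.
#'
#' @param p a [particle_model()].
#' @return Time in s; `Inf` when Brown relaxation is disabled.
#' @export
brown_time_zero_field <- function(p) {
  stopifnot(inherits(p, "particle_model"))
  if (p$brown_disabled) return(Inf)
  3 * p$eta * p$Vh / (mnp_constants$kB * p$T)
}

#' Zero-field Neel relaxation time
#'
#' tau_N0 = tau0 * exp(sigma) / 2 with sigma = K*Vm/(kB*T) — the h = 0
#' limit of the field-dependent escape-rate expression, where both wells
#' contribute a rate exp(-sigma)/tau0.
#'
#' @param p a [particle_model()].
#' @return Time in s; overflows (sigma > ~700) return `Inf` with a
#'   warning.
#' @export
neel_time_zero_field <- function(p) {
  stopifnot(inherits(p, "particle_model"))
  s <- .sigma_a(p)
  if (s > 700) {
    warning("anisotropy barrier sigma = ", signif(s, 4),
            " overflows exp(); returning Inf")
    return(Inf)
  }
  p$tau0 * exp(s) / 2
}

#' Field-dependent Neel time from the static escape-rate expression
#'
#' 1/tau_N = (1/tau0) * (1 - h^2) * ((1+h) exp(-sigma (1+h)^2) +
#' (1-h) exp(-sigma (1-h)^2)), with h = H / H_k the field normalized by
#' the anisotropy field.  The expression diverges at h = 1 and its
#' validity against numerical simulation is restricted to h < 0.4, so
#' h >= 1 is an error and h > 0.4 raises a warning.
#'
#' @param p a [particle_model()].
#' @param H field amplitude, A/m (scalar).
#' @return Time in s.
#' @export
neel_time_field_brown <- function(p, H) {
  stopifnot(inherits(p, "particle_model"))
  h <- H / anisotropy_field(p)
  if (h >= 1)
    stop("reduced field h = ", signif(h, 4),
         " >= 1: the static escape-rate expression is singular at h = 1")
  if (h > 0.4)
    warning("reduced field h = ", signif(h, 4),
            " exceeds the stated h < 0.4 validity range")
  s <- .sigma_a(p)
  rate <- (1 / p$tau0) * (1 - h^2) *
    ((1 + h) * exp(-s * (1 + h)^2) + (1 - h) * exp(-s * (1 - h)^2))
  if (rate <= 0) return(Inf)
  1 / rate
}

#' Field-dependent Brown relaxation time
#'
#' tau_B(H) = tau_B0 / sqrt(1 + 0.07 * xi^2), the Fokker-Planck result
#' for thermally blocked particles in a large AC field, stated valid for
#' xi < 20 (a warning is raised beyond, the value still computed).
#' Asymptotically tau_B ~ H^-1.
#'
#' @param p a [particle_model()].
#' @param H field amplitude, A/m (vectorized).
#' @param warn warn when xi exceeds the validity range (default TRUE).
#' @return Time in s (vector).
#' @export
brown_time_field <- function(p, H, warn = TRUE) {
  stopifnot(inherits(p, "particle_model"))
  xi <- langevin_argument(p$Ms_vol, p$D, H, p$T)
  if (warn && any(xi >= 20))
    warning("xi = ", signif(max(xi), 4),
            " exceeds the stated xi < 20 validity range")
  brown_time_zero_field(p) / sqrt(1 + 0.07 * xi^2)
}

#' Empirical field-dependent Neel relaxation time
#'
#' Default form tau_N(xi) = tau_N0 / sqrt(1 + A * xi^C), mirroring the
#' Brown-time field dependence: tau_N decreases with field with
#' asymptotic log-log slope -C/2 versus H (-1.5 for C = 3).  The
#' alternative `form = "literal"` evaluates tau_N0 * (1 + A * xi^C),
#' which instead grows with field; it is kept only for comparison, as
#' relaxation times of superparamagnets shorten in strong AC fields.
#'
#' @param tau_N0 zero-field Neel time, s.
#' @param xi dimensionless field argument (vectorized).
#' @param A prefactor, >= 0 (2 in the constrained SAR fits).
#' @param C exponent, > 0 (near 3).
#' @param form `"damped"` (default) or `"literal"`.
#' @return Time in s (vector).
#' @export
neel_time_field_empirical <- function(tau_N0, xi, A = 2, C = 3,
                                      form = c("damped", "literal")) {
  form <- match.arg(form)
  stopifnot(A >= 0, C > 0)
  g <- 1 + A * abs(xi)^C
  if (form == "damped") tau_N0 / sqrt(g) else tau_N0 * g
}

#' Effective relaxation time
#'
#' Harmonic combination 1/tau = 1/tau_N + 1/tau_B; the faster mechanism
#' dominates.  Infinite inputs are allowed (a disabled channel).
#'
#' @param tau_N,tau_B relaxation times, s (> 0, `Inf` allowed).
#' @return Effective time, s; always <= min(tau_N, tau_B).
#' @export
effective_time <- function(tau_N, tau_B) {
  stopifnot(all(tau_N > 0), all(tau_B > 0))
  1 / (1 / tau_N + 1 / tau_B)
}

#' Anisotropy field of a uniaxial particle
#'
#' H_k = 2K / (mu0 * Ms_vol), the field scale normalizing h = H/H_k in
#' the field-dependent Neel expression.
#'
#' @param p a [particle_model()].
#' @return Field in A/m.
#' @examples
#' anisotropy_field(particle_model(16e-9, K = 1.6e4, Ms_vol = 4.5e5))
#' @export
anisotropy_field <- function(p) {
  stopifnot(inherits(p, "particle_model"))
  if (p$K <= 0 || p$Ms_vol <= 0) stop("K and Ms_vol must be positive")
  2 * p$K / (mnp_constants$mu0 * p$Ms_vol)
}

#' Relaxation-regime map over size and field amplitude
#'
#' Computes Neel, Brown and effective relaxation times on a (D, H) grid
#' and labels the dominant regime per cell: the channel with the shorter
#' time ("neel" or "brown"), or "mixed" when the two agree within 5%.
#'
#' The Neel channel uses, by default, the static escape-rate expression
#' (`neel_form = "brown"`, the form behind published relaxation
#' surfaces); cells with reduced field h >= 1, where that expression is
#' singular, get `NA`.  `neel_form = "empirical"` uses the damped
#' empirical law seeded with the zero-field Neel time instead.
#'
#' @param p a [particle_model()] carrying everything but the diameter.
#' @param D_grid diameters, m.
#' @param H_grid field amplitudes, A/m.
#' @param neel_form `"brown"` or `"empirical"`.
#' @param A,C empirical-form parameters.
#' @return A data.frame in long format with columns `D_m`, `H_A_per_m`,
#'   `tau_N_s`, `tau_B_s`, `tau_eff_s`, `regime`.
#' @export
relaxation_map <- function(p, D_grid, H_grid,
                           neel_form = c("brown", "empirical"),
                           A = 2, C = 3) {
  stopifnot(inherits(p, "particle_model"),
            length(D_grid) > 0, length(H_grid) > 0)
  neel_form <- match.arg(neel_form)
  grid <- expand.grid(D_m = D_grid, H_A_per_m = H_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  tau_N <- tau_B <- numeric(n)
  for (i in seq_len(n)) {
    pi_ <- particle_model(D = grid$D_m[i], shell = p$shell,
                          Ms_vol = p$Ms_vol, K = p$K, tau0 = p$tau0,
                          T = p$T, eta = p$eta,
                          brown_disabled = p$brown_disabled)
    H <- grid$H_A_per_m[i]
    tau_B[i] <- suppressWarnings(brown_time_field(pi_, H))
    if (neel_form == "brown") {
      h <- H / anisotropy_field(pi_)
      tau_N[i] <- if (h >= 1) NA_real_ else
        suppressWarnings(neel_time_field_brown(pi_, H))
    } else {
      tn0 <- suppressWarnings(neel_time_zero_field(pi_))
      xi <- langevin_argument(pi_$Ms_vol, pi_$D, H, pi_$T)
      tau_N[i] <- neel_time_field_empirical(tn0, xi, A = A, C = C)
    }
  }
  tau_eff <- ifelse(is.na(tau_N), NA_real_, effective_time(tau_N, tau_B))
  ratio <- tau_N / tau_B
  regime <- ifelse(is.na(tau_N), NA_character_,
            ifelse(ratio < 1 / 1.05, "neel",
            ifelse(ratio > 1.05, "brown", "mixed")))
  data.frame(grid, tau_N_s = tau_N, tau_B_s = tau_B,
             tau_eff_s = tau_eff, regime = regime,
             stringsAsFactors = FALSE)
}
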