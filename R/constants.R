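#' Physical constants and run-wide defaults
#'
#' All internal computation is in SI units; unit conversion happens only at
#' I/O boundaries (see [read_curve_csv()]).
#'
#' @format `mnp_constants` is a named list with components:
#' \describe{
#'   \item{mu0}{vacuum magnetic permeability, 4*pi*1e-7 T*m/A}
#'   \item{kB}{Boltzmann constant, J/K (2019 SI exact value)}
#' }
#' @export
mnp_constants <- list(
  mu0 = 4 * pi * 1e-7,
  kB  = 1.380649e-23
)

#' Assemble a run configuration
#'
#' Collects every tunable default of the analysis chain in one overridable
#' list.  The physical constants themselves are fixed in [mnp_constants].
#'
#' @param ... named overrides of any default listed below.
#'
#' @details Defaults and their origin:
#' \describe{
#'   \item{density}{5180 kg/m^3, bulk magnetite; converts mass to volume
#'     magnetization.}
#'   \item{tau0}{1e-9 s, attempt time of the Neel process.}
#'   \item{shell_solid}{2e-9 m nonmagnetic layer for relaxation maps.}
#'   \item{shell_water}{10e-9 m hydrodynamic coating used when fitting
#'     SAR curves measured in water.}
#'   \item{T_magnetometry}{300 K, room-temperature magnetization branch.}
#'   \item{T_hyperthermia}{310 K, physiological temperature.}
#'   \item{frequency}{355e3 Hz driving frequency.}
#'   \item{window_s}{10 s initial-slope window for calorimetry.}
#'   \item{c_water, c_peg8k}{specific heats, J/(kg K).}
#'   \item{m_water, m_peg8k}{sample masses, kg (0.5 mL of each medium).}
#'   \item{eta_water}{1e-3 Pa*s solvent viscosity.}
#'   \item{eta_solid}{1e100 Pa*s surrogate for a frozen matrix (Brown
#'     relaxation disabled).}
#'   \item{A_fixed}{2, fixed prefactor of the empirical field-dependent
#'     Neel time used during SAR fitting.}
#'   \item{H_ref}{65e3 A/m reference amplitude at which fitted Gamma is
#'     reported (top of the studied field range).}
#' }
#' @return A named list of class `run_config`.
#' @examples
#' cfg <- run_config(T_hyperthermia = 300)
#' cfg$density
#' @export
run_config <- function(...) {
  cfg <- list(
    density         = 5180,
    tau0            = 1e-9,
    shell_solid     = 2e-9,
    shell_water     = 10e-9,
    T_magnetometry  = 300,
    T_hyperthermia  = 310,
    frequency       = 355e3,
    window_s        = 10,
    c_water         = 4186.8,
    c_peg8k         = 2135.27,
    m_water         = 0.5e-3,
    m_peg8k         = 0.5426e-3,
    eta_water       = 1e-3,
    eta_solid       = 1e100,
    A_fixed         = 2,
    H_ref           = 65e3
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "run_config")
}
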