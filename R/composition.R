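# Stoichiometry and crystallography helpers for Zn_x Fe_(3-x) O_4.

#' Zinc-substituted magnetite stoichiometry
#'
#' @param x zinc substitution level per formula unit Zn_x Fe_(3-x) O_4;
#'   must satisfy 0 <= x <= 3.
#' @param m_Fe,m_Zn,m_O atomic masses in u (IUPAC standard values by
#'   default; overridable so that tabulated iron contents can be
#'   reproduced with other mass conventions).
#' @return Object of class `stoichiometry`.
#' @examples
#' s <- stoichiometry(0.3)
#' iron_mass_fraction(s)
#' @export
stoichiometry <- function(x, m_Fe = 55.845, m_Zn = 65.38, m_O = 15.999) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop("x must be a single number")
  if (x < 0 || x > 3)
    stop("zinc substitution level x must lie in [0, 3]")
  fu <- x * m_Zn + (3 - x) * m_Fe + 4 * m_O
  stopifnot(fu > 0)
  structure(list(x = x, m_Fe = m_Fe, m_Zn = m_Zn, m_O = m_O,
                 formula_mass = fu),
            class = "stoichiometry")
}

#' Mass fraction of iron in Zn_x Fe_(3-x) O_4
#'
#' Fraction of the formula-unit mass carried by the iron cations,
#' (3-x)*m_Fe / (x*m_Zn + (3-x)*m_Fe + 4*m_O).  Multiplied by the sample
#' mass this gives the iron mass entering the SAR normalization.
#'
#' @param s a [stoichiometry()] object.
#' @return Dimensionless fraction in [0, 1).
#' @examples
#' iron_mass_fraction(stoichiometry(0))    # 0.724 per mg of particles
#' @export
iron_mass_fraction <- function(s) {
  stopifnot(inherits(s, "stoichiometry"))
  (3 - s$x) * s$m_Fe / s$formula_mass
}

#' Invert EDX atomic percentages to the zinc substitution level
#'
#' Given the Fe and Zn cation atomic percentages from an EDX analysis,
#' returns x = 3 * Zn / (Fe + Zn): the three cation sites per formula
#' unit are split between Zn and Fe.
#'
#' @param fe_pct,zn_pct atomic percentages (any common scale); both
#'   nonnegative, not both zero.
#' @return x, dimensionless.
#' @examples
#' x_from_edx(91, 9)      # 0.27
#' x_from_edx(85.1, 14.9) # 0.447
#' @export
x_from_edx <- function(fe_pct, zn_pct) {
  if (any(fe_pct < 0) || any(zn_pct < 0))
    stop("atomic percentages must be nonnegative")
  tot <- fe_pct + zn_pct
  if (any(tot <= 0))
    stop("Fe and Zn percentages cannot both be zero")
  3 * zn_pct / tot
}

#' Theoretical cation atomic percentages for a given x
#'
#' @param s a [stoichiometry()] object.
#' @return Named numeric vector `c(Fe = , Zn = )` in percent of the
#'   cation sites (full precision; round only for display).
#' @examples
#' cation_percentages(stoichiometry(0.1))
#' @export
cation_percentages <- function(s) {
  stopifnot(inherits(s, "stoichiometry"))
  c(Fe = 100 * (3 - s$x) / 3, Zn = 100 * s$x / 3)
}

#' Describe one X-ray diffraction peak
#'
#' @param two_theta peak position 2-theta in degrees, in (0, 180).
#' @param fwhm full width at half maximum in degrees (> 0); Gaussian fit
#'   widths are the usual source.
#' @param hkl integer Miller-index triple, e.g. `c(3, 1, 1)`.
#' @param wavelength radiation wavelength in nm (default Cu K-alpha1).
#' @return Object of class `xrd_peak`.
#' @export
xrd_peak <- function(two_theta, fwhm = NA_real_, hkl = c(3, 1, 1),
                     wavelength = 0.154056) {
  if (two_theta <= 0 || two_theta >= 180)
    stop("two_theta must lie in (0, 180) degrees")
  if (!is.na(fwhm) && fwhm <= 0)
    stop("fwhm must be positive")
  stopifnot(length(hkl) == 3)
  structure(list(two_theta = two_theta, fwhm = fwhm,
                 hkl = as.integer(hkl), wavelength = wavelength),
            class = "xrd_peak")
}

#' Crystallite size from peak broadening (Scherrer)
#'
#' D = K * lambda / (beta * cos(theta)), with beta the FWHM converted to
#' radians and theta half the scattering angle.
#'
#' @param p an [xrd_peak()] with a finite `fwhm`.
#' @param shape_factor Scherrer constant K; 0.9 for near-spherical
#'   crystallites.
#' @return Crystallite size in nm.
#' @examples
#' scherrer_size(xrd_peak(35.4, fwhm = 0.55))
#' @export
scherrer_size <- function(p, shape_factor = 0.9) {
  stopifnot(inherits(p, "xrd_peak"))
  if (is.na(p$fwhm) || p$fwhm <= 0)
    stop("peak fwhm must be positive to apply the Scherrer formula")
  beta  <- p$fwhm * pi / 180
  theta <- p$two_theta / 2 * pi / 180
  shape_factor * p$wavelength / (beta * cos(theta))
}

#' Cubic lattice parameter from a single indexed reflection
#'
#' Combines Bragg's law with the cubic plane spacing
#' d = a / sqrt(h^2 + k^2 + l^2), giving
#' a = lambda * sqrt(h^2 + k^2 + l^2) / (2 sin theta).
#'
#' @param p an [xrd_peak()] with a non-zero `hkl`.
#' @return Lattice parameter in Angstrom (wavelength is held in nm;
#'   the result is converted, 1 nm = 10 Angstrom).
#' @examples
#' cubic_lattice_parameter(xrd_peak(35.35, hkl = c(3, 1, 1)))
#' @export
cubic_lattice_parameter <- function(p) {
  stopifnot(inherits(p, "xrd_peak"))
  n2 <- sum(p$hkl^2)
  if (n2 == 0)
    stop("hkl = (0,0,0) does not index a reflection")
  theta <- p$two_theta / 2 * pi / 180
  10 * p$wavelength * sqrt(n2) / (2 * sin(theta))
}

#' Forward Bragg angle for a cubic reflection
#'
#' Convenience inverse of [cubic_lattice_parameter()]: the 2-theta (deg)
#' at which plane `hkl` of a cubic lattice with parameter `a` diffracts.
#'
#' @param a lattice parameter in Angstrom.
#' @param hkl Miller triple.
#' @param wavelength nm.
#' @return 2-theta in degrees.
#' @export
bragg_two_theta <- function(a, hkl, wavelength = 0.154056) {
  d <- a / sqrt(sum(hkl^2))            # Angstrom
  s <- 10 * wavelength / (2 * d)
  if (s > 1) stop("reflection not reachable with this wavelength")
  2 * asin(s) * 180 / pi
}
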