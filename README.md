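# mnpheat

Quantitative analysis of magnetic nanoparticle hyperthermia for
superparamagnetic spinel ferrites (zinc-substituted magnetite,
Zn<sub>x</sub>Fe<sub>3−x</sub>O<sub>4</sub>).

Magnetic fluid hyperthermia heats tumours with nanoparticles driven by
an alternating magnetic field (AMF). How much heat a particle releases —
its specific absorption rate, SAR (W/kg of iron) — depends on its
saturation magnetization, its size, the relaxation mechanism (Néel
rotation of the moment vs Brown rotation of the particle), and the AMF
amplitude H and frequency f. This package is for experimentalists and
modellers who need to go from raw measurements (magnetization curves,
calorimetric heating records, SAR-vs-field tables) to fitted physical
parameters and comparative statistics, with every step testable against
synthetic data of known ground truth.

## The models at its core

**Magnetometry.** The room-temperature branch M(H) is fitted with a
log-normal Langevin ensemble,

M(H) = M_s ∫ f(D; D₀, σ) L(ξ) dD + χH,  L(ξ) = coth ξ − 1/ξ,
ξ = μ₀ M_s,vol V_m H / k_B T,

yielding the magnetic size distribution (median D₀, shape σ, mean
D_mean = D₀ e^{σ²/2}).

**Relaxation.** Zero-field times τ_N0 = τ₀ e^{KV_m/k_BT}/2 and
τ_B0 = 3ηV_h/k_BT; field dependences τ_B = τ_B0/√(1+0.07ξ²) and
τ_N = τ_N0/√(1+Aξ^C); harmonic combination 1/τ = 1/τ_N + 1/τ_B; and
size–field regime maps.

**Heating.** Linear response P = μ₀π χ″ f H², χ″ = χ₀ωτ/(1+(ωτ)²);
and the Langevin-saturation model

SAR(H) = Γ(H) · L(ξ) · ωτ(H)/(1+(ωτ(H))²),  Γ = πμ₀ f H M_s,vol / ρ,

which reduces to linear response at small ξ and saturates at high
amplitude. `fit_sar_curve()` fits measured SAR(H) curves under the
standard constraints (A = 2 fixed, H-power fixed to 3, M_s from
magnetometry, viscosity encoding the dispersion condition) by bounded
Levenberg–Marquardt with multi-start.

**Calorimetry.** SAR = m·c·(dT/dt)₀ / m_Fe from the first 10 s of a
heating record, with the iron mass from the stoichiometry helpers.

## Worked example

Scalar physics from tabulated inputs:

```r
library(mnpheat)
iron_mass_fraction(stoichiometry(0.3))   # 0.6432891  (mg Fe per mg of particles)
effective_anisotropy(76.2, 31e3)         # 16017.14   (J/m^3, ~1.6e4)
```

A full study-like run — four compositions, three dispersion conditions,
5–65 kA/m at 355 kHz, 1% measurement noise:

```r
rep <- run_pipeline(synthetic_spec(42, "multiplicative", 0.01))
rep$magnetometry
#>     x    Ms D_mean_nm   sigma r_squared
#> 1 0.0 65.84     8.714 0.16203    0.9995
#> 2 0.1 78.25     8.542 0.15096    0.9994
#> 3 0.3 93.23     7.765 0.08097    0.9994
#> 4 0.5 82.63     8.165 0.08039    0.9994
rep$condition_effects
#>     x immobilization_pct alignment_pct
#> 1 0.0             -30.01         39.35
#> 2 0.1             -30.61         21.28
#> 3 0.3             -29.76         19.22
#> 4 0.5             -29.71         19.45
rep$fits[[7]]
#> Langevin-saturation SAR fit (water)
#>   D       = 18.20 nm
#>   C       = 2.876
#>   tau_N0  = 5.121e-05 s
#>   Gamma   = 8.458e+06 W/kg (at 65 kA/m)
#>   R^2     = 0.999808
```

Reading the numbers: the magnetometry stage recovers each sample's
saturation magnetization (A·m²/kg) and a mean magnetic diameter of
8–9 nm — smaller than the ~16 nm physical size, the signature of a
magnetically dead surface layer. Immobilizing the particles in a solid
matrix blocks Brown rotation and costs ~30% of the SAR in every
composition; pre-aligning them in a static field before freezing buys
back ~40% (undoped) or ~20% (zinc-doped). The SAR(H) fit on the
x = 0.3 water curve returns an 18 nm core, a field-dependence exponent
C near 3, and R² above 0.999; across all 12 curves the plateau SAR
correlates linearly with the fitted Γ (r = 0.992 here).

## Layout

- `R/` — composition, magnetometry, relaxation, SAR models,
  calorimetry, SAR fit pipeline, synthetic generators, I/O + pipeline.
- `vignettes/hyperthermia-methods.Rmd` — the models, their assumptions,
  parameter conventions and numerical choices, in detail.
- `tests/testthat/` — unit, property and end-to-end tests.
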