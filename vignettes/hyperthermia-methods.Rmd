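---
title: "Models and methods for magnetic nanoparticle heating analysis"
author: "mnpheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for magnetic nanoparticle heating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnpheat)
```

## Scope

`mnpheat` analyses magnetic fluid hyperthermia experiments on
superparamagnetic spinel-ferrite nanoparticles — in particular
zinc-substituted magnetite, Zn~x~Fe~3−x~O~4~. It covers the full chain a
hyperthermia study runs through:

1. stoichiometry and crystallography bookkeeping (iron content, EDX
   inversion, Scherrer size, cubic lattice parameter);
2. magnetometry: fitting the room-temperature magnetization branch with a
   log-normal Langevin ensemble to extract the magnetic size distribution;
3. relaxation physics: Néel and Brown relaxation times, their dependence
   on the alternating-field amplitude, and size–field regime maps;
4. heating models: the linear-response (Debye) dissipation and a
   Langevin-saturation model of the specific absorption rate, SAR(H);
5. calorimetry: SAR extraction from heating curves by the initial-slope
   method;
6. the constrained SAR = f(H) fitting pipeline across dispersion
   conditions (water, immobilized, pre-aligned), with the comparative
   statistics (condition contrasts, SAR–Γ and SAR–M~s~ regressions).

Every stage has a matching synthetic-data generator with known ground
truth, so the whole pipeline is testable without instrument data.

## Magnetization model

The superparamagnetic ensemble magnetization is

$$M(H) = M_s \int_0^\infty f_{\ln}(D; D_0, \sigma)\,
L\!\left(\xi(D, H)\right) dD + \chi H,$$

with $L(\xi)=\coth\xi - 1/\xi$ the Langevin function,
$\xi = \mu_0 M_{s,\mathrm{vol}} V_m H / k_B T$, $V_m = \pi D^3/6$, and
$f_{\ln}$ a log-normal diameter density with median $D_0$ and shape
$\sigma$. The linear term $\chi H$ absorbs paramagnetic impurities and
very fine particles. The mean magnetic diameter is
$D_\mathrm{mean} = D_0 e^{\sigma^2/2}$.

Because $\ln D$ is Gaussian, the integral is evaluated by Gauss–Hermite
quadrature in $u = \ln D$ (40 nodes by default). This is exact for
$\sigma = 0$ and accurate to better than $10^{-8}$ relative for
$\sigma \le 0.5$; a Monte-Carlo average over $10^6$ log-normal draws
agrees to 0.1% in the tests. Mass magnetization (A·m²/kg) is converted
to the volume magnetization entering $\xi$ with the particle density;
the density is never stated alongside magnetization tables in practice,
so the bulk magnetite value 5180 kg/m³ is the default — it reproduces
the tabulated effective anisotropy constants — and every function takes
it as an argument.

Fitting uses bounded Levenberg–Marquardt over
$(M_s, D_0, \sigma, \chi)$. Langevin fits have well-documented shallow
minima, so $D_0$ is initialized from the closed-form low-field slope:
$M'(0) = M_s \mu_0 M_{s,\mathrm{vol}} \langle V\rangle / 3 k_B T$ with
$\langle V \rangle = (\pi/6) D_0^3 e^{4.5\sigma^2}$, solved for $D_0$ at
a starting $\sigma = 0.1$. Only the superparamagnetic room-temperature
branch is fitted; low-temperature hysteresis loops are summarized by
scalars (coercivity, remanence, squareness $M_r/M_s$, and
$K_\mathrm{eff} = \mu_0 H_c M_{s,\mathrm{vol}}/0.96$, the
random-uniaxial-ensemble relation valid when squareness stays below
0.5).

## Relaxation times

Two mechanisms relax the magnetization: Néel rotation of the moment over
the anisotropy barrier and Brown rotation of the particle body in the
solvent. The package implements:

* zero-field times $\tau_{N0} = \tau_0 e^{\sigma_a}/2$ (with
  $\sigma_a = K V_m / k_B T$) and $\tau_{B0} = 3\eta V_h / k_B T$;
* the static escape-rate field dependence of the Néel time,
  $\tau_N^{-1}(h) = \tau_0^{-1}(1-h^2)\left[(1+h)e^{-\sigma_a(1+h)^2} +
  (1-h)e^{-\sigma_a(1-h)^2}\right]$ with $h = H/H_k$, valid for
  $h < 0.4$ and singular at $h = 1$ (enforced with a warning and an
  error respectively);
* the Fokker–Planck result for the Brown time in large AC fields,
  $\tau_B = \tau_{B0}/\sqrt{1 + 0.07\xi^2}$ (stated validity
  $\xi < 20$; a warning beyond), asymptotically $\tau_B \sim H^{-1}$;
* an empirical AC-field Néel law
  $\tau_N = \tau_{N0}/\sqrt{1 + A\xi^C}$, asymptotically
  $\tau_N \sim H^{-C/2}$ ($-1.5$ at the reference $C = 3$).

Two conventions required a decision. First, the empirical Néel law is
sometimes quoted in a form that *grows* with field,
$\tau_{N0}(1 + A\xi^C)$; relaxation of a driven superparamagnet
shortens with amplitude, and only the damped form reproduces both the
published relaxation surfaces and the $H^{-1.5}$ asymptote, so the
damped form is the default and the growing one is available as
`form = "literal"` for comparison. Second, the anisotropy field is
implemented as the dimensionally consistent
$H_k = 2K/(\mu_0 M_{s,\mathrm{vol}})$ (a common typo writes its
reciprocal); with the measured $K_\mathrm{eff}$ of 16 nm magnetite this
gives ≈ 57 kA/m, the quoted "around 60 kA/m" scale.

`relaxation_map()` evaluates both channels on a (D, H) grid. The
default Néel form for maps is the static escape-rate expression — the
form behind published size–field surfaces — with cells beyond $h = 1$
returned as `NA`. At zero field the classical picture emerges: Néel
dominates below a crossover at 15–20 nm and Brown above it. At high
amplitude the picture inverts: the Néel time falls faster with field
than the Brown time, so by ~60 kA/m the Néel channel dominates even at
35 nm. With the empirical law seeded by the Arrhenius zero-field time
this inversion cannot occur at large D (the $e^{\sigma_a}$ factor is
astronomically large there), which is why the map defaults to the
escape-rate form.

```{r relaxmap}
p <- particle_model(16e-9, shell = 2e-9, Ms_vol = 4.5e5, K = 2e4,
                    T = 300, eta = 1e-3)
relaxation_map(p, D_grid = c(10e-9, 35e-9), H_grid = c(0, 60e3))
```

## Heating models

Linear response gives the volumetric power
$P = \mu_0 \pi \chi'' f H_\mathrm{max}^2$ with the Debye out-of-phase
susceptibility $\chi'' = \chi_0 \omega\tau/(1+(\omega\tau)^2)$ and
static susceptibility
$\chi_0 = \mu_0 M_{s,\mathrm{vol}}^2 V_m / 3 k_B T$; absorption peaks
at $\omega\tau = 1$ with $\chi_0/2$.

The saturation model replaces the linear equilibrium response by the
Langevin function:

$$\mathrm{SAR}(H) = \Gamma(H)\, L(\xi)\,
\frac{\omega\tau(H)}{1 + (\omega\tau(H))^2}, \qquad
\Gamma(H) = \frac{\pi \mu_0 f H M_{s,\mathrm{vol}}}{\rho},$$

where $\tau(H)$ combines the empirical field-dependent Néel time with
the field-dependent Brown time harmonically
($\tau^{-1} = \tau_N^{-1} + \tau_B^{-1}$). $\xi$ uses the field
amplitude. Because $\Gamma \propto H$ and $L(\xi) \to \xi/3$, the model
reduces *exactly* to linear response as $\xi \to 0$ (the package tests
this to $10^{-6}$ relative), and flattens at high amplitude where the
Langevin factor saturates and $\omega\tau$ drops below 1.

A point worth stating explicitly: in the parameter regime of 17–19 nm
ferrite cores heating at 355 kHz, $\omega\tau$ starts far above 1 at
low field and sweeps through the Debye resonance as the field grows.
SAR/H² is therefore not constant below the saturation onset — it rises
to a maximum and falls. A parabola still describes the rising portion
of a 5–65 kA/m curve reasonably (and its residual degrades several-fold
once the plateau region is included), which is how the two-regime
"quadratic then saturating" description of measured curves should be
read; strict quadraticity holds only in the genuine linear-response
window $\xi \lesssim 0.3$.

Hyperthermia calculations default to 310 K (physiological);
magnetometry to 300 K. SAR is expressed per kilogram of particle mass
through the density in $\Gamma$; rescaling per kilogram of iron uses
`iron_mass_fraction()`.

## Calorimetric SAR

From a heating record T(t), `sar_from_heating_curve()` computes
$\mathrm{SAR} = m\,c\,(dT/dt)_0 / m_\mathrm{Fe}$. The initial slope is
the OLS slope over the first 10 s by default — robust to 1 Hz
quantization — with a strict two-point $\Delta T/\Delta t$ mode
available. In a non-adiabatic vessel the early slope underestimates the
adiabatic rate $P/mc$; the synthetic generator uses a single
Newton-cooling term, $T(t) = T_\mathrm{env} + (P/k)(1 - e^{-kt/mc})$,
under which the 10-s window keeps that bias below 5% at typical loss
rates. The iron mass is an explicit input: per-milligram iron contents
(e.g. 0.724 mg/mg for magnetite) refer to 1 mg of particles, while a
0.5 mL sample at 1 mg/mL holds 0.5 mg — a factor-2 ambiguity between
conventions that `iron_mass_conventions()` surfaces rather than
resolves silently; it affects only the absolute SAR scale, not field or
composition trends.

## The constrained SAR = f(H) fit

`fit_sar_curve()` fits the saturation model to a measured curve under
the conventions a constrained analysis needs to avoid
overparametrization:

* $A$ fixed (default 2); $C$ free in [1, 6];
* `h_power = "h3"`: the explicit power of H in the Néel field term is
  fixed at 3 while the non-field factors of $\xi$ carry the free
  exponent, i.e. the term is $A (\mu_0 M_{s,\mathrm{vol}} V_m / k_B
  T)^C H^3$ — the reading consistent with letting "the rest of the
  terms in ξ" vary; a strict $A\xi^C$ mode is provided and the two
  coincide at $C = 3$;
* $M_{s,\mathrm{vol}}$ fixed from the magnetometry fit;
* viscosity by condition: 1e-3 Pa·s in water, 1e100 Pa·s as a frozen-
  matrix surrogate (exactly equivalent, by construction and by test, to
  an explicit infinite Brown time);
* hydrodynamic coating 10 nm for water-condition fits;
* $\Gamma$ either free (default; reported at the 65 kA/m reference
  amplitude, scaling linearly in H inside the model) or computed from
  $\pi\mu_0 f H M_{s,\mathrm{vol}}/\rho$ (`gamma_mode = "eq9"`). A
  constant $\Gamma$ would break the low-field $H^2$ limit, which is why
  the fitted value is anchored at a reference amplitude.

Optimization is bounded Levenberg–Marquardt
(D ∈ [5, 50] nm) with five fixed starts, fitting the time parameter and
Γ on a log scale. Residuals are weighted by 1/SAR by default: the
scatter of calorimetric SAR values is multiplicative, and unweighted
residuals leave the low-field points — which pin the quadratic
regime — nearly voiceless, visibly biasing the recovered diameter on
simulated data.

The time parameter itself is, by default, the attempt time $\tau_0$,
with $\tau_{N0} = \tau_0 e^{K V_m/k_B T}/2$ tied to the fitted diameter
at the measured anisotropy constant, plus a log-normal prior
$\log_{10}\tau_0 = -9.5 \pm 0.5$ (the physical $10^{-10}$–$10^{-9}$ s
range). The prior is scaled by the residual noise estimated from a
first unpenalized pass, so it is inert on clean data — noiseless curves
are recovered to machine precision — and only acts where it is needed:
the 4-parameter likelihood has a shallow ridge along which $C \to 1$
with a zero-field Néel time of order 0.05 s, a solution incompatible
with any physical attempt time for a particle that heats at 355 kHz.
Without the prior that spurious basin captures a large minority of
noise realizations; with it, parameter recovery on simulated curves at
3% noise is unbiased to ~1% (median over 50 seeds). A free-$\tau_{N0}$
mode without the prior is retained.

Downstream statistics: `quadratic_region_fit()` (no-intercept parabola
over a low-field window, with its relative residual as the regime
diagnostic), `saturation_sar()` (plateau mean over H ≥ 50 kA/m, with
the fitted model's top-field value as an alternative),
`compare_conditions()` (signed percentage contrasts between water,
immobilized and pre-aligned), `correlate_sar_gamma()` and
`sar_vs_ms_regression()`.

## Synthetic data and what the tests show

Generators are pure functions of a `synthetic_spec` (seed, noise model,
noise level) — identical specs give identical output. Default noise is
3% multiplicative, a typical calorimetric scatter.

`gen_study_like_dataset()` emulates the structure of a four-composition
(x = 0, 0.1, 0.3, 0.5) study: the measured room-temperature saturation
magnetizations (65.9, 78.5, 93.4, 82.1 A·m²/kg) and magnetic size
distributions, three dispersion conditions, 5–65 kA/m at 355 kHz. The
water-condition shape is the saturation model for an 18 nm core
(the size regime such fits report) with $\tau_{N0}$ = 3e-5 s, C = 3,
A = 2; the immobilized shape is the same model with the Brown channel
disabled, normalized so its plateau is exactly 70% of the water plateau
(the ~30% immobilization drop); pre-alignment multiplies the
immobilized curve by exactly 1.40 for undoped magnetite and 1.20 for
zinc-doped samples. Within each condition, every sample's curve is the
condition shape scaled by its M~s~, making saturation SAR exactly
proportional to M~s~ per condition. Note that the multiplicative
condition factors scale the SAR-vs-M~s~ slope by the same factors, so
the per-condition regression lines are proportional rather than
parallel in the strict sense.

What the generator does *not* emulate: dipolar interactions and
aggregation, distributions of anisotropy, temperature drift during a
measurement, field inhomogeneity, or any instrument noise beyond the
single multiplicative/additive term. Passing recovery tests therefore
demonstrate the estimators' correctness and conditioning under the
stated noise model, not robustness to those real-data effects.

Problem sizes used by the test-suite simulation studies: 50 noise seeds
for the SAR-fit recovery study (13 field points per curve, 3%
multiplicative noise) and 50 seeds for the magnetization recovery
(50 field points, 0.5% noise); the end-to-end pipeline runs the full
12-curve, 4-magnetization-curve study at 1% noise.

## Numerical choices and degenerate inputs

* Langevin function: series $\xi/3 - \xi^3/45$ below $|\xi| < 10^{-4}$
  avoids cancellation; `1/tanh` elsewhere.
* Arrhenius exponents above 700 return `Inf` with a warning rather than
  overflowing silently.
* Harmonic combination of relaxation times passes `Inf` through (a
  disabled channel) and always returns at most the smaller input.
* Quadrature for the log-normal ensemble: Gauss–Hermite in ln D, exact
  at $\sigma = 0$.
* Relative residual weighting guards against zero SAR values by
  flooring weights at $10^{-3}$ of the curve maximum.
* Curves are sorted by field/time at construction; strictly monotone
  time and non-negative field grids are enforced there, so downstream
  code never re-validates.

## Known limitations

* The SAR model treats the pre-alignment enhancement as empirical
  scaling; no chain-anisotropy or dipolar model is attempted.
* Hysteresis-loop (Stoner–Wohlfarth) heating of ferromagnetic particles
  is out of scope; the models here assume superparamagnetism.
* The static escape-rate Néel expression is used outside its strict
  h < 0.4 validity range in maps (with warnings); cells at h ≥ 1 are
  `NA`.
* Figure digitization of published data points is out of scope; the
  pipeline consumes tabulated or synthetic curves.
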