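---
title: "Methods: characterizing nano-in-micro dry powder inhalers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing nano-in-micro dry powder inhalers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerodpi)
```

`aerodpi` implements the complete data-reduction chain used to characterize
carrier-free "nano-in-micro" dry powder inhalers (DPIs): micrometre-sized
spray-dried composite particles built from drug nanocrystals, designed so
that the micrometre geometric size targets the respiratory zone while the
embedded nanoparticles provide fast local dissolution. This vignette is the
package's account of the models behind each reduction, the parameters that
matter, and the choices made where the methods literature leaves the design
open.

## Particle size statistics

Laser diffraction reports a volume distribution through its quantiles
D[0.1], D[0.5], D[0.9] (µm). The width statistic is

$$\mathrm{Span} = \frac{D[0.9] - D[0.1]}{D[0.5]},$$

dimensionless and scale-invariant; Span below about 2 is the usual
"monodisperse enough for dosing" criterion. `span()` operates on the mean
quantiles. For replicate-resolved data a mean of per-replicate Spans is
possible and differs slightly (quantile means do not commute with the ratio);
the package reduces mean quantiles by default, so values derived from
replicate-averaged Spans in instrument reports can disagree in the second
decimal, and no attempt is made to force agreement.

The parametric stand-in for a measured distribution is the lognormal with a
*volume-median* diameter and a geometric standard deviation (GSD). Specific
surface area assumes spheres,

$$\mathrm{SSA} = \frac{6}{\rho\, D_{32}}, \qquad
  D_{32} = d_{v,50}\, e^{-\tfrac{1}{2}\ln^2\sigma_g},$$

the Hatch–Choate Sauter mean written in the volume-median convention (the
familiar count-median form multiplies by $e^{2.5\ln^2\sigma_g}$ instead). A
quadrature oracle over the lognormal number density verifies the moment
identity to 0.1% in the tests. Instrument SSA additionally reflects optical
model and particle rugosity, so measured values are matched in order of
magnitude only: for a 138 nm suspension median the spherical estimate is
around 30–40 m²/g against a measured ~44 m²/g.

## Powder rheology

From bulk ($\rho_b$) and tapped ($\rho_t$) density,

$$\mathrm{HR} = \frac{\rho_t}{\rho_b}, \qquad
  \mathrm{CI} = \frac{\rho_t - \rho_b}{\rho_t}\cdot 100,$$

linked exactly by $\mathrm{HR} = 1/(1-\mathrm{CI}/100)$. `reduce_rheology()`
offers both averaging orders for triplicates — per-replicate ratios averaged
(default, which is what instrument reports usually print) or ratio of mean
densities; for typical replicate scatter they differ below 1%.
`flowability_class()` implements the pharmacopoeial Carr scale
(≤10 excellent … 26–31 poor, 32–37 very poor, >37 very, very poor) with
boundary values assigned to the better class. Published tables occasionally
label CI values near 28 as "very poor"; the package keeps the scale and
`run_study()` flags such rows instead of replicating the label.

## Surface free energy by the Wu harmonic-mean method

A sessile drop of a probe liquid with known surface-tension split
$(\gamma_l^d, \gamma_l^p)$ obeys the Wu equation

$$(1+\cos\theta)\,\gamma_l =
  4\left[\frac{\gamma_s^d \gamma_l^d}{\gamma_s^d + \gamma_l^d}
       + \frac{\gamma_s^p \gamma_l^p}{\gamma_s^p + \gamma_l^p}\right],$$

and two liquids — water (22.6/50.2 mN/m) and diiodomethane (49.0/1.8 mN/m)
by default, overridable via `probe_liquid()` — determine the solid split
$(\gamma_s^d, \gamma_s^p)$. Derived quantities are the total
$\gamma_s = \gamma_s^d + \gamma_s^p$, polarity
$\gamma_s^p/\gamma_s \cdot 100$ and cohesion work $2\gamma_s$.

`solve_wu()` runs a damped Newton iteration on the 2×2 system with the
analytic Jacobian ($\partial/\partial\gamma_s^d$ of a harmonic term is
$4\gamma_l^{d\,2}/(\gamma_s^d+\gamma_l^d)^2$), multi-started from a coarse
grid over $[0,100]^2$ and clipped to $[0,200]^2$ mN/m, converging to
residuals below $10^{-10}$ mN/m. The map is monotone in each component, so
in practice all starts coalesce on one root; distinct roots would trigger a
warning and the smallest-residual one is returned.

A point worth noting: the forward map is only invertible on the *admissible*
set where both liquids give a real contact angle. High-energy solids are
completely wetted by water ($\cos\theta > 1$ formally), carry no angle, and
`wu_contact_angle()` refuses them; round-trip guarantees are therefore
stated, and tested, over admissible component pairs. Time-resolved angle
kinetics are out of scope — one averaged angle per liquid enters the
inversion, and replicate angles are averaged per liquid by
`surface_energy_table()`.

## Crystallinity from powder diffractograms

Residual crystallinity after milling and spray-drying is scored against a
physical mixture of the same composition: the summed areas of the drug's
characteristic reflections (9 peaks between 6.6° and 26.4° 2θ for
meloxicam; the leucine reflections are excluded), each integrated above a
linear local baseline drawn between the edges of a ±0.25° window, ratioed
sample over reference. The local baseline makes the index exactly invariant
to flat offsets; areas are clipped at zero so noise around an absent peak
cannot go negative. "Mean of the per-peak decrease" is the other defensible
reading of such an index and is available (`method = "per_peak"`); the two
agree exactly under uniform attenuation, which is also how the synthetic
generator builds its fixtures. Equal drug loading in sample and reference is
assumed — no per-mass normalization is applied.

## Dissolution and permeation

The dissolution protocol dissolves a 1.5 mg dose in 50 mL of simulated lung
medium and withdraws 5 mL at each sampling time, replenished with fresh
medium. The withdrawal dilutes every later sample, so the standard
replacement correction is applied:

$$C^{corr}_n = C_n + \frac{V_s}{V}\sum_{i<n} C_i, \qquad
  \mathrm{released}\,\% = \frac{C^{corr}_n V}{\mathrm{dose}}\cdot 100.$$

The correction is exact for ideal mixing, always non-negative, and the
synthetic generator inverts it exactly, so noiseless first-order fixtures
round-trip to their generating release curve.

Diffusion-cell permeation is reduced end-point: flux $J = m/(A t)$ over the
0.785 cm² membrane and full run duration, and permeability coefficient
$K_p = J/C_d$. The donor concentration defaults to dose over donor volume
(1500 µg / 9 mL ≈ 166.7 µg/cm³), which is correct when the donor phase fully
dissolves the dose; for a poorly soluble raw drug the donor can be
solubility-limited and $C_d$ must then be measured — `run_study()` logs this
caveat rather than guessing a solubility.

## Cascade impactor reduction

An eight-stage Andersen cascade impactor at 28.3 L/min classifies the
emitted aerosol by the calibrated cut-off diameters 9.0, 5.8, 4.7, 3.3,
2.1, 1.1, 0.7, 0.4 µm (stage 0 … stage 7, filter below 0.4). The reduction
conventions are:

* **Emitted dose** is everything leaving device and capsules — induction
  port plus stages plus filter — so mass balance
  $\mathrm{ED} + \mathrm{device} + \mathrm{capsules} = \mathrm{total}$ holds
  exactly. This reading lets a high emitted fraction coexist with a
  substantial throat deposit, as real capsule-inhaler runs show.
* **Sizing** excludes the induction port (it has no calibrated cut-off):
  the cumulative-undersize fraction at each stage cut-off counts mass on
  locations with smaller cut-offs, is non-decreasing in diameter, and equals
  the generating CDF exactly for lognormal fixtures.
* **MMAD/GSD** come from the classical log-probability plot: least squares
  of probit(fraction) on $\log_{10}$(cut-off) over points strictly inside
  (0, 1) — endpoints have no probit — with
  $\mathrm{MMAD} = 10^{-a/b}$ and $\mathrm{GSD} = 10^{1/b}$; a non-positive
  slope is a degeneracy error. On noiseless lognormal stage data the
  regression is exact, so recovery across MMAD 0.8–8 µm and GSD 1.3–3 is
  limited only by floating arithmetic; the tests assert 2%.
* **FPD** evaluates the fitted lognormal CDF at exactly 5.0 µm (not the
  4.7 µm stage-2 cut-off) times the sized mass; FPF = FPD/ED · 100. FPF and
  EF are invariant under uniform mass scaling, so per-capsule versus per-run
  accounting does not affect them.
* Cut-offs are used as calibrated; the optional $Q^{-1/2}$ rescaling for
  off-calibration flows exists but is off by default.

## Stochastic regional lung deposition

The Monte Carlo simulator tracks individual particles through a randomized,
asymmetric branching airway tree until deposition or exhalation, tallying
extrathoracic, bronchial (conducting, generations 1–16) and acinar
(generations 17–24) fates. Published whole-lung stochastic models of this
family do not print their coefficient sets, so this module implements the
model *family* with documented, configurable pieces; its contract is
internal consistency and the qualitative orderings that drive formulation
decisions, not absolute regional percentages.

**Geometry.** The shipped tree (`inst/extdata/airway_geometry.json`) has 24
generation classes with Weibel-type median diameters and lengths rescaled to
a functional residual capacity of 3300 cm³ (conducting-zone lengths ordered
monotone), lognormal inter-airway variability (GSD 1.15 bronchial, 1.10
acinar), branching angles uniform on 15–60° (0 for the trachea) and gravity
angles uniform on 0–90°. Generation $g$ carries $2^{g-1}$ parallel airways;
the air volume not in duct lumina is attributed to alveoli on the acinar
generations in proportion to airway count. A full morphometric database is
deliberately not redistributed; the JSON schema accepts any user tree.

**Transport.** Each particle draws an aerodynamic diameter from the
lognormal APSD — taken directly as (MMAD, GSD) or fitted from an impactor
run — and faces an empirical oral mouth–throat filter monotone in the
impaction parameter $d_{ae}^2 Q$, $P = x/(1+x)$ with
$x = (d_{ae}^2 Q/500)^{1.2}$ (coefficients configurable; a nasal set is
shipped but unexercised). Penetration depth follows the air-front picture:
the volumetric depth is uniform over the inhaled volume (1.7 L over 3.2 s by
default, a COPD patient on a capsule inhaler), and the residence time in a
generation is its gas volume over the flow, which reduces exactly to $L/u$
in a single tube.

**Deposition in a segment** combines three analytic single-tube
efficiencies as $1-\prod(1-P_i)$: Yeh–Schum inertial impaction
($\varepsilon = \theta\,\mathrm{Stk}$,
$P = 1 - \tfrac{2}{\pi}\cos^{-1}\varepsilon + \tfrac{1}{\pi}\sin 2\cos^{-1}\varepsilon$),
gravitational sedimentation in an inclined tube
($P = 1 - e^{-4 v_s t \cos\phi/(\pi d)}$), and Gormley–Kennedy laminar
diffusion in the $\mu = DL/Q$ parameterization. Slip correction, settling
velocity and diffusivity use body conditions (310 K, air viscosity
1.89·10⁻⁴ P, mean free path 0.0712 µm) and the unit-density
aerodynamic-diameter convention (shape factor 1). During the breath-hold,
sedimentation and the first radial diffusion mode act in still air for the
full hold duration in the terminal segment the particle reached — the
simplest defensible convention when inhalation ends mid-tree. Exhalation
retraces the same sampled path; its duration defaults to the inhalation time
(not reported for such protocols) and is configurable.

**Statistics.** Tallies are integer particle counts, so
extrathoracic + bronchial + acinar + exhaled = 100% exactly and
lung = bronchial + acinar identically. One seed drives the whole
simulation, with all random draws generated in a fixed order *before* the
walk; runs with the same seed therefore share their random numbers across
parameter changes, which makes comparisons sharp — lengthening the
breath-hold can only add deposition, particle by particle. Regional
standard errors are binomial and scale as $n^{-1/2}$; a degenerate
single-tube geometry reproduces the analytic formula within Monte Carlo
error, which is the simulator's absolute anchor.

The tests exercise the documented qualitative claims: lung deposition
non-decreasing from a 5 s to a 10 s hold, acinar exceeding bronchial
deposition for a respirable ~2 µm MMAD aerosol under the patient breathing
pattern, and extrathoracic deposition growing with MMAD.

## Synthetic data

Every reducer has a generator that is exactly its inverse model
(`generate_fixture()`), written in the same CSV/JSON schemas the readers
consume. Defaults emulate the study conditions for spray-dried leucine
formulations: volume medians 3–4.5 µm with GSD ≈ 1.7, bulk densities
0.15–0.18 g/cm³, surface-energy components in the 30–45 mN/m range, ~2 µm
MMADs, first-order release reaching 65–85% in an hour, and Gaussian noise
with the standard deviations typical of triplicate instrument reports
(0.05 µm on quantiles, 0.01 g/cm³ on densities, 0.3° on contact angles, 3%
relative on stage masses). What the generators do *not* emulate: correlated
stage biases and wall losses in an impactor, drifting baselines and peak
shifts in diffractograms, non-sink dissolution, or multimodal aerosols — so
green round-trip tests certify the reductions, not instrument realism.

## Problem sizes and numerical choices

The shipped test suite and study runs are sized for interactive use: 3
samples × 7 fixture kinds, deposition at 1.5–10 thousand particles (the
single-tube anchor uses 10⁵), 100-point Wu round-trip batches. The Wu
solver tolerance is 10⁻¹⁰ mN/m; peak integration uses the trapezoid rule on
the instrument's own 0.01° grid; probit regression drops exact 0/1 points
rather than winsorizing them; boundary Carr indices go to the better class;
ties in the Monte Carlo event sequence cannot occur (continuous uniforms).

## Known limitations

* Instrument SSA is matched qualitatively only (spheres, no rugosity).
* The deposition simulator's absolute regional fractions depend on the
  extrathoracic coefficients and geometry scaling; only orderings and
  consistency are guaranteed. Clearance, hygroscopic growth and CFD-level
  flow are out of scope.
* The Wu inversion is undefined under complete wetting; characterize
  high-energy solids with a different liquid pair.
* Raw-drug permeation runs with a solubility-limited donor need a measured
  donor concentration; the default assumes full dissolution of the dose.
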