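---
title: "Models and methods behind quenchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchkit)
```

# The measurement model

quenchkit analyses cell-by-cell fluorescence titrations: a fluorescent
host at constant total concentration $H_t$ (typically 10–20 µM), a guest
(quencher) added up to a few tens of equivalents (total $G_t$ up to a few
hundred µM), excitation at a fixed wavelength, and emission read either at
a band maximum or as an integrated band (both are accepted through the
single `F` column; provenance belongs in the series label).

Three physical processes can lower the measured intensity:

1. **Static quenching.** Ground-state 1:1 association
   $H + G \rightleftharpoons HG$ with constant
   $K = [HG]/([H][G])$ and a non-emissive complex. The emitted intensity
   is proportional to $[H]_{free}$, so
   $F_0/F = H_t/[H]_{free} = 1 + K\,[G]_{free}$: a Stern–Volmer plot with
   slope $K$. Lifetimes are unchanged — only the *amount* of free
   fluorophore drops.
2. **Dynamic (collisional) quenching.** Diffusive encounters deactivate
   the excited state: $F_0/F = \tau_0/\tau = 1 + k_q\tau_0 [Q]$. Lifetimes
   shorten in exact proportion to the steady-state loss.
3. **The inner filter effect (IFE).** If the quencher absorbs at the
   excitation wavelength, the beam is attenuated before it reaches the
   observed volume; the intensity drops with *no* excited-state or
   ground-state interaction at all. For emission collected from the centre
   of a 1 cm cell, Beer's law gives
   $F_{corr} = 10^{\Delta A \cdot d_{ex}}\, F$ with
   $\Delta A = A - A_0$ the absorbance change at the excitation wavelength
   on a 1 cm basis and $d_{ex}$ the effective excitation path. With the
   default geometry ($d_{ex} = 0.5$ cm) the familiar
   $F_{corr} = 10^{\Delta A/2} F$ results.

The package's purpose is to keep these three apart. Its core empirical
observation — reproduced on synthetic ground truth in the test suite — is
that an uncorrected IFE inflates apparent association constants
substantially at quite ordinary absorbances (a factor ~1.8 at
$\Delta A_{max} = 0.30$ under the default conditions), and can create
entirely fictitious binding for non-associating pairs.

## Geometry is a parameter, not a constant

The $\tfrac12$ in $10^{\Delta A/2}$ is a property of centre-of-cell
observation in a 1 cm cuvette, not of nature. Correction formulas valid
for other detection geometries differ, and applying the wrong one is a
recognised failure mode. `geometry()` therefore carries
`cell_path_cm`, `eff_excitation_path_cm` (default 0.5) and
`eff_emission_path_cm` (default 0.5) explicitly; the default reproduces
the centre-of-cell formula exactly, and a front-face-like worst case is
one argument away. Absorbances are *stored* normalised to 1 cm and the
geometry is applied only at correction time, so data and optics stay
separable.

The emission-side factor $10^{\Delta A_{em}\, d_{em}}$ is implemented
(`correct_emission_ife()`) but off by default: the excitation side
dominates when quenchers absorb near the excitation wavelength, and
emission-side screening is reported separately with a warning flag
instead.

# Estimators

## 1:1 speciation

$[HG]$ is the smaller root of
$K x^2 - (K(H_t+G_t)+1)x + K H_t G_t = 0$, evaluated as
$2c/(b + \sqrt{b^2-4ac})$ to avoid cancellation at both the weak- and
strong-binding ends. The tests pin it against an independent 200-step
bisection on the mass-balance residual over a grid of 1000 random cases
spanning $K \in [10^{-3}, 10^{8}]$ M⁻¹ and totals in
$[10^{-8}, 10^{-2}]$ M (agreement to 1e-9 relative), and check the exact
limits $K=0$ and $K\to\infty$.

## Stern–Volmer fits

`stern_volmer_fit()` regresses $F_0/F$ on guest concentration. Choices
that matter:

- **Intercept fixed at 1** by default: the plot passes through
  $F_0/F = 1$ by construction. The free-intercept option exists as a
  systematic-error diagnostic (a miscalibrated reference shows up as an
  intercept offset), not as the default estimator.
- **Total vs free guest.** The x-axis is the *added* (total) guest by
  default, which is what titration plots normally show and is accurate
  when host ≪ guest. At host 10 µM the early points (guest a few tens of
  µM) bind away a few percent of the guest, biasing the slope low by
  ~2–3%; the `refine_free_guest` flag iterates the fit with
  $[G]_{free}$ from the speciation solver, which removes this bias
  exactly for the static 1:1 model. The parameter-recovery checks in the
  acceptance tests use the refined fit for precisely this reason: the
  study design (host 10 µM, guest from 0) is not deep in the
  host-≪-guest regime at its first points.
- **Curvature flag.** Uncorrected IFE data bend upward (the ratio grows
  like $10^{\Delta A/2}$, super-linear in $[Q]$ when $\Delta A$ is
  linear in $[Q]$). A nested-model F-test (linear vs + quadratic term,
  $\alpha = 0.05$, a single test per series) sets `curvature_flag`;
  fits that are exact to numerical noise skip the test, since an F-test
  on round-off residuals is meaningless. Truncating high-concentration
  points is available only as an explicit `max_points` argument and is
  always logged — never silent.
- **Significance of the slope** is reported as a one-sided p-value and
  consumed by the workflow (below).

## Global absorbance fit

`global_absorbance_fit()` re-implements the standard spectrophotometric
global analysis: predicted absorbance
$\varepsilon_H[H] + \varepsilon_G[G] + \varepsilon_{HG}[HG]$ at every
wavelength and titration point, with speciation from the exact solver.
For fixed $K$ the problem is linear in $\varepsilon_{HG}(\lambda)$, which
is profiled out per wavelength under a non-negativity clamp; $K$ itself is
searched on a $\log_{10}$ scale (coarse 56-point grid over
$[10^{-3}, 10^{8}]$ M⁻¹, then local refinement), which both conditions the
problem and enforces $K \ge 0$ by parameterisation. Two safeguards:

- `identifiable = FALSE` when the best fit's binding signal
  $\max|A_{pred}(\hat K) - A_{pred}(0)|$ is below 3× the residual rms —
  when $\varepsilon_{HG} \approx \varepsilon_H + \varepsilon_G$ the
  spectra simply carry no binding information and any $K$ is an artifact
  of noise.
- `classify_association()` separates `statistical` ($K < 1$ M⁻¹ or not
  significantly $> 0$), `weak`, and `stable` ($K \ge 100$ M⁻¹ and
  significant). The thresholds are policy, exposed as arguments; the
  sub-0.1 M⁻¹ regime typical of non-binding pairs falls squarely into
  `statistical` with large margin.

## TCSPC reconvolution fitting

Decays are modelled as $\sum_i a_i e^{-t/\tau_i}$ (1–3 components)
convolved with a unit-area IRF (delta, Gaussian, or measured histogram;
an optional colour shift displaces the IRF by interpolation). Fitting
minimises the Poisson-weighted chi-square with variance
$\max(y, 1)$ — the standard TCSPC weighting; the max() guard keeps
zero-count channels from having infinite weight. Numerical choices:

- **Variable projection.** For trial lifetimes, the amplitudes (and
  optional background) solve a ≤ 4-column non-negative weighted linear
  problem exactly (active-set elimination); only the log-lifetimes are
  searched nonlinearly (golden-section for one component, Nelder–Mead
  otherwise). This halves the nonlinear dimension and is robust to the
  close-lying lifetimes expected from heterogeneous supramolecular
  emitters.
- **Multi-start.** Five starts with lifetimes log-spaced over
  [channel width, 10× record length] guard against local minima;
  non-convergence after multi-start is an error, not a silent result.
- **Degeneracy.** Lifetimes agreeing within 1% raise a collapse warning;
  `select_n_exp()` offers an F-test between nested orders
  ($\alpha = 0.05$) as a helper, deliberately not automatic — model
  order is a judgement call made by inspecting fits.
- The fit window starts at the peak channel by default (configurable),
  and the record length should be matched to the decay: very long
  all-but-empty tails bias the Poisson-weighted reduced chi-square low.
  The validation suite uses 1024 channels × 0.05 ns (51.2 ns records)
  for lifetimes of 2–8 ns and peak counts of 10⁴, where the reduced
  chi-square of a correct model is centred on 1.0.
- Parameter covariance comes from the Gauss–Newton approximation
  $(J^T W J)^{-1}$ at the optimum. A known limitation of observed-count
  weighting is a small downward bias of lifetimes, about 0.35% at these
  count levels — negligible against the 3–5% recovery tolerances, and it
  cancels in comparisons *between* fits of equal design.

Averages follow the two standard definitions
$\langle\tau\rangle_{amp} = \sum a_i\tau_i/\sum a_i$ and
$\langle\tau\rangle_{int} = \sum a_i\tau_i^2/\sum a_i\tau_i$; the
single-component case returns $\tau$ for both exactly, and a one-ulp
guard enforces the Cauchy–Schwarz inequality
$\langle\tau\rangle_{int} \ge \langle\tau\rangle_{amp}$ against floating-
point round-off when lifetimes nearly coincide.

## Lifetime invariance: static vs dynamic

`assess_lifetime_invariance()` answers "did the decay change when
quencher was added?" with two calibrated tests:

- **Dynamic trend:** $\tau_0/\tau - 1$ regressed through the origin on
  $[Q]$, weighted by the ratio variance propagated from each fit's
  lifetime standard errors — a z-test that remains calibrated even with
  only two nonzero quencher levels, where a residual-based t-test (1
  degree of freedom) is nearly powerless. A significantly positive slope
  (one-sided $\alpha = 10^{-3}$) is the dynamic verdict, and the slope
  itself estimates $k_q\tau_0$.
- **Invariance:** a Cochran-Q heterogeneity chi-square per parameter
  (each lifetime and amplitude fraction) across all quencher levels,
  summed, with the reference treated as one level among the others.
  An earlier design compared each level to the zero-quencher fit at
  $k\sigma$; that statistic is miscalibrated, because the comparisons
  share the reference's noise (we measured a ~2× inflation of its
  nominal tail probability), and its familywise false-alarm rate grows
  with every parameter and level compared. The joint Q-test at
  $\alpha = 10^{-3}$ keeps the false-"inconclusive" rate at the level
  its nominal size states. The per-parameter maximum deviation (in
  combined-sigma units, default report threshold $k = 3$) is still
  reported as a diagnostic.

# The sequential diagnosis

`run_quenching_workflow()` chains the stages and applies, in order:

1. corrected slope **not** significantly positive while the uncorrected
   one is → `no_quenching_ife_artifact`;
2. corrected slope significantly positive and lifetimes invariant →
   `static_quenching` (if no decays were measured, diffusional quenching
   is discounted — with a mandatory logged caveat — only when the
   quencher never exceeds 1 mM, where diffusion-limited quenching of
   nanosecond emitters is unobservably small);
3. lifetimes dynamic and the corrected steady-state slope matching
   $k_q\tau_0$ within 25% → `dynamic_quenching`;
4. otherwise `mixed_or_inconclusive`.

"Significantly positive" uses a one-sided $\alpha = 10^{-3}$ throughout:
the null screen is run on every titration, and a loose threshold would
flag spurious binding in a few percent of clean replicates. The
redesign branches of the screen (change excitation wavelength, shorter
path cell) are emitted as textual recommendations, never automated. All
thresholds are echoed in the report for auditability, and the report is
deterministic given the input series.

# What the simulator emulates — and what it does not

`simulation_scenario()` encodes the study conditions: constant host
(default scenarios use 10 µM), guest to 300 µM including the mandatory
zero-guest reference, 1:1 static quenching with a fully quenched complex
(`complex_emissive_fraction = 0`), guest absorbance at the excitation
wavelength (the default recovery scenario uses
$\varepsilon_G = 1000$ M⁻¹cm⁻¹, i.e. $\Delta A$ rising linearly to
0.30 AU — a realistic mid-range value for nitroaromatic quenchers at
typical naphthalene/pyrene excitation wavelengths), multiplicative
Gaussian noise on F (1% s.d.) and
value-proportional Gaussian noise on A (0.2% s.d.), both typical
instrument repeatabilities. The simulator *applies* the excitation
attenuation $10^{-\Delta A_{ex} d_{ex}}$ that the correction removes, so
correction + simulation compose to the identity on noiseless data
(verified to 1e-12). The emission-side filter and a complexation-induced
host absorbance change are options, off by default. TCSPC scenarios draw
independent Poisson counts around the reconvolved model scaled to a
target peak count (default 10⁴).

Passing tests on these data demonstrate *estimator* correctness —
unbiased recovery, calibrated uncertainties, correct decision logic —
under the stated noise model. They do not certify real-instrument
effects the generator deliberately omits: wavelength-dependent detector
response, scattering and reabsorption of emitted photons, IRF drift and
colour shift (simulated only via the shift parameter), dead-time pile-up
distortion of TCSPC statistics, dilution errors in cumulative-addition
titrations, or photobleaching drifts of the reference intensity.

Seeding: every scenario carries one integer seed; replicate suites derive
per-replicate seeds by offsetting it. Simulators save and restore the
caller's RNG state, so they are reproducible without side effects.

# Problem sizes and determinism of the validation suite

The suite validates with 12-point titrations, 100-replicate recovery runs
(1% noise; mean recovered $K$ within 5% of the 3000 M⁻¹ ground truth),
1000-case equilibrium property grids, 1024-channel decay fits at 10⁴
peak counts, and 20-seed verdict sweeps for each canonical workflow
scenario (IFE artifact, static, dynamic) — sizes chosen so that each
stage's claim is tested at meaningful statistical resolution while the
whole suite stays fast enough to run on every change. All stochastic
tests use fixed seeds, making every reported outcome reproducible
bit-for-bit.

# Known limitations

- Only 1:1 stoichiometry; no 1:2/2:1 models, Job plots, or global
  multi-wavelength *fluorescence* fitting.
- The static-quenching estimator assumes a non-emissive complex by
  default; an emissive fraction is a simulator option but not a fit
  parameter of `stern_volmer_fit()`.
- No ray-tracing of beam/detection volumes: the geometry model is the
  effective-path abstraction, which is exactly right for centre-of-cell
  observation and only approximate otherwise.
- Decay analysis fits each histogram independently — no global linked-
  lifetime analysis, lifetime distributions, or anisotropy.
- Readers accept delimited text only (comma/tab/semicolon, decimal
  point); proprietary instrument formats and wavelength-resolved emission
  matrices are out of scope.
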