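---
title: "Models, numerics and design choices in nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

`nmrdyn` implements a complete quantitative workflow for characterizing a
protein's backbone dynamics across timescales — ¹⁵N relaxation and
Lipari–Szabo model-free analysis (ps–ns), CPMG relaxation dispersion
(µs–ms), amide hydrogen exchange (seconds–days) — together with
chemical-shift perturbation mapping and ligand-affinity determination from
circular-dichroism thermal shifts. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Configuration and physical constants

All stages share one configuration object, `nmr_config()`. Temperatures
are Kelvin internally (°C only at file boundaries), energies kcal/mol
throughout, R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹. The spin-physics defaults
are a 600.0 MHz ¹H frequency (¹⁵N at 0.101329118 of it), an N–H bond
length of 1.02 Å and a ¹⁵N CSA of −160 ppm. The bond length and CSA are
not directly measurable in this kind of study and published analyses use
values in the ranges 1.02 ± 0.02 Å and −160 to −172 ppm; the defaults here
were chosen because together they reproduce the rigid-rotor transverse
rates expected for a ~24 kDa monomer tumbling with τ_m,eff ≈ 14.5 ns at
this field (21–21.5 s⁻¹ for an NH parallel to the unique axis, 19.7–20 s⁻¹
perpendicular). Both are configurable, and `spin_physics()` always
recomputes the dipolar and CSA interaction constants from the current
configuration rather than caching them.

Every fitting stage takes its random seed and Monte-Carlo replicate count
from the configuration, and `serialize_results()` embeds the whole
configuration (seed included) in every report, so reports are
self-describing.

## ps–ns dynamics

**Rate fitting.** ¹⁵N R₁ and R₂ come from the classical two-parameter
single exponential I(t) = I₀e^(−Rt) fitted by Levenberg–Marquardt with a
log-linear starting guess; an offset variant exists but is off by default,
because constant-time peak-height decays have no baseline term. When
per-point errors are absent they are estimated from a duplicated delay
(the replicate is carried through the readers for exactly this purpose) or
from the RMS residual; fits with per-point errors are weighted and their
covariance standard errors are reported without the residual-variance
rescaling that `nls` applies (the errors are known, not estimated).
A fitted rate indistinguishable from zero is flagged, never silently
dropped: all exclusions in this package are explicit flags.

**Diffusion tensor.** The tensor is estimated from R₂/R₁ of a rigid
subset: residues with NOE < 0.65 are removed first (fast internal motion),
then R₂/R₁ outliers beyond 1.5 SD of the median are trimmed once
(exchange-broadened R₂). R₂/R₁ is used because the I₀ and S² dependences
largely cancel, so rigid amides can be treated as S² = 1 during the tensor
fit. The axial fit minimizes χ² over (τ_m,eff, D_ratio, θ, φ) with a
10 × 10 orientation multi-start grid followed by Nelder–Mead refinement;
the isotropic model is a 1-D optimization. Axial vs isotropic is decided
by an F-test at α = 0.05 on the χ² reduction (3 extra parameters).
Parameter uncertainties and the joint (τ_m,eff, D_ratio) confidence region
come from seeded Monte-Carlo resampling of the observed ratios, refit
warm-started from the estimate; `tensor_ci_contains()` tests membership of
the joint 95% region via the Mahalanobis distance under the Monte-Carlo
covariance. In recovery studies the trimming step slightly clips the
orientation extremes of the rigid set, which biases D_ratio a few percent
toward 1; this is inherent to the rigid-subset R₂/R₁ method rather than to
the optimizer.

**Model-free fits.** Each residue's (R₁, R₂, NOE) triple is fitted under
the fixed tensor with the five standard parameterizations: S²; S², τe;
S², R_ex; S², τe, R_ex; and the two-timescale form (S_f², S_s², τ_s) with
S² = S_f²·S_s². Model selection uses AIC = χ² + 2k. The small-sample AICc
correction was considered and rejected on arithmetic grounds: with n = 3
observables per residue the correction term 2k(k+1)/(n−k−1) is undefined
at k = 2 and negative-denominator at k = 3, so AICc simply does not exist
for most of the candidate set at single-field data. Ties within numerical
noise go to the model with fewer parameters. The optimizer is L-BFGS-B
with per-model `parscale` (τe lives near 10⁻¹⁰ s while R_ex lives near
1–10 s⁻¹; without scaling the gradient steps are dominated by one
parameter) and a small multi-start grid. S² is clamped to [0, 1] with a
boundary flag, and uncertainties come from 200 seeded Monte-Carlo
resamples of the observables, warm-started, for the selected model only.
R_ex is defined at the reference field and is not field-scaled — this is a
single-field analysis.

## µs–ms exchange

R₂,eff(ν) = −ln(I(ν)/I₀)/T_relax with T_relax = 50 ms by default;
uncertainties propagate as σ_I/(I·T_relax), with the duplicated 480 Hz
point supplying the fractional error when explicit errors are absent.

The closed-form model is the all-timescale two-site expression

R₂,eff(ν) = R₂⁰ + p_a p_b Δω² k_ex / (k_ex² + √(p_a² Δω⁴ + 144/τ_cp⁴)).

The τ_cp convention deserves a note, because the constant under the root
changes meaning with it. This package defines ν_cpmg as the echo rate
(τ_cp = 1/(2ν_cpmg) is the interval between the centres of successive
180° pulses), implements the numerical Bloch–McConnell propagator
`bloch_mcconnell_r2eff()` under exactly that convention (τ–180–2τ–180–τ
cycles, integer cycles filling T_relax, R₂,eff from the end-point
magnetization of the major state, exact to numerical tolerance and
cross-checked against an independent matrix-exponential implementation),
and keeps the constant and convention isolated in `model_r2eff()`. Against
the propagator, this reading tracks R₂,eff within about 6% at
representative intermediate-exchange parameters (p_b ≈ 0.07,
k_ex ≈ 420 s⁻¹, Δω ≈ 2 ppm) and within about 12% in the worst corners of
the slow-to-intermediate regime; alternative constant readings trade
pointwise agreement against the bias of exchange parameters recovered by
fitting the closed form to exact data (a variant with a 4/3-larger
constant is pointwise tighter but biases fitted k_ex by over 20%). The
adopted convention keeps the k_ex recovered from propagator-generated
profiles within 15% of truth at the cluster conditions used throughout.
Since the closed form is an approximation, the propagator — not the model —
is the reference in tests.

Individual profiles are compared flat-vs-exchange by an F-test at
α = 0.05, with the exchange fit multi-started over k_ex ∈ [100, 5000] s⁻¹
and p_b ∈ [0.01, 0.3]. Cluster fits share (k_ex, p_b) across user-supplied
residue groups (the package never invents clusters) with per-member
(Δω, R₂⁰). The joint optimization is parameterized in well-conditioned
units — log k_ex, logit p_b, Δω in ppm — and started from a coarse grid
over the shared pair with exact inner per-member fits, then refined
jointly (Nelder–Mead, then BFGS). Uncertainties: 200 seeded Monte-Carlo
replicates refit warm-started. Reported p_b ± σ may straddle zero; no
truncation is applied to uncertainties. Members flagged as overlapped
cross-peaks are excluded with a log entry.

## Amide exchange and EX2 thermodynamics

Slow H/D decays are fitted with the three-parameter model
I(t) = I(∞) + A·e^(−kt). Censoring produces bounds, never point
estimates: intensities at the noise floor from the first spectrum yield
`too_fast` with a lower bound on k from the dead time (1800 s default);
decays indistinguishable from noise over the window (the early-vs-late
mean difference below 3σ) yield `too_slow` with an upper bound
−ln(1−3σ_frac)/window. CLEANEX build-ups are fitted for (k, R_1A,app) with
the apparent water relaxation rate R_1B,app held fixed at 0.6 s⁻¹ — a
previously determined constant treated as configuration, never fitted.

Intrinsic rates use the poly-DL-alanine reference scale with the published
side-chain correction factors (shipped as a commented CSV under
`inst/extdata/` with its provenance header), acid/base/water catalysis
terms, Arrhenius temperature corrections (14/17/19 kcal/mol), and
pD = pH_read + 0.4 in D₂O by default (a flag disables it). Charge states
are those dominant near neutral pH; His titration is not modelled, and the
H₂O medium reuses the reference rates with the H₂O ionization constant —
both documented simplifications appropriate for protection factors read on
a log scale. Protection results enforce the EX2 identities exactly:
P_f = k_int/k_obs, K_op = P_f⁻¹, ΔG_op = RT ln P_f,
P_op = K_op/(1+K_op), and censored rates propagate to one-sided bounds on
all derived quantities. EX2 is an assumption of the analysis (single-pH
study) and is recorded as such in every output.

## Chemical-shift mapping

CSD = √(Δδ_H² + (w·Δδ_N)²) with w the ratio of the spectral widths of the
two dimensions in ppm by default (fixed weights in the common 0.10–0.20
range can be supplied instead; the weight used is always recorded).
Significance is mean + 1 SD over the computed set, recomputed
deterministically from the supplied residues only; a median + MAD variant
is available behind a flag for outlier-heavy maps. When all CSDs are
equal the SD is zero and the threshold degenerates to the mean, flagging
everything — the degenerate case is documented rather than special-cased.

## Thermal-shift binding

Melts are fitted with the two-state signal model
y(T) = (y_F + y_U·K)/(1+K), K = exp(−ΔG°u(T)/RT), linear baselines, and
Gibbs–Helmholtz ΔG°u(T) = ΔH°u(1−T/T°) + ΔC°p[(T−T°) − T ln(T/T°)].
Melt fits hold ΔC°p fixed at 0 by default — over the ±10–15 K window a
melt constrains, ΔC°p and the baselines are strongly confounded, and the
zero-ΔC°p convention is the one under which the fitted (T°, ΔH°) reproduce
a measured unfolding free energy at 25 °C. The K_d pathway instead uses
the ΔC°p estimated from the slope of ΔH°u(T°) across the ligand series,
as the linkage protocol prescribes; both choices are tagged in reports.
ΔΔG°u,L is evaluated at the apo midpoint (where the apo term vanishes),
and K_d comes from a one-parameter weighted least squares in log₁₀K_d of
ΔΔG°u,L = RT ln(1 + [L]free/K_d), with [L]free the physical root of the
binding quadratic — the stoichiometric regime, since protein and ligand
concentrations (µM) are comparable to K_d. The assumption that the ligand
does not bind the denatured state is what equates ΔΔG°u,L with the binding
free energy; it is recorded in the fit object. An all-nonpositive ΔΔG
series returns a `no_binding` verdict rather than a K_d.

## Structure utilities

The inertia frame is computed from the mass-weighted inertia tensor
(standard atomic masses by default, unit masses for geometry-only axes),
with axes ordered by ascending moment and a right-handed frame enforced.
α angles are folded to [0°, 90°]: every spectral-density coefficient
depends on cos²α, so the fold loses nothing for the dynamics model while
removing a sign ambiguity. Ensemble RMSD-to-mean superposes each model
onto an iteratively refined mean structure (Kabsch rotations; convergence
when the mean moves < 10⁻⁶ Å, with a 10-round cap); an averaged-pairwise
variant is available because the two conventions are both in common use
and differ systematically (to-mean is smaller by roughly √2 for large
ensembles). RMSF is the per-atom RMS deviation from the time-mean
position, averaged over the backbone atoms of each residue.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, on the standard
experimental schedules: the 13-point R₁ (0–1000 ms) and R₂ (0–490 ms)
delay grids, the 80–1000 Hz CPMG grid with its duplicated 480 Hz point,
the 0–200 ms CLEANEX mixing grid, H/D sampling from the 1800 s dead time
out to 4 days, and 10–90 °C melts at 1 °C steps. Noise is multiplicative
Gaussian on intensities — the dominant noise mode for peak heights — with
an optional absolute floor for censoring tests; melt noise is Gaussian
relative to the baseline span. Every dataset returns its ground truth
alongside, and recovery tests compare against that sidecar, never against
hard-coded numbers. All generators are bit-reproducible under a fixed
seed.

Deliberately not emulated: peak overlap and lineshape effects, spectral
artifacts, temperature drift within an experiment, EX1/EXX exchange
kinetics, scan-rate-dependent (kinetic) unfolding, and aggregation.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated for well-resolved, two-state, EX2-regime
data at a single field — not that real spectra free of those artifacts
will fit equally well.

Default generator parameters are the study conditions: an axial tensor
with τ_m,eff = 14.5 ns and D_ratio = 1.15 at 600 MHz; dispersion clusters
at (p_b, k_ex) of (0.07, 420 s⁻¹) and (0.15, 590 s⁻¹) with per-residue Δω
drawn from 1–3 ppm (the per-residue values are a preset assumption — real
Δω sets are not published); melts at T° = 54.0 °C, ΔH°u = 106.5 kcal/mol,
[P_T] = 6 µM with ligand ratios 0.5–5 and K_d = 3.08 µM; 2% intensity
noise for relaxation and dispersion, 5% for melts.

## Problem sizes and runtime

The test suite runs recovery studies at sizes chosen to make the
statistics meaningful while keeping the default run to a few minutes:
150 synthetic amides for tensor recovery (with 100 Monte-Carlo replicates
for the joint confidence region), 8-member dispersion clusters with
100–200 replicates, 30-residue model-free bias studies, 100–200-repeat
Monte-Carlo checks for the scalar fits. The acceptance script uses the
same sizes.

## Known limitations

Single-field data cannot separate R_ex from CSA-like contributions or
constrain Δω and p_b independently in individual dispersion fits (hence
the cluster analysis); rhombic diffusion tensors, R₁ρ dispersion,
multi-field global fits, EX1 analysis and three-state unfolding are out of
scope. The closed-form dispersion model carries the approximation error
quantified above; analyses that need better than ~10% accuracy in R₂,eff
should fit the numerical propagator directly.
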