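# nmrdyn

Protein backbone dynamics span timescales from picoseconds to days, and no
single experiment sees all of them. `nmrdyn` is an R toolkit for the
quantitative analyses that stitch those windows together for a single
protein studied by solution NMR and circular dichroism:

- **ps–ns motions** — fit ¹⁵N R₁/R₂ single-exponential peak-height decays
  and the {¹H}-¹⁵N heteronuclear NOE; estimate the global rotational
  diffusion tensor (isotropic or axially symmetric) from R₂/R₁ of rigid
  amides; fit per-residue Lipari–Szabo model-free parameters
  (S², τe, R_ex, two-timescale) under that tensor.
- **µs–ms exchange** — convert constant-time CPMG intensities to
  R₂,eff(ν_cpmg) dispersion profiles, fit the Ishima–Torchia all-timescale
  two-site model per residue and per user-defined cluster (shared k_ex and
  p_b), and validate the closed form against a numerical Bloch–McConnell
  propagator.
- **seconds–days opening** — fit slow H/D exchange decays and fast
  CLEANEX-PM build-ups, predict intrinsic (random-coil) exchange rates from
  the sequence, and convert to protection factors and EX2 opening
  thermodynamics (ΔG_op, open-state populations), with explicit censoring
  for amides that exchange within the dead time or not at all over days.
- **binding** — weighted ¹H/¹⁵N chemical-shift displacement mapping with a
  mean + 1 SD significance threshold, and ligand affinity from CD thermal
  shifts: two-state van't Hoff melt fits, ΔC°p from the ΔH°(T°) slope,
  ΔΔG°u,L at the apo midpoint, and a stoichiometric-regime K_d fit.
- **geometry** — inertia-frame placement of a structure, NH-vector α angles
  to the diffusion axis, ensemble RMSD-to-mean (iterative Kabsch
  superposition) and per-residue RMSF.

A seeded synthetic-data generator emulates every input the pipeline
consumes — decay tables on the standard delay schedules, dispersion
profiles with the repeated 480 Hz control point, HX/CLEANEX curves, melt
series with ligand-linked stability shifts — so every stage is testable by
parameter recovery against known ground truth, without any external data.

## The models in brief

Global tumbling enters through the axially symmetric spectral density

J(ω) = (2/5) Σₖ Aₖ(α) [ S² τₖ/(1+(ωτₖ)²) + (1−S²) τ′ₖ/(1+(ωτ′ₖ)²) ],

with τ₁ = (6D⊥)⁻¹, τ₂ = (D∥+5D⊥)⁻¹, τ₃ = (4D∥+2D⊥)⁻¹ and the usual
orientation weights Aₖ(α); R₁, R₂ and NOE follow from the standard dipolar
+ CSA expressions. Two-site exchange contributes

R₂,eff(ν) = R₂⁰ + p_a p_b Δω² k_ex / (k_ex² + √(p_a²Δω⁴ + 144/τ_cp⁴)),
τ_cp = 1/(2ν_cpmg),

and amide opening obeys P_f = k_int/k_obs, ΔG_op = RT ln P_f under EX2.
Thermal shifts use Gibbs–Helmholtz ΔG°u(T) with ligand linkage
ΔΔG°u,L = RT ln(1 + [L]free/K_d), [L]free from the binding quadratic.

## Worked example: cluster analysis of CPMG dispersion

Simulate eight residues sharing one exchange process (p_b = 0.07,
k_ex = 420 s⁻¹, per-residue Δω between 1 and 3 ppm) on the standard
80–1000 Hz field grid, then fit the cluster with shared (k_ex, p_b):

```r
library(nmrdyn)
cfg <- nmr_config(seed = 42, mc_replicates = 100)
set.seed(42)
sim <- gen_dispersion_dataset(residues = 101:108, p_b = 0.07, k_ex = 420,
                              dw_ppm = runif(8, 1, 3), r2_0 = 15,
                              noise = 0.02, config = cfg, seed = 42)
profiles <- lapply(sim$series, r2eff_profile, i0 = sim$i0,
                   t_relax = sim$t_relax)
fit <- fit_cluster(profiles, cfg)
fit
#> CPMG cluster fit: 8 member(s)
#>   k_ex = 419.5 +/- 30.8 s^-1
#>   p_b  = 0.0698 +/- 0.0033
#>   reduced chi^2 = 0.965
head(fit$members, 3)
#>   residue   dw_rad dw_ppm dw_rad_sd   r2_0 r2_0_sd   r_ex
#> 1     101 1067.832  2.795    23.197 15.015   0.113 25.109
#> 2     102 1101.698  2.884    21.296 15.090   0.129 25.327
#> 3     103  600.257  1.571     9.321 14.943   0.103 19.197
```

The shared parameters come back within one standard deviation of the
generating truth; the per-member Δω (here in rad/s and ppm at the ¹⁵N
frequency) and exchange-free R₂⁰ are determined individually, and `r_ex`
is the zero-field dispersion amplitude each residue would show. All
uncertainties are seeded Monte-Carlo estimates, and the seed is recorded
in the fit object and in every serialized report.

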