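---
title: "Constitutive models and recoil analysis for an elongating embryonic epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive models and recoil analysis for an elongating embryonic epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirheo)
```

## The problem

During Drosophila dorsal closure the dorsal epidermis elongates steadily for
hours — roughly from 60 to 90 µm at about 0.2 µm/min — while being pulled by
the contracting amnioserosa. A purely elastic (Kelvin-Voigt) tissue cannot do
this: under constant traction it stretches for a few characteristic times
τ and then plateaus, and when the traction is released (laser ablation) it
recoils all the way back. The observed behavior — sustained linear
elongation, fast (≈ 5 min) retraction, and cells that keep most of their
elongation after tension release — points instead to a *viscoplastic*
tissue that converts stretch into new rest length. In embryos lacking early
DPP/BMP signaling (*tkv* mutants) the plastic component is missing and the
tissue behaves like a simple viscoelastic solid.

`epirheo` implements the 1-D rheology needed to make that argument
quantitative: three constitutive models with closed-form creep-and-recovery
solutions, a brute-force numerical integrator to check them, exponential
recoil fitting with the standard ablation proxies, the
recoil-ratio-versus-length regression that discriminates the three material
classes, and a seeded synthetic-data generator that emulates the study's
measurement structure so every stage is testable without data downloads.

## The three models

All models describe the length `L(t)` (µm) of a chain of `n0` identical
units under a constant traction σ that may be released at `t_release`.
Only ratios of the mechanical constants are identifiable from length data,
so the canonical parameters are:

| parameter | meaning | unit | control default |
|---|---|---|---|
| `l0` | rest length of one unit | µm | 0.05 (tissue), 0.3 (cell) |
| `n0` | initial unit count | — | 400 (tissue), 20 (cell) |
| `stretch` | steady elastic stretch per unit, σ/k | µm | 0.10 (tissue), 0.1 (cell) |
| `tau` | viscoelastic time η_KV/k | min | 5 |
| `period` | polymerization period p = l0·η_M/σ | min | 0.75 (tissue); ∞ = no plasticity |

**Kelvin-Voigt** (spring ∥ dashpot): `σ = k(l − l0) + η_KV dl/dt`, so under
traction `L(t) = n0·l0 + n0·(σ/k)(1 − e^{−t/τ})` and after release the
stretch decays with the same τ and nothing is retained.

**Maxwell/Kelvin-Voigt** (series dashpot added): the same traction drives a
linear flow `(σ/η_M)·t` on top of the elastic transient; the flow
(`l_deform = (σ/η_M)·t_release`) is permanent. In the ratio
parameterization the flow rate is `l0/period`.

**Ratchet polymerization**: new Kelvin-Voigt units are appended once per
period p while traction lasts,

```
L(t) = n0·l0 + n0·(σ/k)(1 − e^{−t/τ}) + Σ_{i=1..⌊t/p⌋} [ l0 + (σ/k)(1 − e^{−(t−i·p)/τ}) ]
```

so the rest length itself grows: after release the count freezes and
`⌊t_release/p⌋·l0` is kept. Unit addition is deterministic with floor
semantics (a unit appears exactly at each multiple of p, inclusive); the
derivative discontinuities this creates are part of the printed model, and
the asymptotic elongation rate is `(l0 + stretch)/p` — each period adds one
unit that eventually carries both its rest length and its stretch.

The recoil ratio (recoil over pre-ablation length, for release times well
beyond τ) is the discrimination statistic:

* Kelvin-Voigt: `1 − n0·l0/L` — increases with length;
* Maxwell/KV: `n0·(σ/k)/L` — decreases with length;
* ratchet: `(σ/k)/(l0 + σ/k)` — constant (25% when stretch = l0/3).

## Numerical choices

The closed forms are the implementation; `integrate_numeric()` is an
independent check, not a fallback. It advances the linear relaxation ODE
between breakpoints (release time, unit additions, output times) with
fixed-step classical RK4 substeps of at most τ/200, applying unit additions
as exact `+l0` jumps; this keeps it an auditable explicit scheme while
agreeing with the closed forms to better than 1e-6 relative (1e-4 near
addition instants). The output grid must resolve the dynamics (spacing at
most τ/50 and p/20); coarser grids are refused rather than silently
integrated. Unit-count arithmetic uses an epsilon-guarded floor so that
exact multiples of p are inclusive despite floating-point division. The
geometric sum over added units is evaluated in closed form anchored at the
most recent addition, so long simulations neither loop nor overflow.

`fit_exponential_recoil()` initializes from the curve itself (rest from the
tail mean, stretch from the head-minus-tail, τ from the 63%-drop time,
clamped into bounds) and uses Levenberg-Marquardt with a small multi-start
over τ guesses; τ is bounded by 10× the observation window. A curve whose
apparent drop is below `noise_floor` (default 1e-3 µm) is flagged
"no-recoil" instead of fitted; non-convergence is an explicit error, never
a silent default. The five-parameter logistic uses the form
`y = lower + (upper − lower)/(1 + 10^{b(xmid − x)})^s`; its maximum
absolute slope has the closed form
`(upper − lower)·|b|·ln10/(1 + 1/s)^{s+1}` at `x = xmid + log10(s)/b`,
which reduces to the symmetric 4PL inflection at `s = 1`. The tests check
this closed form against numerical 1-D maximization of the analytic
derivative.

Classification in `recoil_ratio_regression()` uses a two-sided t test on
the OLS slope of ratio on length at a configurable α (default 0.05):
significantly positive → elastic-increasing, significantly negative →
maxwell-decreasing, otherwise plastic-constant. The original analysis
compared genotypes by ANCOVA; a per-dataset slope test is the natural
single-sample analogue and is the documented divergence. Records with
negative recoil (cells longer after "relaxation", the signature of an
ectopic wound-healing constriction) are flagged and excluded, never
silently dropped.

## What the synthetic data emulate — and what they do not

`make_preset()` exposes the study conditions at two scales, because the
printed constants do not reconcile into one parameter set: at tissue scale
the elastic amplitude is 40 µm on a 60-µm tissue (ratio 2/3), while at
cell scale the constant 25% recoil ratio forces stretch = l0/3. We keep
both as separate presets rather than forcing consistency.

* **Tissue scale** (trajectories): the control preset is a ratchet of 400
  units whose aggregate carries the canonical constants — rest 20 µm,
  amplitude 40 µm, τ = 5 min, slope 0.2 µm/min, equilibrated onset 60 µm.
  The fine discretization (0.15 µm per unit, p = 0.75 min) makes the
  staircase negligible against the 0.5 µm measurement noise. The tkv
  preset is a pure Kelvin-Voigt with the same τ and unit size, per-unit
  stretch 1.3× control (stress is higher in the mutant) and fewer units
  (no plastic growth before closure), so it sits near 60 µm and stays
  flat.
* **Cell scale** (ablations): 20 units of 0.3 µm. Control cells differ by
  plastic history (unit count 20–40, release just before the next
  addition so every unit is settled); tkv cells by a per-cell traction
  scale drawn in [0.2, 1] of the full stretch, spanning the observed
  25→50% ratio range and guaranteeing the ≥ 1.5-fold length span the
  regression requires; Maxwell cells by a per-cell flow time (60–300 min
  at 0.06 µm/min). The per-cell stretch is deliberately *not* given the
  lognormal inter-embryo cv: traction heterogeneity would make longer
  cells proportionally more stretched, a real confound that masquerades
  as elasticity — in these models, each class's length variation comes
  from its own mechanism.

Dispersion defaults are ours, not printed values: additive Gaussian length
noise sd 0.5 µm (small against the 40 µm signal, visible in fits),
lognormal cv 0.15 on stretch and τ across embryos, ratio noise sd 0.02.
The 150-min closure duration is a calibration so that 60 µm + 0.2 µm/min
reproduces the printed 90 µm endpoint. Trajectories start *equilibrated*
by default (a burn-in of 20τ, rounded to a whole number of periods,
re-anchored at the onset length): the observed closure-phase elongation is
linear because the elastic transient happened earlier, during germ-band
retraction; `equilibrate = FALSE` exposes the transient instead.

Passing tests on these data show that the inference machinery is correct
and well-powered under the assumed noise structure. They do not show that
real embryos satisfy the assumptions: real measurements have segmentation
error that is neither additive nor Gaussian, cells are mechanically
coupled rather than independent, traction is pulsatile rather than
constant, and unit addition — if it is the right microscopic picture — is
surely stochastic, not periodic. The deterministic ratchet is the printed
model, and we implement exactly that.

## Design choices where the source was open

* Whether the intermediate Maxwell/KV model was ever fitted to data is not
  stated; we implement it purely as the discrimination alternative, with a
  demo preset strong enough (flow 0.06 µm/min) for a 30-cell dataset to
  detect its falling ratio at the default noise.
* The long-release approximation `L_stretch ≈ (σ/k)(n0 + ⌊t_release/p⌋)`
  drops partial-relaxation terms for recently added units; we treat it as
  the t_release ≫ τ limit. The exact decomposition is always available
  from `release_decomposition()`, and `simulate_ablation()` warns when
  t_release < τ.
* Exponential fits act on length-versus-time; displacement series are
  accepted as an offset convention (the rest level is then the residual
  offset).
* Seconds (ablation movies) are converted to minutes at the ingest
  boundary; everything internal is µm and min.

## Problem sizes

The test suite and the acceptance script run simulations sized to the
study: 20–30 cells or curves per dataset, 50 datasets per class for the
discrimination benchmark, 10 replicate seeds for recovery, 300-min
trajectories on 0.5-min grids. The full suite completes in well under a
minute on one CPU.

## Known limitations

1-D only: no tissue geometry, no eggshell curvature, no active
amnioserosa dynamics. Deterministic unit addition (see above). The
aggregate Kelvin-Voigt treatment of a chain is exact only because units
are identical; heterogeneous units would need the numeric route. The
discrimination test assumes independent records; clustered (per-embryo)
dependence would widen the true slope error beyond the reported SE.
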