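---
title: "Methods: committee active learning and MD infrared spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: committee active learning and MD infrared spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdirspec)
```

# Overview

`mdirspec` implements, at desk scale, the full loop by which machine-learned
force fields are trained for, and then used in, gas-phase infrared (IR)
spectroscopy of small H/C/N/O molecules:

1. an **analytic oracle** — a bonded force field with exact energies, analytic
   forces and a point-charge dipole surface — plays the role a first-principles
   labeller plays in production workflows;
2. **normal-mode sampling** around each relaxed structure builds an initial
   training set;
3. a **committee of surrogate potentials** is trained on it, and
   **active learning** iteratively extends the dataset with the most
   force-uncertain frames visited by committee-driven molecular dynamics (MD)
   at 300, 500 and 700 K;
4. **Langevin MD** with committee-averaged forces produces dipole
   trajectories, from which the IR spectrum follows as the Fourier transform
   of the dipole time-derivative autocorrelation function (ACF);
5. spectra are compared with Pearson correlation (PCC) and the 1-D
   Wasserstein distance (WD).

Everything below states the models, the conventions and the genuinely open
design choices, in that order of importance. All empirical claims made here
are the ones the test suite and `scripts/acceptance.R` compute.

# Units

Internally everything is Angstrom / femtosecond / electronvolt / amu / Debye.
A single constants table (`unit_constants()`) carries the derived factors,
computed once from SI definitions: the acceleration factor
eV Å⁻¹ amu⁻¹ → Å fs⁻² (≈ 9.6485 × 10⁻³), Boltzmann's constant in eV/K,
e·Å → Debye (≈ 4.8032), and rad/fs → cm⁻¹. The reference stretch used
throughout — a harmonic bond with k = 1 eV/Å² between two 1-amu atoms — has

$$\tilde\nu = \frac{1}{2\pi c}\sqrt{k/\mu} \approx 737.47\ \mathrm{cm^{-1}},
\qquad \mu = 0.5\ \mathrm{amu}.$$

# The analytic oracle

A `surrogate_molecule` is a connected bond graph with

* bond terms, Morse \(D_e(1-e^{-a(r-r_0)})^2\) by default (anharmonicity is
  the point of MD-based spectra; harmonic bonds are retained for closed-form
  tests),
* harmonic angle terms \(\tfrac12 k_\theta(\theta-\theta_0)^2\), and
* fixed zero-sum partial charges giving the dipole
  \(\mu = \sum_i q_i (r_i - r_{\mathrm{COM}})\) in Debye.

Forces are analytic; `finite_difference_check()` guards them against central
differences (≤ 10⁻⁵ eV/Å on all sampled configurations). Energies and
dipoles are translation invariant and rotation covariant by construction.

**What the generator emulates.** `make_surrogate_suite()` draws randomized
molecules of 2–6 atoms: a heavy-atom tree (C/N/O, valences 4/3/2) with an
occasional ring, hydrogens on spare valence, Morse parameters
D\(_e\) ∈ [2.5, 5] eV, a ∈ [1.6, 2.4] Å⁻¹, r₀ within 3% of tabulated bond
lengths, angle constants 2–5 eV/rad², θ₀ near tetrahedral, and
electronegativity-ordered charges. Each reference geometry is relaxed by
BFGS (the optimizer a practitioner would use) to max|F| < 10⁻³ eV/Å — the
meV/Å convergence scale of structure optimizers. These ranges were fixed
once, as what this field would call realistic for single-bonded organics
(stretches roughly 700–3000 cm⁻¹), and are not tuned per experiment.
Compositions within one suite are kept distinct: two different force fields
over the same element multiset would be indistinguishable to any
geometry-only regressor, which is a property of the synthetic setup, not of
real chemistry.

**What it does not emulate.** Fixed charges carry no charge flux, so
intensity transfer between modes (e.g. IR activation by charge
rearrangement) is absent; there are no torsions, non-bonded terms or
reactive events. Passing tests therefore demonstrate the *machinery* —
sampling, learning, dynamics, spectroscopy — on a smooth anharmonic
potential-energy and dipole surface, not fidelity to any real molecule.

# Normal-mode analysis and the initial dataset

The Hessian is built from central differences of analytic forces
(step 10⁻³ Å) and symmetrized; the mass-weighted eigenproblem gives
frequencies \(\tilde\nu = \omega/2\pi c\), with negative eigenvalues
reported as negative wavenumbers and entering error metrics by absolute
value (so the metric stays defined for slightly unconverged minima).
Modes with |ν̃| < 5 cm⁻¹ are classified rigid — well below any bonded-mode
frequency of the surrogates. Reported per-mode reduced masses follow the
quantum-chemistry convention \(\mu_m = 1/\sum_i l_{im}^2\),
\(l = M^{-1/2}q\).

Initial training data samples each vibrational mode sinusoidally with the
amplitude at which the maximum harmonic potential energy equals
\(k_B T_{\mathrm{ref}}\) (T_ref = 300 K), keeping the first 10 of 31 phases
per mode. Both knobs are configurable; 31 (odd) is used because an even
phase count puts pairs of phases symmetrically about the quarter-cycle and
returns literally duplicate geometries. Sampled energies stay within
\(k_B T_{\mathrm{ref}}\) plus a 10% anharmonic allowance.

The double-harmonic stick spectrum (`harmonic_ir()`) places mode m at
\(\tilde\nu_m\) with intensity \(\propto |d\mu/dQ_m|^2\) via central
differences of the dipole along the mass-weighted mode.

# The reference potential and its committee

The pluggable `PotentialModel` contract is: fit on labelled samples, predict
energy and forces. The bundled reference implementation is a kernel ridge
regression on a permutation-invariant descriptor:

* **descriptor** d(x): inverse interatomic distances, sorted descending
  within each element-pair class;
* **model** \(E(x) = \bar y + \sum_m \alpha_m\,
  e^{-\|d - d_m\|^2/2\sigma^2}\);
* **fit**: energies *and* forces enter a weighted ridge least squares —
  forces are linear in α through the analytic chain-rule gradient, so force
  labels just add design rows. Fitting forces is what makes the model's
  gradients (hence MD and Hessians) quantitative; a fit on energies alone
  interpolates energies beautifully while its gradients at ray-sampled data
  are unconstrained.
* **hyperparameters**: σ defaults to the median pairwise descriptor
  distance of the training block; ridge λ = 10⁻⁶; force weight 1. The model
  partitions internally by element composition (one kernel block per
  composition); a pooled cross-composition kernel on padded descriptors is
  badly conditioned and was rejected. Externally trained potentials (e.g.
  message-passing networks) plug in through the same calculator contract.

**Committee.** M = 3 members by default, with two diversity mechanisms:

1. *Seeded bootstrap resamples*, realized as multiplicity weights: every
   sample remains a kernel center, its residual weight is its bootstrap
   draw count. (Dropping non-drawn samples entirely made members disagree
   so strongly near minima — where forces are small and the relative force
   error denominators tiny — that the sanity abort fired immediately; the
   weighted form keeps members tight where data is dense and diverse where
   it is sparse.)
2. *Support-gated randomized linear priors*. A kernel committee has a
   structural blind spot: far from the data the kernel decays and every
   member's forces go to the same limit (zero), so the disagreement
   collapses exactly where the model knows least — the opposite of a
   neural ensemble, whose members diverge off-manifold through their random
   initializations. Each member therefore carries a fixed random linear
   trend in descriptor space (slope scale `prior_scale` = 2 × the robust
   label spread per descriptor unit; drawn once from the member seed, never
   fitted) multiplied by one minus a support gate
   \(s = e^{-q_{\min}/2(8\sigma)^2}\), where \(q_{\min}\) is the squared
   descriptor distance to the nearest training point. Inside the data and
   through the few-σ halo that exploration MD visits, the gate is closed
   and the committee behaves exactly like a pure kernel ensemble (fit
   quality, acquisition ranking and the abort statistic are untouched);
   in the genuinely unexplored region each member reverts to its own
   slope, and the force disagreement at twice-stretched geometries exceeds
   its on-manifold value severalfold. Joint or residual *fitting* of such
   a linear term was tried and rejected: letting a global trend compete
   with the kernel inside the manifold visibly degraded the fitted
   Hessians.

Member prediction spread uses the population standard deviation, so two
members predicting F and −F report a spread of exactly |F|.

Committee statistics:

* `committee_predict()` — mean energy/forces, per-atom component spread;
* `relative_force_error()` — \(\sqrt{\overline{\mathrm{Var}\,F}}\,/\,
  (\mathrm{RMS}\,\bar F + \varepsilon)\), ε = 10⁻³ eV/Å; committee MD aborts
  when it exceeds 0.5;
* `frame_uncertainty()` — max over atoms of the per-atom spread norm
  (acquisition should react to the worst-described atom; RMS aggregation is
  available).

**Dipole model.** Per-atom effective charges are ridge-regressed from local
atomic descriptors (element one-hot plus per-element inverse-distance and
exponential neighbour sums) against the labelled dipole vectors; predicted
charges are recentred to zero sum, so \(\hat\mu = \sum_i \hat q_i r_i\) is
exactly translation invariant. Identical atoms in identical environments
necessarily receive identical charges — a symmetric homonuclear diatomic
with opposite oracle charges is unlearnable by construction, which is why
dipole-model tests use heteronuclear systems.

# Langevin dynamics

`run_md()` integrates BAOAB-split Langevin dynamics: at friction 0 it
reduces to velocity Verlet (total-energy drift < 10⁻⁵ eV over 10⁴ steps on
the reference diatomic), and at friction 0.01 fs⁻¹ (the friction unit is
fs⁻¹ — stated prominently because it changes the dynamics) it holds the
time-averaged kinetic temperature within 5% of the 300 K set-point over
50 ps. Velocities initialize from a seeded Maxwell–Boltzmann draw with the
centre-of-mass momentum removed. Frames record every `record_every` steps
(count ⌊n/record⌋ + 1); the final frame carries velocities, and
`continue_md()` with `seed = NULL` continues the thermostat noise stream so
a 5 ps + 5 ps continuation reproduces a single seeded 10 ps run bit for
bit. Aborted runs refuse continuation and must be re-seeded explicitly.

**Rotation-free dynamics.** For an isolated molecule the Langevin noise
continuously pumps angular momentum. A one-bond rotor with 1-amu atoms has
a thermal rotational frequency of order 170 cm⁻¹ at 300 K: its vibrational
line is split into rotational P/R branches several hundred cm⁻¹ wide and
the far-IR rotational band dominates the spectrum — real classical physics,
but it buries the band positions the analytic checks target.
`md_settings(remove_rotation = TRUE)` projects rigid-body rotation and
translation out of the velocities after each thermostat step (pseudo-inverse
of the inertia tensor, so linear molecules are handled); the diatomic
spectroscopy tests use it, production polyatomic runs need not. The
production protocol defaults are 5 ps thermalization + 50 ps production,
three trajectories with consecutive velocity seeds, averaged with a
standard-deviation band. Reference (oracle-driven) trajectories use the same
Langevin thermostat as the model-driven ones; thermostat identity is
immaterial to any property tested here.

# IR spectra

For a dipole series μ(t) sampled every dt:

1. μ̇ by central differences, endpoints dropped;
2. ACF of μ̇ by the Wiener–Khinchin route: FFT of the zero-padded signal,
   squared modulus, inverse FFT — the biased (1/N) estimator, truncated at a
   correlation depth of 1000 fs (2000 lags at dt = 0.5 fs). Biased rather
   than unbiased: the 1/(N−t) correction amplifies the noisy ACF tail
   exactly where the window should suppress it. The FFT path equals a
   direct O(N²) lag sum to < 10⁻¹⁰ relative error;
3. Hann window over the ACF support, zero-padding to the next power of two
   ≥ 16× the depth (a ≈ 2 cm⁻¹ cosmetic grid; padding interpolates and adds
   no information), real-FFT magnitude, frequency axis in cm⁻¹.

The ACF is not normalized at lag 0, so relative band intensities within a
spectrum are preserved; absolute cross-sections are out of scope. No quantum
or harmonic correction factor is applied to the classical spectrum. With
depth 1000 fs the Hann main lobe is ~100 cm⁻¹ wide, and the Langevin
friction contributes a ~50 cm⁻¹ Lorentzian width; both broaden
symmetrically, so band *positions* remain sharp — the harmonic reference
diatomic peaks within 2 grid bins (≈ 4 cm⁻¹) of 737.47 cm⁻¹ under the full
5 + 50 ps protocol. The Morse diatomic (D_e = 0.5 eV, a = 1 Å⁻¹, same
harmonic limit) red-shifts by roughly 20 cm⁻¹ at 300 K and substantially
more at 700 K, the classic anharmonic temperature trend.

# Spectral comparison

`compare_spectra(a, b)` regrids the "theoretical" spectrum a onto the
"experimental" grid of b by linear interpolation (zeros with a warning
outside the support), optionally baseline-corrects b, and reports

* **PCC** on the raw regridded intensities (the statistic is
  scale invariant, so no normalization is imposed), and
* **WD** between the two spectra normalized to unit mass over the
  wavenumber axis — the 1-D optimal transport distance, computed exactly as
  the L1 distance between inverse CDFs on merged quantile levels. Two unit
  point masses 50 cm⁻¹ apart give WD = 50; a 10 cm⁻¹ shift of a single band
  transports by ≈ 10 cm⁻¹.

Baseline correction is asymmetric least squares (sparse second-difference
penalty, λ = 10⁵, asymmetry p = 0.01, 10 reweighting iterations) — a
standard automated method adopted as the documented stand-in, with both
knobs exposed. Only the input designated experimental is corrected by
default.

# Test-set construction

Per molecule: a 300 K MD trajectory; uniform subsampling (evenly spaced
indices including first and last); a 2-body structural descriptor
(Gaussian-broadened histograms of inverse pairwise distances on a 32-bin
grid over 0–1.6 Å⁻¹, σ = 0.05 Å⁻¹, one channel per element pair — 3-body
terms were omitted as the 2-body channels already separate the surrogate
conformations); k-means with k-means++ seeding (`stats::kmeans` behind a
seeded initializer) into 5 clusters; 4 random picks per cluster → 20
structures per molecule, 480 over a 24-molecule suite. The transferability
variant keeps k = 5 with 10 per cluster → 50 per molecule, 400 over 8
molecules. Features enter k-means unstandardized (configurable). The
protocol lengths are 100 ps / 2000 frames; desk-scale runs shrink MD length
and subsample count proportionally (the bundled checks use 1–2 ps and
100–400 frames), which leaves every selection count unchanged.

# Active learning

Iteration 1 trains the committee on the initial dataset (80:20
per-molecule split, seeded). Each later iteration:

1. continues the per-(molecule, temperature) restart trajectories for the
   exploration time with committee-mean forces and the 0.5 sanity abort;
2. ranks recorded frames by `frame_uncertainty` (ties → earlier frame) and
   labels the top 5 per temperature with the oracle (content-hash
   deduplication; no temporal-spacing constraint is enforced — a possible
   redundancy source, accepted);
3. re-splits, retrains all members from scratch with fresh seeds
   (seed_base + 0…M−1);
4. evaluates the harmonic-frequency MAE of the *first* member against the
   oracle frequencies at the oracle minima (the first member, not an
   ensemble average, is the documented stopping statistic; configurable).

The loop stops below 5 cm⁻¹ or at 40 iterations. After an abort, the
restart frame for that temperature is re-seeded from the last valid frame
with fresh velocities. Held-out energy/force RMSEs are recorded
retrospectively each iteration. Batch scheduling across molecules is plain
sequential execution; parallel scheduling would not change any result.

**Desk-scale study conditions.** The bundled convergence study runs 8
surrogate molecules of 2–4 atoms, 0.5 ps exploration per temperature per
iteration, 10 iterations, 3 base seeds — sizes chosen once so the full
suite exercises every stage in minutes on one CPU. Under these conditions
the median-over-seeds harmonic MAE of the first member falls from roughly
500 cm⁻¹ after the initial fit to roughly 300 cm⁻¹ at the final iteration.
The absolute level reflects the deliberately compact reference regressor;
the *decrease* is the property asserted. Iteration-to-iteration
fluctuations are real: retraining from scratch resamples the bootstrap
weights, and acquisition occasionally labels frames high on the repulsive
wall.

# Numerical choices and degenerate inputs

* Hessian step 10⁻³ Å; dipole-derivative step 10⁻³ Å√amu; finite-difference
  guards at 10⁻⁴ Å.
* Kernel solves go through the normal equations with ridge 10⁻⁶; a singular
  system raises an error suggesting a larger ridge.
* Ties in acquisition break to the earlier frame; k-means selection with an
  undersized cluster takes all members and flags the selection.
* Degenerate inputs error early and specifically: empty extended-XYZ
  writes, duplicate spectrum abscissae, fewer than 5 training samples,
  single-spectrum averaging, zero-mass distributions, aborted-trajectory
  continuation.
* Every stochastic operation takes an explicit seed; nothing reads implicit
  global randomness (helpers save and restore the caller's RNG state).

# Known limitations

* The oracle's fixed charges cannot produce charge-flux intensity effects;
  IR intensities test only the geometric dipole mechanism.
* The reference regressor keys on element composition; distinct systems
  sharing a composition must be fitted separately (the bundled generator
  avoids the collision by construction).
* Classical spectra: no quantum nuclear effects, by design.
* The committee uncertainty of a kernel model is structurally different
  from a neural ensemble's; the linear extrapolation term restores growth
  off the manifold but the absolute uncertainty scale is not calibrated.
* Absolute IR intensities are arbitrary units throughout.
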