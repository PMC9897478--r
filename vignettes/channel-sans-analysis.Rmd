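---
title: "Methods: SANS prediction, fitting, and structural dynamics of pentameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SANS prediction, fitting, and structural dynamics of pentameric channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsans)
```

This vignette is the package's account of its own methods: the models it
implements, the parameters that matter and their defaults, the numerical
choices behind them, what the synthetic generator does and does not
emulate, and the known limitations. It states no result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A monodisperse solution of a rigid particle scatters neutrons with the
orientation-averaged (Debye) intensity

$$I(Q) \;=\; \sum_{i,j} \Delta b_i\,\Delta b_j\,
  \frac{\sin(Q r_{ij})}{Q r_{ij}},
  \qquad Q = \frac{4\pi}{\lambda}\sin\theta ,$$

with $d = 2\pi/Q$ connecting momentum transfer to real-space distance.
The physical content is entirely in the excess scattering lengths
$\Delta b_i = b_i + n_{\mathrm H} b_{\mathrm H} + n_{\mathrm D} b_{\mathrm D}
- \rho_{\mathrm{solv}} v_i$: coherent scattering length of the heavy atom,
its attached hydrogens (assigned from per-residue templates, since
deposited models lack explicit H), and the displaced solvent.

### Contrast model and its parameters

`contrast_model()` exposes the experimentally meaningful knobs:

* `d2o_fraction` (unitless, default 1): solvent D₂O fraction. The solvent
  scattering length density interpolates linearly between H₂O
  (−0.056 fm Å⁻³) and D₂O (+0.64 fm Å⁻³) using a 29.9 Å³ water volume.
* `exchanged_fraction` (unitless, default 0.90): the fraction of
  solvent-exposed labile (N/O/S-bound) hydrogens replaced by deuterium.
  A single uniform fraction replaces residue-resolved exchange kinetics;
  0.90 is a reasonable expectation for a protein that has spent on the
  order of 100 min in D₂O buffer near pH 7.5. Carbon-bound hydrogens
  never exchange.
* `shielded_selection`: a selection (typically the transmembrane region,
  residue ranges or a z-slab) whose labile hydrogens are kept as ¹H —
  lipid- or detergent-buried amides exchange far too slowly to matter on
  chromatography timescales. The user supplies the membrane span; the
  package does not attempt membrane positioning itself.
* `b_table`, `volume_table`: editable per-element coherent scattering
  lengths (Sears values, fm) and displaced volumes (Fraser–Traub-style
  group volumes for H/C/N/O/S/P, ionic volumes for common counterions,
  Å³). Atom volumes include their attached hydrogens.

Side-chain carboxylates (Asp/Glu) carry no labile hydrogen — they are
deprotonated at neutral pH — and histidine is counted as the neutral
single N–H tautomer. Unknown residues contribute geometry but zero labile
hydrogens, with a warning. Match-out deuterated detergent is treated as
invisible (zero excess contrast); there is no micelle model.

### Histogram-accelerated Debye sum

`debye_curve()` replaces the $O(N^2 N_Q)$ double sum by a weighted
pair-distance histogram (default `bin_width` 0.5 Å, compiled code),
evaluating the kernel once per occupied bin. Two refinements make the
default bin width essentially exact: the kernel is evaluated at each
bin's *weighted mean* distance (removing the first-order binning error),
and a second-order term $\tfrac12\,\mathrm{var}_b\,Q^2\,
\mathrm{sinc}''(Q\bar r_b)$ uses the within-bin distance variance. The
test suite pins the residual error against a pure-R exact double sum at
below 0.2% (observed ≈ 5×10⁻⁶) on 300-atom clusters for Q ≤ 0.5 Å⁻¹, and
the identity $I(0) = (\sum_i \Delta b_i)^2$ holds to 10⁻⁹. The atomic
self-term $\sum_i \Delta b_i^2$ is always added exactly. The default
model grid is 120 log-spaced points on 0.005–0.35 Å⁻¹. No instrument
resolution smearing is applied; curves are treated as desmeared.

## Guinier analysis and the window question

`guinier_fit()` fits $\ln I$ against $Q^2$ by weighted least squares over
the largest low-Q window satisfying $Q_{\max} R_g \le$ `qrg_limit`,
iterating window and fit to self-consistency (converged when Rg moves
< 0.1%). On an exactly Gaussian curve the recovery is exact to machine
precision.

The window bound deserves care. The classical $qR_g \le 1.3$ is a bias /
variance compromise for noisy data on globular particles. For a
multi-domain particle with peripheral lobes the systematic truncation
bias at 1.3 is about 1% (low); at 0.8 it drops below 0.4%. The package
therefore defaults to 1.3 for experimental curves — where point noise
dominates and a wide window is needed — but the consistency checks
between Guinier-of-a-noiseless-model-curve and the coordinate-space
$R_g = \sqrt{\sum w_i |r_i - \bar r|^2 / \sum w_i}$ (excess-b weighted)
use 0.8, where the comparison is meaningful at the 0.5% level. Both
conventions are exposed; reports print coordinate and Guinier values side
by side since printed literature values can follow either.

## Molecular weight from forward scattering

On absolute scale (cm⁻¹), $M = I(0) N_A / (c\,\Delta b_m^2)$ with
concentration $c$ in g cm⁻³ and $\Delta b_m$ the excess scattering length
per unit mass (cm g⁻¹) computed from the sequence composition under the
contrast model (`contrast_summary()`). Sequence masses use standard
residue weights plus one water per chain. The estimate inherits the
concentration uncertainty linearly, which in practice dominates (±10% is
typical).

## Pair distributions: model side and data side

`model_pddf()` histograms all pair distances weighted by
$\Delta b_i \Delta b_j$ (default `dr` 1 Å); its forward transform
(`pddf_to_curve()`) shares the per-bin mean/variance machinery with
`debye_curve()`, so the two routes agree to 0.5% — an internal
cross-oracle the tests exercise.

`ift()` inverts a measured curve into $p(r)$ on $[0, d_{\max}]$ (default
100 bins) by minimizing $\chi^2 + \alpha \|\Delta^2 p\|^2$ subject to
$p \ge 0$ with both endpoint bins pinned to zero. Numerical choices:

* **Non-negativity** is enforced by an exact active-set (Lawson–Hanson)
  solve of the regularized normal equations. A first-order projected
  descent was tried first and abandoned: on the near-singular systems
  that arise at small α it converges so slowly that the α-selection saw
  arbitrarily bad solutions. The active-set method returns the exact
  constrained optimum at this problem size (≤ ~200 unknowns) in
  milliseconds.
* **Choosing α**: a 25-point log-spaced grid scaled by
  $\mathrm{tr}(A^TA)/\mathrm{tr}(D^TD)$ is scanned; the corner of the
  χ²-vs-smoothness trade-off is located as the *largest α whose χ² stays
  within 10% + 0.05 of the grid minimum* — the point where the flat
  branch of the L-curve begins to bend. This deterministic rule replaces
  Bayesian evidence maximization used by reference tools; it is simpler,
  reproducible, and (the tests show) recovers sphere distributions with
  peak-position error under one bin. Results can differ from
  evidence-based tools in the strength of smoothing, not in the
  recovered geometry.
* A ridge floor of $10^{-12}\,\overline{\mathrm{diag}(A^TA)}$ keeps the
  system positive definite at α → 0.
* Warnings flag $d_{\max}$ outside the information limits of the
  measured Q range ($\pi/q_{\max}$, $2\pi/q_{\min}$).

$d_{\max}$ itself is soft: distributions vanish smoothly at their support
edge, so underestimates of ~5–10% still fit noisy data. The tests
estimate it by scanning candidate values and taking the smallest one on
the χ² plateau, which lands within 5% for spheres at the 0.05% noise
level; at 1% noise the data genuinely cannot distinguish 55 from 60 Å
support for a 60 Å sphere.

Comparisons between distributions (`compare_pddf()`) interpolate onto a
common grid, normalize to unit area (display normalization in the
literature varies, so area-one is the only safe common currency), and
report the L1 distance plus the area fraction beyond a threshold
(default 100 Å) — the long-distance tail that peripheral-domain extension
inflates.

## Fitting model curves to data

`fit_scale_background()` solves the 2×2 weighted normal equations for
intensity scale and constant background analytically — no iteration, no
starting values — and reports the reduced χ² with $N-2$ degrees of
freedom. The model is linearly interpolated onto the data grid. χ² is
invariant under joint rescaling of data and uncertainties, and the
calibration closure (fit the generating model to its own simulated
measurement) averages χ² = 1.00 over 20 seeds in the tests. Because no
hydration-shell term is fitted (reference tools add one), χ² values
against real data are expected to track published ones only within a few
tens of percent.

## Pore profiles

`pore_profile()` implements the probe-sphere convention: at each slice
along the channel axis, the pore radius is the maximum over probe centers
$c$ in the slice plane of $\min_i(|c - x_i| - r^{\mathrm{vdW}}_i)$. The
search is a multi-start Nelder–Mead (8 starts, one on the axis, the rest
uniformly jittered; fixed RNG seed, so profiles are deterministic),
constrained to `max_offaxis` (default 6 Å) and clipped at a bulk cutoff
(default 12 Å); slices with no atoms in reach report the cutoff and are
flagged. Radii are Bondi van der Waals values without united-atom
corrections (heavy-atom structures). Defaults: 0.5 Å slice spacing.
`atom_subset = "backbone"` reproduces backbone-only traces. The z origin
is placed by `anchor_selection`, conventionally the Cα ring of the 9′
gate residue, matching the prime-notation convention for pore-lining
positions (z = 0 at 9′). On an exact cylinder lattice the profiler is
accurate to machine precision; against other tools subtle objective
differences (probe path continuity, united-atom radii) mean published
radii should be compared within ±0.5 Å.

The axis comes from `channel_axis()`: the leading inertia eigenvector of
a Cα selection (refused when the inertia tensor is near-spherical, ratio
< 1.2, in favor of the two-selection COM-line method), oriented by an
extracellular selection or, absent one, by a deterministic sign rule.

## Trajectories, ranking and landscapes

Trajectories are multi-model PDB or XYZ frame series (binary formats are
out of scope; the tested path is text). RMSD uses Kabsch superposition
(SVD with determinant correction, verified against a brute-force
quaternion-grid oracle); RMSF aligns per frame then averages fluctuations
per residue. `domain_track()` reports each domain's center of mass in
cylindrical coordinates $(r_{xy}, z)$ about an axis recomputed per frame
from a core selection (default) or held fixed — both conventions exist in
the literature and differ when the core itself drifts.

`rank_frames_by_sans()` predicts a curve per frame and fits it to the
data; rows sort by ascending reduced χ², ties within 0.01 keeping input
order. The ranking is invariant to common rescaling of the data. The
planted-recovery experiment (`planted_recovery_experiment()`) formalizes
the package's central claim: with two of five peripheral lobes displaced
10 Å out and 8 Å down, a 1%-noise curve suffices to pick that conformer
(or a neighbor within 2 Å in every lobe COM) out of 50 candidates — 20/20
seeded repeats in the acceptance run.

`pca_landscape()` performs unweighted Cartesian PCA on superposed
selected coordinates (alignment reference: frame 1 of the first
trajectory; covariance by SVD of the centered frame matrix, so
rank-deficient cases keep their zero eigenvalues). Whether to
mass-weight conformational PCA is a genuinely open convention; the
implementation is unweighted with a `weights` hook, since for Cα-level
analyses the difference is cosmetic. Projections of new structures are
centered on the stored mean after superposition onto the stored
reference, making them invariant to rigid pre-transformation.

## The synthetic system: what it emulates, what it does not

`build_toy_channel()` generates a C5-symmetric pseudo-atomic channel:
four helix-like rods per subunit (TMD), an annular blob (ECD), and two
spherical peripheral lobes per subunit (NTD1-like at larger radius,
NTD2-like above it). Defaults were chosen once to mirror the scale of a
real pLGIC with peripheral domains — 2,540 pseudo-atoms, Rg 50.7 Å, dmax
158.6 Å — and are not tuned per test. One seeded subunit template is
replicated by exact rotation, so symmetry holds to machine precision.
Uniform unit scattering weights are the default (geometry tests need no
contrast realism); `mode = "alanine"` attaches alanine-like residue
records so the full contrast model can run on toy geometry.

`lobe_walk_trajectory()` moves each lobe's center through a reflected
mean-reverting random walk in (radial, axial) displacement — per-frame
step SDs default to 2.5 Å for NTD1 (both coordinates) and 0.8/2.0 Å
radial/axial for NTD2, reversion 0.08 per frame, reflecting bounds
(−8, +25) Å radially and (−20, +12) Å axially — mobile NTD1, z-dominated
NTD2, excursions that return. Without bounds the stationary SD is
$\sigma/\sqrt{1-(1-\kappa)^2}$, which the tests verify by simulation.
`simulate_sans()` adds Gaussian noise with
$\sigma_k = f I_k + \sqrt{I_k I_0}/E$ (relative floor $f$ = 0.01,
exposure scale $E$ = 500), reporting the generating σ in the curve — so
χ² calibration is exact by construction, as a correctly reduced
experimental curve's would be.

What the toy does *not* emulate: real secondary structure and side-chain
packing (so absolute χ² levels against real curves are not comparable),
residue-realistic contrast variation, the detergent belt, instrument
smearing, inter-particle effects, or correlated core breathing motions.
Passing the synthetic closed loop therefore demonstrates that the
*machinery* — contrast bookkeeping, kernel accuracy, fitting, ranking,
geometry — is correct and well-calibrated, not that any particular real
dataset will be fit to a particular χ².

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by choice:
300-atom clusters for kernel oracles, 1,500–8,000-point spheres for
closed forms, the 2,540-atom toy for end-to-end work, 50-frame ensembles
and 20 seeded repeats for the recovery and calibration experiments
(about one minute in total). All generators take explicit seeds and
restore the caller's RNG state; identical inputs give bit-identical
outputs, and report writers emit stable text tables.

## Known limitations

* No hydration-shell contrast term in curve prediction; fitted χ²
  against published values carries a systematic offset.
* No resolution smearing (flagged as the natural extension point in
  `debye_curve()`).
* The exchange model is a single global fraction, not per-residue
  kinetics; shielding is a user-supplied selection, not a membrane
  positioning algorithm.
* mmCIF is read-only; PDB is the write format, with its fixed-width
  field limits (serials wrap at 10⁵, coordinates at ±9999 Å).
* `ift()` recovers distributions, not shapes; there is no bead modelling
  or multi-component decomposition.
* Pore profiles report probe clearance geometry only — no hydrophobicity
  or solvation annotation.
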