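# ionsans

Integrative small-angle neutron scattering (SANS) and structural-dynamics
analysis for pentameric ligand-gated ion channels (pLGICs) — membrane
channels whose peripheral domains can be too mobile for any single static
structure to explain a solution measurement.

The package is written for structural biologists who have (i) atomic models
of an oligomeric channel (crystallography, cryo-EM, or simulation
snapshots), (ii) reduced solution-scattering curves, and (iii) questions of
the form *which conformation — or which member of an ensemble — does the
solution data support?* It also targets the channel-specific geometry that
accompanies such studies: pore-radius profiles with prime-notation
anchoring, interfacial ion-site distances, and domain center-of-mass
tracking.

## The science in brief

**Curve prediction.** The orientation-averaged scattering of a rigid
assembly is the Debye sum

    I(Q) = sum_ij  Δb_i Δb_j  sin(Q r_ij) / (Q r_ij)

where the excess scattering length of atom *i* under the solvent contrast is

    Δb_i = b_i + n_H b_H + n_D b_D − ρ_solv v_i .

The contrast model accounts for hydrogen–deuterium exchange of labile
(N/O/S-bound) hydrogens via a single exchanged fraction (default 0.90),
keeps transmembrane-shielded hydrogens as ¹H, and treats match-out
deuterated detergent as invisible. The pair sum is accelerated by a
weighted distance histogram (Rcpp) with per-bin mean/variance corrections,
so a 2,500-atom curve costs milliseconds while agreeing with the exact
double sum to ≲0.001%.

**Curve analysis.** Guinier fits of ln I vs Q² (iterated to a
self-consistent q·Rg window) give Rg and I(0); molecular weight follows
from I(0) on absolute scale; pair-distance distributions come from models
(weighted histograms) and from data (regularized indirect Fourier
transform with non-negativity, solved exactly by an active-set method).
Model curves are fitted to data by analytic weighted least squares with a
free scale and constant background; goodness of fit is the reduced χ².

**Structure and ensembles.** Kabsch superposition, RMSD/RMSF, HOLE/CHAP-style
pore-radius profiles (probe-sphere clearance maximized per z-slice),
per-frame χ² ranking of trajectory snapshots against a measured curve, and
Cartesian-coordinate PCA landscapes with per-frame goodness-of-fit
annotation.

**Synthetic ground truth.** A C5-symmetric toy channel (TMD rod bundle,
ECD annulus, two mobile peripheral lobes per subunit; ~2,500 pseudo-atoms,
Rg ≈ 50 Å, dmax ≈ 160 Å) with bounded mean-reverting lobe walks and a
calibrated SANS noise model makes every stage testable without downloads.

## Worked example

The `analysis/` scripts run the full workflow on the synthetic system
(each takes seconds; run them in order from the repository root):

```sh
Rscript analysis/01_build_models.R
Rscript analysis/03_fit_models.R
```

which prints, among other things:

```
compact reference: 2540 pseudo-atoms, Rg = 50.7 A, dmax = 158.6 A
asymmetric conformer (2/5 NTD1 out-and-down): Rg = 51.0 A (+0.30 A)

Guinier: Rg = 50.37 +/- 0.26 A, I(0) = 6.414e+06 +/- 1.4e+04 (46 pts, qRg <= 1.26)
model ranking:
       model   chi2 rg_coord rg_guinier
1 asymmetric 0.8556    51.02      50.55
2    compact 3.9989    50.72      50.10
best-supported candidate: asymmetric (chi2 0.86 vs 4.00)
```

Reading this: the simulated measurement was generated from the asymmetric
conformer (two of five NTD1 lobes translated 10 Å outward and 8 Å toward
the membrane). Although the two candidates differ by only 0.3 Å in Rg —
indistinguishable by Guinier analysis alone — the full-curve χ² separates
them cleanly (0.86, i.e. fitting at the noise level, versus 4.0). Script
`05_ensemble_fit.R` repeats the exercise against a 50-frame lobe-motion
ensemble: the planted conformer ranks first (χ² 0.86 vs 4.0 for the
symmetric starting structure) and projects onto the PCA landscape inside
its generating cluster.

In R, the same workflow is three calls:

```r
library(ionsans)
toy   <- build_toy_channel()
curve <- simulate_sans(perturb_lobes(toy, list(NTD1_A = c(dr = 10, dz = -8),
                                               NTD1_C = c(dr = 10, dz = -8))),
                       seed = 11)
run_structure_vs_sans(list(compact = toy$model), curve)
```

For experimental data, replace the simulated pieces with
`read_structure("model.pdb")`, `read_curve("reduced.dat")`, and a
`contrast_model()` describing the buffer (D₂O fraction, exchange, shielded
transmembrane selection).

## Layout

- `R/`, `src/` — the package (structure I/O and selections, contrast model,
  Debye/Guinier/MW/fitting, p(r) and IFT, pore profiling, trajectories and
  PCA, synthetic generators, report drivers)
- `analysis/01–05_*.R` — the narrative workflow over the package
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/channel-sans-analysis.Rmd` — the methods vignette (model,
  parameters, numerical choices, limitations)
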