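---
title: "Solution structure determination of long-hinged antibodies at bead resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution structure determination of long-hinged antibodies at bead resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sasens)
```

## The problem

Human IgG3 carries a hinge of roughly 60-70 residues between its two Fab
arms and its Fc region — several times longer than in the other IgG
subclasses — and stabilized by eleven inter-chain disulfide bridges. The
molecule is too flexible to crystallize whole, so its solution structure
has to be inferred by fitting conformational ensembles to small-angle
X-ray and neutron scattering (SAXS/SANS) curves, cross-validated by
analytical-ultracentrifugation sedimentation coefficients. `sasens`
implements that determination pipeline end to end at coarse-grained bead
resolution, together with a synthetic-data generator that supplies ground
truth, so every stage is testable without any deposited data.

## The model

A **bead model** represents the antibody as one bead per residue with unit
scattering length, partitioned into rigid regions:

* `FAB1`, `FAB2` — the antigen-binding arms, filled ellipsoids of beads on
  a jittered lattice (default semi-axes 4.4 x 2.4 x 2.4 nm, spacing
  0.8 nm);
* `HINGE` — the expanded 70-residue hinge
  `ELKTPLGDTTHTCPRCP(EPKSCDTPPPCPRCP)3APELLGGP` (continuous numbering
  216-285), built as a gently coiled chain with a 0.38 nm virtual bond;
* `FC` — the receptor-binding region, an ellipsoid plus a rigid 8-residue
  anchor peptide (SVFLFPPK) embedded at its top, which is the segment the
  hinge hands over to;
* `GLYCAN` — optionally two 11-residue biantennary chains
  (core Man3GlcNAc2 with two NeuNAc-Gal-GlcNAc antennae) on the Fc
  surface. A glycosylated/deglycosylated pair built from the same seed
  differs only in these 22 beads.

At the momentum transfers analyzed here (Q <= 1.5 nm^-1, with
Q = 4 pi sin(theta)/lambda) all implemented observables — R_G, P(r), I(Q),
hull-based s — are shape-dominated, which is what justifies the one-bead
reduction. Internal units are nm; PDB files are converted from/to
Angstrom on I/O. Continuous 1-based numbering is canonical, with an EU
offset (-47) reproducing the conventional Fc labels (Asn344 continuous =
Asn297 EU).

### Hinge length

The literature quotes both "62 amino acids" and a printed 70-residue
216-285 hinge sequence for IgG3. The package fixes the modeled span at
the 70-residue expansion of the printed repeat pattern, which contains
exactly the 11 cysteines of the inter-chain bridges; the shorter count is
noted but unused.

### One hinge chain, two Fabs

The physical molecule pairs two heavy-chain hinges; the bead model
reduces them to a single 70-bead chain carrying both Fab arms at its
N-terminal end. Consequences to keep in mind: torsion moves on the
N-terminal pivots reorient the *Fab pair as a rigid unit* relative to
hinge and Fc, and the Fab-Fab internal geometry is fixed at construction.
The two-strand disulfide-paired hinge is retained where it matters — in
`generate_hinge_starts()`, whose conformers must keep all 11 chain-A/
chain-B cysteine pairs at disulfide-like separations (0.4-0.75 nm).

## Conformational sampling

`run_tamc()` performs torsion-angle Monte Carlo: each proposal picks a
pivot residue uniformly from the active profile, an angle kind (phi/psi,
mapped to the two virtual bonds flanking the pivot bead), and one of 24
discrete 15-degree steps, rotates everything on the moving side rigidly,
and accepts the conformer if and only if it is free of steric clashes.
There is no energy function and no Metropolis criterion: the published
procedure rejects on steric feasibility alone, and we mirror that.

* Pivot profiles: glycosylated 217-222 (Fab side) plus 285-286 (Fc side);
  deglycosylated 217-220 plus 283-284.
* Clash rule: any inter-region or non-bonded intra-hinge bead pair closer
  than the cutoff; sequence neighbors (|delta residue| <= 2 within a
  chain) are exempt. The cutoff default is 0.35 nm, a standard C-alpha
  excluded-volume scale; the original software's atom-level criterion is
  not published, so this value is this package's own choice.
* A move can only create clashes between the moving and the static side,
  so the hot loop checks exactly those pairs; the full pair scan
  (`detect_clash()`) is kept as the reference implementation and the test
  suite verifies every stored conformer against it.
* `n_moves` counts proposals (whether the published per-start move counts
  include auto-rejections is unstated; proposals are the cleaner
  bookkeeping).
* Determinism: (start, profile, n_moves, cutoff, seed) fully determine a
  library. Production runs pool several chains, one per start structure,
  with `merge_libraries()` — the multi-start protocol of the original
  procedure, which also prevents a single random walk from drifting away
  from the start region and biasing the library.

At default settings the rejection fraction lands around 0.4, inside the
31-61% range reported for the glycosylated libraries of the reference
workflow.

## Scattering and analysis

* `debye_curve()` computes I(Q) = sum_jk f_j f_k sinc(Q r_jk). With
  `bin_width > 0` (default 0.02 nm) pair distances are histogrammed
  first; at Q <= 1.5 nm^-1 the binning error is far below 0.1%, and the
  exact sum (`bin_width = 0`) is available for small models.
* `orientational_grid_curve()` averages |F(Q n)|^2 over a golden-ratio
  (Fibonacci) spherical lattice. The published calculator does not state
  its orientation count; the default here is 1000, where agreement with
  the Debye sum is comfortably below 0.5% for models of this size.
* `guinier_fit()` and `cross_section_fits()` use the fixed antibody
  windows 0.10-0.22 (R_G), 0.22-0.28 (R_XS-1) and 0.50-1.10 nm^-1
  (R_XS-2) by default and report achieved Q.R_G limits rather than
  auto-selecting windows; for a ~9 nm R_G molecule the default window
  exceeds the nominal Guinier validity range and the reported limits make
  that visible.
* `kratky_dimensionless()` returns (Q R_G)^2 I/I(0) against Q R_G with
  its peak; a globular particle peaks at (sqrt(3), 3/e).
* No hydration shell and no smearing are modeled (matching the reference
  analysis, where smearing left Guinier results essentially unchanged);
  X-ray and neutron modality differ only in grid, noise and the flat
  incoherent background.

## Real space

`pr_from_model()` is the weighted pair-distance histogram (total weight
exactly (sum f)^2 - sum f^2); `indirect_transform()` inverts a curve to
P(r) on [0, Dmax] by nonnegative least squares with a second-difference
smoothness penalty and the boundary conditions P(0) = P(Dmax) = 0. For
error-free curves the penalty weight defaults to 0.01 (scaled by the
Frobenius norms of the design and penalty matrices so it is
intensity-scale invariant); round-trip errors then plateau near 4.5-5%
normalized RMS, which is the information limit set by the
Q <= 1.5 nm^-1 truncation, not by the penalty. For curves carrying
per-point errors the system is sigma-weighted and the penalty is chosen
automatically by the discrepancy principle — the smallest weight whose
weighted residual reaches chi-squared per point of about one — because a
weight tuned on noiseless curves under-regularizes noisy data: the
resulting P(r) ripple can split the broad Fab-Fc bump into spurious
maxima and mislabel M2. The discrepancy choice stops the fit exactly
where it would start reproducing noise, with no reference to any known
answer. `analyze_pr()` reads the maximum length L where P falls below
1% of its maximum, and labels the up-to-three most prominent local maxima
M1 < M2 < M3 after a 3-bin running mean that suppresses bead-lattice
shell ripple (peak positions move by less than one bin). M1 collects
intra-region distances, M2 the Fab-Fab separation, M3 Fab-Fc.

A diagnostic note: transform-derived M3 positions are sensitive to the
regularization and to Dmax, which is consistent with modality-dependent
M3 readings in experimental work; the package surfaces the forward-fit
residual so such cases are visible rather than resolved silently.

## Fitting and screening

Experimental curves are interpolated to the uniform fitting grids — 825
points (X-ray) or 146 points (neutron) on [0, 1.5] nm^-1 — by monotone
piecewise-cubic interpolation, with Guinier-model extrapolation below the
first measured point (`preprocess_curve()`). Model curves are compared by
the crystallography-style L1 R-factor

R = 100 * sum |I_expt - eta I_model| / sum |I_expt|,

with eta found by golden-section search on the bracketed convex
objective, refined to 1e-6 relative, ties resolving to the smallest eta.
Chi-squared fitting is deliberately absent: interpolated points carry no
independent errors. For neutron fits a flat incoherent background of
2.0% of I(0) is *added to the model curve* (the published wording is
ambiguous between adding to the model and subtracting from data; the
model side is implemented, and the `fraction` argument makes the
alternative a one-liner). `screen_library()` scores a whole library,
ranks ascending and keeps the best `n_select` (default 100), annotating
the (R_G, R-factor) cloud with the +/-2% band around the experimental
R_G.

## Ensemble analysis

Best-fit sets are glycan-stripped (`strip_glycans()`), superposed on the
Fc region by least-squares rigid superposition (`superpose()`, SVD-based;
the tests cross-check against an independent quaternion solution), and
clustered by PCA (`pca_cluster()`): eigendecomposition of the coordinate
covariance, k-means on the first three components, and a centroid model
per group (the member minimizing summed in-group projection distance).
The published workflow reports PC1-PC3 and five X-ray/three neutron
groups but not its clustering algorithm; k-means on PC1-3 with a fixed
seed and 20 restarts is this package's choice, with k a parameter.
Eigenvector signs are fixed by making each component's largest loading
positive. `fab_tip_separation()` measures the antigen-binding reach
between the most hinge-distal bead of each Fab.

## Hydrodynamics

`s20w_standardize()` applies the textbook viscosity/buoyancy correction
to water at 20 C (rho = 0.99823 g/ml, eta = 0.010019 P).
`hull_s_estimate()` predicts s from shape alone: convex hull of the bead
centers (a self-contained incremental hull; no external dependency),
equivalent-sphere radius grown by a 0.28 nm hydration layer, and a
Perrin-type prolate frictional factor from the hull's principal-axis
ratio a/sqrt(bc). This is a documented simplification of published
hull-based predictors — their reduced-atom rules are not reproduced — and
is validated against analytic Stokes cases (a compact 158-kDa sphere
lands within 5% of the Stokes-law oracle) rather than against any
external tool. Glycan beads enter the hull like all others. The pipeline
consumes s only as a cross-validation statistic: extended three-body
models must sediment more slowly than compact controls of the same mass.

## The synthetic-data generator

`make_ground_truth()` fixes the study conditions:

* `igg3_like` — the long-hinge default; by construction its maximum
  dimension falls in the 25-28 nm band characteristic of IgG3 and its
  P(r) resolves three maxima (M2 at the 9.0 nm Fab-Fab center
  separation). The hinge end-to-end length (about 10.3 nm) sits inside
  the 7.67-10.80 nm range reported for extended IgG3 hinges.
* `compact_control` — an IgG1-like antibody with the 15-residue hinge
  EPKSCDKTHTCPPCP; Dmax below 18 nm and only two resolvable maxima.

`simulate_curve()` emits instrument-like observations: the Debye curve on
the 825-point (X-ray) or 146-point (neutron) grid, multiplicative
Gaussian noise with sigma(Q) = sigma0 (1 + (Q/Qmax)^2) I(Q) — reduced
solution-scattering data are background-subtracted averages, so Gaussian
rather than Poisson, with the growth term mimicking the visibly noisier
high-Q neutron data — and, for neutrons, a flat background of 2% of
I(0). Defaults: sigma0 = 0.01 (X-ray) and 0.04 (neutron). A
"concentration series" is emulated as a noise-level series; no real
concentration dependence is simulated. What the generator does *not*
emulate: intra-region flexibility, aggregation, interparticle structure
factors, radiation damage, O-linked hinge glycans, and per-element
scattering contrast. Passing tests therefore demonstrate that the
pipeline recovers known geometry under idealized instrument statistics,
not that it would be robust to every pathology of real data.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
desk scale, chosen so the whole suite completes in minutes on one CPU:
~755-bead models, five Monte Carlo chains of 2,000 proposals each
(pooling to >= 5,000 accepted conformers, the scale at which top-100
screening statistics stabilize), 825/146-point curves, and top-100
ensembles for PCA. The published libraries are two orders of magnitude
larger; every algorithmic component is identical, only the counts are
scaled.

## Known limitations

* Fab-Fab geometry is fixed per construction (single-hinge reduction), so
  screening recovers Fab-pair orientation and Fc placement, not
  independent Fab motion.
* Unit scattering lengths ignore contrast differences between protein and
  glycan; at Q <= 1.5 nm^-1 and this resolution the effect is below the
  noise floor of the synthetic data, but real contrast-variation work
  needs per-residue weights (the `f` column accepts them).
* The hull s predictor is calibrated against Stokes-law spheres only; its
  absolute values for strongly anisometric shapes carry the Perrin
  approximation's error and should be read comparatively.
* Experimental R_G values near 7-9 nm put the fixed Guinier window beyond
  the nominal Q.R_G validity limit; the reported limits quantify the
  bias, which is shared by fixed-window experimental practice for
  antibodies.
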