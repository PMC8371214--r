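# sasens

Small-angle scattering ensemble modeling of multi-domain antibodies.

## What this is for

Antibodies with long flexible hinges — IgG3 above all, with its ~70-residue
disulfide-rich hinge — cannot be crystallized whole. Their solution
structures are determined by fitting libraries of physically plausible
conformers to small-angle X-ray and neutron scattering (SAXS/SANS) curves
and cross-validating against sedimentation coefficients from analytical
ultracentrifugation. `sasens` implements that workflow as a tested R
package for structural biologists who want to run, probe, or extend the
method at coarse-grained bead resolution:

1. **Model building** — three-body bead models (Fab/Fab/Fc) joined by an
   explicit hinge chain, with optional Fc glycans
   (`build_three_body_model()`).
2. **Conformational sampling** — torsion-angle Monte Carlo with discrete
   15° steps at hinge pivots and steric-clash rejection (`run_tamc()`,
   `merge_libraries()`).
3. **Theoretical scattering** — Debye sum and golden-ratio orientational
   average (`debye_curve()`, `orientational_grid_curve()`).
4. **Curve analysis** — Guinier, cross-sectional Guinier, dimensionless
   Kratky, and distance distributions P(r) with L and M1/M2/M3 peak
   extraction (`guinier_fit()`, `cross_section_fits()`,
   `kratky_dimensionless()`, `pr_from_model()`, `indirect_transform()`,
   `analyze_pr()`).
5. **Screening** — L1 R-factor with optimal scale factor η, SANS flat
   background handling, best-100 selection (`rfactor()`,
   `screen_library()`).
6. **Ensemble analysis** — Fc superposition, PCA + k-means clustering
   with centroid models, Fab-tip separation (`superpose()`,
   `pca_cluster()`, `fab_tip_separation()`).
7. **Hydrodynamics** — convex-hull sedimentation prediction and s20,w
   standardization (`hull_s_estimate()`, `s20w_standardize()`).
8. **Synthetic data** — ground-truth generators and instrument-like noisy
   curves so the whole pipeline runs and is verified without any
   deposited data (`make_ground_truth()`, `simulate_curve()`,
   `make_fixture_suite()`).

## The statistics at the core

With Q = 4π sin θ / λ, a bead model with scattering weights f_j gives

    I(Q) = Σ_j Σ_k f_j f_k sin(Q r_jk) / (Q r_jk)

Guinier analysis reads ln I(Q) = ln I(0) − R_G² Q² / 3 in the antibody
window 0.10–0.22 nm⁻¹; cross-sections read ln[I(Q)Q] = const − R_XS² Q²/2
in 0.22–0.28 and 0.50–1.10 nm⁻¹. Real space comes from
P(r) = (1/2π²) ∫ I(Q) Q r sin(Qr) dQ, inverted here by regularized
nonnegative least squares. Model-to-experiment agreement is the
crystallography-style R-factor

    R = Σ|I_expt(Q_i) − η I_model(Q_i)| / Σ|I_expt(Q_i)| × 100 ,

with η minimizing the L1 objective. Sedimentation coefficients follow
s = M(1 − v̄ρ) / (N_A 6π η_s R_s F) from the convex hull of the bead
centers (Stokes radius R_s, Perrin shape factor F), standardized by
s_20,w = s_T,B (η_T,B/η_20,w) · (1 − v̄ρ)_20,w / (1 − v̄ρ)_T,B.

## Worked example

```r
library(sasens)

truth <- make_ground_truth("igg3_like", seed = 1)
truth
#> ground_truth [igg3_like]: R_G 9.31 nm, Dmax 25.81 nm, Fab-Fab 9.00 nm, tips 12.36 nm

expt <- simulate_curve(truth, noise_spec("xray", seed = 42))
guinier_fit(expt)
#> Guinier: R_G = 8.264 nm, I0 = 5.354e+05, window 0.10-0.22 (Q.RG 0.83-1.82)

indirect_transform(expt, Dmax = 27)
#> pr_curve: Dmax = 27.00 nm, R_G = 9.31 nm; peaks: M1=3.24 M2=9.45 M3=17.28

lib <- run_tamc(truth$model, n_moves = 500, seed = 7)
lib
#> model_library: 302 stored conformers ( 301 accepted of 500 moves; rejection 0.40 )

screen_library(lib, expt, n_select = 25)
#> screen_result: 302 models scored; top 25 R-factors 0.85-2.62%, mean R_G 9.05 nm (expt band 8.10-8.43 nm)

hull_s_estimate(truth$model, mass = 158100, vbar = 0.776)
#> hydro_result: s = 4.40 S (s20,w = 4.40 S), R_s = 6.42 nm, f/f0 = 1.95, hull 967 nm^3
```

Reading the numbers: the generator records its true geometry (R_G 9.31 nm,
maximum length 25.8 nm inside the 25–28 nm band of long-hinged
antibodies, Fab–Fab center separation 9.0 nm). The P(r) transform of the
noisy synthetic curve recovers the real-space R_G exactly and places M2
at 9.45 nm, within 5% of the true Fab–Fab separation; the fixed-window
Guinier R_G under-reads an R_G this large (the printed Q·R_G limits flag
it). A 500-move Monte Carlo library accepts ~60% of proposals, and
screening ranks conformers so that the best-fit set clusters near the
generating structure. The extended model sediments at 4.4 S versus
~9.5 S for a compact sphere of the same mass — the elongation signature
the hydrodynamic cross-validation is after. At production scale (five
chains of 2,000 moves; ≥5,000 accepted models) the top-100 mean R_G lands
within ±2% of truth.

## Layout

* `R/` — implementation: `model_core`/`io` (types, construction, PDB and
  bead-table I/O), `conformer` (TAMC + hinge starts), `scattering`,
  `real_space`, `fitting`, `ensemble`, `hydro`, `synthetic`.
* `tests/testthat/` — unit and property tests per module plus the
  end-to-end acceptance suite; independent oracles (closed forms,
  brute-force scans, quaternion superposition, Monte-Carlo pair
  sampling) back every nontrivial numeric claim.
* `vignettes/antibody-solution-modeling.Rmd` — the methods account:
  model assumptions, parameter choices, numerical decisions, and what
  the synthetic tests do and do not demonstrate.
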