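# scswim — structurally constrained quantitative susceptibility mapping

Quantitative susceptibility mapping (QSM) reconstructs tissue magnetic
susceptibility χ from gradient-echo MRI phase by inverting the dipole
convolution: in k-space the field shift is `D(k)·χ(k)` with
`D(k) = 1/3 − (k·b̂)²/|k|²`, which vanishes on the magic-angle cone and makes
the inversion ill-posed.  This package is for researchers who work with
multi-echo, dual-flip-angle gradient-echo (STAGE-style) acquisitions and
want accurate susceptibility values in iron-rich deep gray matter, veins,
microbleeds and calcifications without the streaking and underestimation of
direct inversion.

The core estimator solves

    min over χ:  1/2 ‖W (F⁻¹ D F χ − δB)‖₂²  +  λ₁ ‖P Gχ‖₁  +  λ₂/2 ‖R χ‖₂²

where `W` weights data fidelity by image magnitude, the binary per-axis edge
masks `P` (from a high-contrast structural image and an initial
susceptibility estimate) exempt true edges from the gradient-sparsity
penalty, and `R` — zero over deep gray matter, veins and other
high-susceptibility regions — lets the amplitude penalty smooth the
background without flattening protected structures.  λ₁ = 0.005·λ₂; λ₂ per
echo comes from L-curve analysis.  Per-echo solutions are chained (each echo
initialized from the previous) and fused by R2\*-weighted averaging with
weights `wᵢ = TEᵢ·exp(−TEᵢ·R2*)`.

Also included: TKD, iSWIM and COSMOS baseline inversions, Laplacian phase
unwrapping with model-guided refinement, SHARP background-field removal, a
fully synthetic STAGE brain phantom (labeled anatomy, Ernst-equation
magnitudes, dipole-forward phase, complex noise), L-curve selection, and
evaluation tools (RMSE, 3D SSIM, ROI statistics, CSF-referenced accuracy
regression).

## Worked example

```r
library(scswim)

ds  <- simulate_stage(phantom_spec(), acq_params(), snr = 10, seed = 1)
rec <- run_stage_pipeline(ds, masks = "ideal")   # ground-truth P/R masks
print(rec)

rs <- roi_stats(rec$chi, ds$labels, tissue_table())
subset(rs, name %in% c("GP-L", "WM", "CMB1", "CMB2", "PG"))
rmse(rec$chi, ds$chi_gt, ds$brain_mask)
```

Output from this exact run:

```
Multi-echo scSWIM reconstruction: 96x96x64 voxels, 4 echoes fused
  FAL_TE1: lambda2 = 0.00681, 2 outer iter, objective 6.025e-05
  FAH_TE1: lambda2 = 0.00147, 2 outer iter, objective 1.301e-05
  FAL_TE2: lambda2 = 0.00316, 1 outer iter, objective 2.796e-05
  FAH_TE2: lambda2 = 0.001, 1 outer iter, objective 8.847e-06
   code name         mean        sd     n
1     1   WM    -3.235829 0.2151948 94061
3     3 GP-L   176.476196 0.2761684   214
19   19 CMB1  2996.996184 0.6896467    80
20   20 CMB2   998.534454 0.1468979   344
23   23   PG -3006.733032 0.9941512    76
[1] 3.831462
```

Reading it: the globus pallidus (model value 180 ppb) is recovered at
176.5 ppb, white matter (0 ppb) at −3.2 ppb, the +3000 and +1000 ppb
microbleed inserts at 2997 and 999 ppb, the −3000 ppb pineal-gland insert
at −3007 ppb, and the whole-brain RMSE against the ground-truth model is
3.8 ppb — the constrained inversion holds focal high-susceptibility objects
that direct inversions underestimate by hundreds of ppb.

A command-line front end over the same functions lives in
`inst/cli/scswim.R` (`simulate`, `reconstruct`, `evaluate`, `demo`
subcommands).

## Package layout

- `R/grids.R` — voxel grids, dipole kernel, forward model, finite differences
- `R/phantom.R` — tissue tables, parametric anatomy, STAGE simulation
- `R/preprocess.R` — unwrapping, refinement, SHARP, fidelity weights
- `R/baselines.R` — TKD, iSWIM, COSMOS
- `R/constraints.R` — edge (P) and protection (R) masks
- `R/scswim.R` — the constrained solver and multi-echo pipeline
- `R/selection.R` — L-curve scan
- `R/eval.R` — RMSE, SSIM, ROI statistics, accuracy regression
- `vignettes/scswim-methods.Rmd` — model, assumptions, design choices
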