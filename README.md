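# ivimsim

Monte-Carlo evaluation of intravoxel incoherent motion (IVIM) fitting
methods in low-perfused tissue.

IVIM imaging decomposes the diffusion-weighted MRI signal decay into a
tissue-diffusion compartment and a capillary pseudo-diffusion compartment:

    S(b)/S(0) = f · exp(−b·D*) + (1 − f) · exp(−b·D)

with `D` the tissue diffusion coefficient (mm²/s), `D*` the
pseudo-diffusion coefficient (mm²/s) and `f` the perfusion fraction. In
brain tissue — and especially in low-grade tumors — perfusion is low, the
decay is only subtly bi-exponential, and the nonlinear fit becomes
fragile. This package is for imaging scientists who need to quantify that
fragility before trusting IVIM maps: it simulates noisy signal ensembles at
controlled SNR, fits them with three cascades of increasing constraint
(fully segmented, partially segmented, simultaneous), and reports accuracy,
reproducibility (CV%), Bland-Altman bias with limits of agreement, outlier
rates, ANOVA/Tukey method comparisons, F-test confidence regions and a
multi-start census of local minima. A voxel-wise mapping layer applies any
cascade to 4D multi-b-value volumes (synthetic digital phantoms, NIfTI in
and out) with the `f > 0.3` CSF-masking rule.

## A worked example

Simulate 1000 noisy gray-matter curves at SNR 40, fit the fully
constrained cascade, and summarize:

```r
library(ivimsim)

gm  <- reference_params("gm")        # D = 8.32e-4, D* = 2.68e-2, f = 0.115
cfg <- simulation_config(gm, snr_levels = 40, n_iterations = 1000,
                         seed = 1, model_id = "gm")
fits <- fit_ensemble(generate_ensemble(cfg), methods = "one_parameter")
ok   <- !fits$outlier

cv_percent(fits$f[ok])                       # 36.5
mean_error_percent(fits$D[ok], gm$D)         # 2.20
bland_altman(fits$D[ok], gm$D)$bias_percent  # -2.20
100 * mean(fits$outlier)                     # 12.0
```

Read: across the 880 usable replicates the ensemble-mean `D` sits 2.2%
below truth (noise steepens the high-b log-linear segment, so `D` is
underestimated as SNR falls), the perfusion fraction is reproducible to a
CV of ~37%, and 12% of replicates were discarded because the `D*` fit did
not converge to an interior, well-conditioned solution. Run the same lines
with `reference_params("tumor")` and the numbers degrade sharply — that
contrast between a clearly bi-exponential tissue and a low-perfused one is
the point of the package.

The study-scale analysis lives in `analysis/01_simulate.R` …
`05_phantom_maps.R`, thin numbered drivers that generate the full
ensembles (2 tissues × 6 SNR levels × 1000 iterations), fit all three
cascades, and write `table1.csv` (CV% + outlier %), `table2.csv` (bias +
limits of agreement), `accuracy.csv`, `comparisons.csv` (ANOVA/Tukey),
confidence-grid matrices and the minima census under `results/`.
`run_study()` performs the same end-to-end run from a single YAML config.
The methods vignette (`vignettes/ivim-simulation-methods.Rmd`) documents
the model, the noise engine, the outlier rule and every numerical design
choice.

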