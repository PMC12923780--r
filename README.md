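# glymphalps

An R package for computing and validating the **DTI-ALPS index** — the
diffusion-MRI "analysis along the perivascular space" marker of glymphatic
function — together with a fully synthetic testbed: digital fiber phantoms,
a monoexponential diffusion-signal simulator with Rician noise, log-linear
tensor fitting, ROI extraction, a two-group cohort generator with clinical
covariates, and the statistical layer used in clinical group comparisons.

It is aimed at neuroimaging methodologists who want a transparent,
end-to-end-testable reference implementation of the ALPS computation, and at
analysts who want to run the accompanying group statistics (ANCOVA with
covariates, effect sizes, Bonferroni correction, partial correlations) on
their own subject tables.

## The index

At the level of the lateral-ventricle body, projection fibers run along z,
association fibers along y, and the medullary veins — the perivascular
direction — along x, perpendicular to both fiber systems. From the six
diffusion-tensor component maps, mean diffusivities are taken in a
projection-fiber ROI and an association-fiber ROI, and

```
ALPS = ((Dxx_proj + Dxx_assoc) / 2) / ((Dyy_proj + Dzz_assoc) / 2)
```

The numerator collects diffusivity *along* the perivascular direction; the
denominator collects diffusivity perpendicular to both the fibers and the
perivascular axis. An index near 1 means no preferential perivascular
diffusion; larger values indicate more.

Tensors are estimated per voxel by ordinary least squares on the
log-signal, `log S = log S0 − b gᵀDg`, from a single-shell acquisition
(default: one b = 0 volume plus 30 directions at b = 800 s/mm², the
scheme built by `make_gradient_scheme()`). Non-brain voxels are removed by
thresholding the b = 0 signal at `k` times the mean background noise
measured outside the parenchyma (default k = 3).

## Worked example

Build a noiseless phantom whose fiber regions carry the diabetic-group mean
diffusivities, push it through the full simulate → fit → extract pipeline,
and read off the index:

```r
library(glymphalps)

ph     <- build_phantom(phantom_spec(noise_sigma = 0))
scheme <- make_gradient_scheme(30, 800, n_b0 = 1, seed = 0)
dwi    <- simulate_dwi(ph, scheme, noise_model = "none")
res    <- subject_alps(dwi, ph$rois, subject_id = "phantom-t2dm")
res
#> <alps_result> subject phantom-t2dm: ALPS = 1.2703
round(res$roi_diffusivities[c("dxx_pro", "dyy_pro", "dxx_asc", "dzz_asc")] * 1e3, 4)
#> dxx_pro dyy_pro dxx_asc dzz_asc
#>    0.72    0.61    0.69    0.50
```

The recovered ROI means equal the generating values to numerical precision,
and the index is the exact ratio (0.72 + 0.69)/2 over (0.61 + 0.50)/2 =
1.2703 — the pipeline inverts its own signal model.

A small noisy cohort, end to end (simulation, tensor fits, ALPS, ANCOVA
adjusted for age, sex and BMI):

```r
run <- end_to_end(list(seed = 1, n_t2dm = 20L, n_control = 20L,
                       grid_shape = c(20L, 20L, 6L)))
run$report$table2[run$report$table2$variable == "alps", ]
#>  variable mean_t2dm sd_t2dm mean_ctrl sd_ctrl       p p_bonf       d      f
#>      alps     1.287  0.1175     1.345  0.1115 0.07407 0.9629 -0.5093 0.2547
```

Here the groups were generated with a true ALPS difference (1.296 vs 1.35,
SD 0.11); at n = 20 per arm the adjusted test is underpowered, as the
p-value shows — at the default study sizes (78 vs 106) the comparison is
detected in ~90% of replicates.

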