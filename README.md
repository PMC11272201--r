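# dtialps

A toolkit for **DTI-ALPS** — diffusion tensor image analysis along the
perivascular space — the MRI index proposed as a non-invasive proxy of
glymphatic (brain waste-clearance) function, together with the statistics
used to validate it as an instrument: intraclass correlation coefficients,
Bland–Altman agreement, and interpretation bands.

It is aimed at neuroimaging researchers who need (a) a transparent,
scripted ALPS computation from preprocessed single-shell diffusion MRI,
(b) a phantom simulator with *known* analytic ALPS indices for validating
any ALPS pipeline, and (c) reliability analyses for multi-scanner,
multi-rater or test-retest studies.

## The index

At the level of the lateral-ventricle body, perivascular spaces run
right–left (x) along the medullary veins, while projection fibers run
inferior–superior (z) and association fibers anterior–posterior (y). With
`Dxx`, `Dyy`, `Dzz` the diagonal diffusion-tensor elements (mm²/s) in the
anatomical frame, averaged over spherical ROIs in the projection (`proj`)
and association (`assoc`) fiber areas:

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

Left and right hemispheres are computed independently; the reported ALPS
index is their average. Values near 1 mean no preferential perivascular
diffusion. Two published ROI presets are built in (`DSI_DEFAULT`,
12-voxel-diameter spheres at (53,47,40), (59,47,40), (25,47,40),
(19,47,40); `FSL_DEFAULT`, 5 mm spheres at (116,110,99), (128,110,99),
(64,110,99), (51,110,99) on the 1 mm white-matter atlas grid).

Reliability of a cohort of ALPS indices is assessed with single-measure
two-way random-effects ICCs — the consistency form
`(MS_R − MS_E) / (MS_R + (k−1) MS_E)` for inter-scanner comparisons, the
absolute-agreement form
`(MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E))` for
inter-rater and test-retest comparisons — with McGraw–Wong 95% confidence
intervals and the conventional poor/moderate/good/excellent bands at
0.5 / 0.75 / 0.9.

## Worked example

Simulate a noise-free phantom whose true ALPS index is 1.5, fit tensors,
and compute the index:

```r
library(dtialps)

spec  <- default_phantom_spec("DSI_DEFAULT", gain = 1.5, snr = Inf)
sim   <- simulate_phantom(spec)                       # 6 b0 + 40 dirs, b=1000
tensor <- fit_tensor(sim$dwi, sim$gradients, method = "wls")
compute_alps(scalar_maps(tensor), "DSI_DEFAULT")
#> <alps_result> preset DSI_DEFAULT
#>   left 1.5000 | right 1.5000 | mean 1.5000
```

The recovered mean equals the designed gain because the phantom's analytic
ALPS is exactly the perivascular gain `g` — the package's central
correctness guarantee (it holds to 1e-9 through the full
simulate → fit → index chain).

Simulate a 15-subject × 4-scanner cohort on the ALPS scale and run the
inter-scanner validation:

```r
cs  <- cohort_spec(15, 4, sigma_subject = 0.15, sigma_error = 0.05, seed = 42)
tab <- simulate_cohort(cs)$truth
names(tab)[3] <- "alps_mean"
validation_report(tab, design = "inter_scanner")
#> <alps_validation_report> design inter_scanner (consistency ICC), n = 15, k = 4
#> <icc_result> ICC(C,1) = 0.882 (95% CI [0.766; 0.953], P = 1.4e-17) — good
#> pairwise:
#>   pair estimate ci_lower ci_upper  p_value      band
#>  M1-M2    0.839    0.587    0.943 2.41e-05      good
#>  M1-M3    0.871    0.659    0.955 5.68e-06      good
#>  M1-M4    0.857    0.626    0.950 1.12e-05      good
#>  M2-M3    0.902    0.735    0.966 8.75e-07 excellent
#>  M2-M4    0.883    0.688    0.959 2.94e-06      good
#>  M3-M4    0.941    0.834    0.980 2.87e-08 excellent
```

The overall row is the consistency ICC across all four scanners; the six
pairwise rows mirror the scanner-pair tables reliability studies report.
The designed cohort (`sigma_subject = 0.15`, `sigma_error = 0.05`) implies
a theoretical agreement ICC of 0.9; the estimate 0.882 is its sampling
realization at n = 15.

## Command line

A thin wrapper over the same functions ships with the package:

```sh
DTIALPS=$(Rscript -e 'cat(system.file("cli", "dtialps.R", package = "dtialps"))')
Rscript $DTIALPS fit      --dwi dwi.nii.gz --bval dwi.bval --bvec dwi.bvec --out maps/
Rscript $DTIALPS index    --maps maps/ --preset both --out alps.csv
Rscript $DTIALPS simulate --n 15 --k 4 --seed 1 --out cohort/
Rscript $DTIALPS validate --alps alps_long.csv --design inter_scanner --out report/
```

Inputs are NIfTI volumes with FSL-dialect gradient files (one-row `.bval`,
three-row `.bvec`, vectors in the voxel frame), assumed already
distortion-corrected and registered; run TOPUP/EDDY, denoising, etc. with
your preferred tools beforehand. Volumes are reoriented to RAS internally
and b-vectors rotated accordingly. Exit codes: 0 success, 2 usage/config
error, 3 data error.

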