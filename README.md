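# brmspheroid

Correlative Brillouin–Raman analysis of multicellular tumor spheroids.

Brillouin microspectroscopy measures a GHz-frequency acoustic shift
ω_B that reports local stiffness, but a spheroid voxel averages two
materials — cells and extracellular matrix (ECM) — so ω_B alone
confounds "stiffer cells" with "less watery surroundings". This package
implements the analysis that untangles the two by pairing each Brillouin
measurement with a high-wavenumber Raman spectrum of the same volume:

- **Brillouin fitting** (`fit_brillouin`, `fit_dho`): damped harmonic
  oscillator (DHO) lineshape fits with Stokes/anti-Stokes symmetry
  calibration of the frequency axis, elastic-line exclusion, and
  curvature-based standard errors.
- **Raman composition chain** (`remove_baseline`, `optimize_factors`,
  `subtract_scaled`, `integrate_band`, `ch_oh_ratio`): spline
  fluorescence removal, subtraction of PDMS-chip and culture-medium
  reference spectra with least-squares factor optimization, and the
  CH/OH band-area ratio that measures dry matter vs. water.
- **Biphasic model** (`calibrate_kappa`, `estimate_phi`,
  `forward_omega`, `invert_omega_ecm`): converts the CH/OH ratio into
  cell and ECM volume fractions (Φ_cell + Φ_ECM = 1), calibrated on
  compressed spheroids of known composition, and decomposes the measured
  Brillouin shift as ω_B = ω_cell·Φ_cell + ω_ECM·Φ_ECM.
- **Morphometry** (`nucleus_shapes`, `classify_zone`,
  `positive_fraction`, `invasion_ratio`): nuclear aspect ratios by
  spheroid zone, marker-positive fractions, and invasion areas from
  label images and masks.
- **Synthetic data** (`make_dataset`, `make_brillouin`, `make_raman`,
  `make_nuclei_image`, …): seeded generators with recorded ground truth
  for every stage, so the whole pipeline is testable without instrument
  data.
- **Orchestration** (`run_pipeline`, `compare_groups`): manifest-driven
  batch processing with CSV/YAML outputs and normality-gated group
  statistics.

See the methods vignette (`vignettes/methods.Rmd`) for the physical
model, the design rationale behind each numerical choice, and the
generator's stated limits.

## Worked example

Generate a synthetic three-condition dataset (control, ROCK-inhibited,
and compressed spheroids — the compressed ones have no interstitial
space and calibrate the model), run the full pipeline, and compare
conditions:

```r
library(brmspheroid)

data_dir <- file.path(tempdir(), "demo")
manifest <- make_dataset(c("control", "rock", "compressed"), n_per = 5,
                         seed = 42, outdir = data_dir)

cfg <- pipeline_config(
  manifest_path = manifest,
  pdms_path    = file.path(data_dir, "refs", "pdms.txt"),
  medium_path  = file.path(data_dir, "refs", "medium.txt"),
  offchip_path = file.path(data_dir, "refs", "offchip.txt"),
  outdir       = file.path(tempdir(), "demo-results"))
out <- run_pipeline(cfg)

res <- attr(out, "results")
subset(res$summary, metric %in% c("omega_b", "phi_ecm"))
#>   condition  metric n        mean          sd
#>  compressed omega_b 5 8.198457668 0.002161618
#>     control omega_b 5 8.172060764 0.003134220
#>        rock omega_b 5 8.076556506 0.003383851
#>  compressed phi_ecm 5 0.007918328 0.012028502
#>     control phi_ecm 5 0.151682247 0.018016500
#>        rock phi_ecm 5 0.234729614 0.023600626

comp <- res$composition
compare_groups(split(comp$phi_ecm, comp$condition)[c("control", "rock")])
#> <group comparison> t-test
#>    group n      mean         sd
#>  control 5 0.1516822 0.01801650
#>     rock 5 0.2347296 0.02360063
#> p-value(s):
#> [1] 0.0002445664
```

The control spheroids come out near 15% ECM / 85% cells, the
ROCK-inhibited ones near 24% ECM, and the compressed calibrants at zero
— and the ~0.1 GHz Brillouin softening under ROCK inhibition is
attributable to composition, not just cell mechanics.

A single spectrum can be fitted directly:

```r
gen <- make_brillouin(condition_preset("control"), seed = 1)
fit_brillouin(gen$spectrum)
#> <DHO fit> omega_B = 8.1706 +/- 0.0012 GHz, Gamma = 1.2154 +/- 0.0039 GHz
#>   amplitude 3.02e+03, background 58.9, rss 4.15e+05, offset 0.0002 GHz
gen$truth$omega_b_linear
#> [1] 8.17
```

## License

MIT (see `LICENSE`).
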