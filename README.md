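# smlmpipe

Post-processing, nanodomain morphometry and correlative registration for
single-molecule localization microscopy (SMLM).

SMLM instruments emit *coordinate tables* — one row per fitted
single-molecule detection (frame, x, y, photon count, PSF FWHM) — not
images. Everything biological downstream depends on how those
coordinates are filtered, drift-corrected, rendered and measured.
`smlmpipe` implements that chain for multi-channel imaging of early
endosomes, where a small GTPase (Rab5-type marker) concentrates in
nanodomains of a few tens of nanometres on the endosome's limiting
membrane, together with endocytosed cargo (EGF- and transferrin-type
markers) in the lumen and in tubules:

- **Record filtering** — closed FWHM window (typically 250–450 nm on
  sections) and per-dye photon thresholds (3000 / 1500 / 450 photons for
  AF647 / AF568 / Dronpa-GFP), inclusive boundaries.
- **Track linking and localization precision** — greedy
  mutual-nearest-neighbour linking of localizations in consecutive
  frames; per track, the pooled per-axis SD around the track mean
  `s = sqrt((var_x + var_y)/2)`; the **median of `s` over all tracks**
  is the localization precision.
- **Linear drift correction** — per-track displacement-vs-frame slopes
  from long (fiducial) tracks, combined by spread-weighted median;
  correction `x' = x − v_x (t − t_0)`.
- **Rendering** — 2-D count histogram at 10 nm/px (floor binning), with
  a 0–1 px median filter for the nanodomain channel to suppress
  monomeric cytosolic signal.
- **Morphometry** — Gaussian blur (σ = 2 px) → IsoData (iterative
  intermeans) auto-threshold → hole-inclusive 8-connected particle
  analysis with a 4 px² area floor → area-matched moment ellipses
  (diameter = mean of axes) → per-endosome domain counts, covered area
  and coverage fraction, with OLS fits of covered area vs count and
  count vs endosome area. A quadrature broadening correction
  `d_corr = sqrt(d² − (2.355 σ_eff)²)` compensates the analysis blur.
- **Registration** — rod-shaped broadband fiducials (bacteria
  surrogates) give centre-of-mass and axis-endpoint landmarks;
  similarity / rigid / affine fits are closed-form, thin-plate splines
  solve the regularized kernel system; overlay precision is the
  leave-one-out residual distance, reported as mean ± SD and
  median ± MAD.
- **Synthetic ground truth** — a first-class generator of endosome-like
  scenes (membrane rings with non-overlapping nanodomains, tubules,
  luminal cargo, uniform cytosolic background, drifting stage, rod
  fiducials, EM-style reference image) against which every stage is
  validated.

## Worked example

```r
library(smlmpipe)

cfg <- run_config(out_dir = "endosome_run", seed = 3)   # bundled preset
res <- run_domain_analysis(cfg)
print(res$morphometry$summary)
#> <morphometry_summary> 8 endosomes, 34 domains
#>   domains/endosome: 4.2 +/- 1.7 (mean +/- SD)
#>   domain diameter : 77.2 +/- 9.3 nm
#>   covered area vs count: slope 4546 nm^2/domain, r = 0.979

mean(res$morphometry$domains$diameter_corrected)
#> [1] 55.46647
res$drift$ch488
#> <drift_model> v = (0.02, -0.0099708) nm/frame (track_lsq); SE = (4.92e-05, 4.68e-05)
res$precision$ch488
#> <precision_estimate> median 9.80 nm over 22027 tracks (pooled_axes variant)
```

The preset scene truly contains ~5 domains of 55 nm per endosome with
10 nm localization error and a drift of (0.02, −0.01) nm/frame: the
summary's raw diameter (77.2 nm) shows the expected broadening of the
blur-and-threshold procedure, the corrected diameter (55.5 nm) recovers
the true size, and drift and precision are recovered from the data
alone. `run_overlay_qc(cfg)` runs the registration workflow on the same
scene and prints per-channel-pair overlay reports; a thin command-line
wrapper with `analyze` / `overlay-qc` / `simulate` / `benchmark`
subcommands lives at `system.file("cli", "smlmpipe.R", package =
"smlmpipe")`.

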