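# msifuse

Classification of beef cuts (sirloin, flank, shank) from six-band
multispectral image cubes, for researchers in food quality assessment and
spectral imaging who need a tested, reproducible implementation of the
standard texture + spectrum feature-fusion pipeline.

Different cuts differ both in composition (water, myoglobin, intramuscular
fat — visible as band-wise reflectance differences, e.g. a deoxymyoglobin
absorption dip near 760 nm in sirloin) and in spatial structure (fascia
stripes in shank, fat marbling in sirloin). The pipeline therefore extracts
and fuses two kinds of features from calibrated reflectance cubes and
compares three classifiers on every feature combination.

## The pipeline

1. **Reflectance calibration.** Raw counts are converted to relative
   reflectance against dark and diffuse-reference frames:

   R = (I_raw − I_dark) / (I_ref − I_dark) × ρ_ref,   ρ_ref = 0.20,

   which also cancels smooth illumination inhomogeneity.

2. **Texture features (24).** Per band, reflectance is quantized to N = 64
   gray levels and a symmetric gray-level co-occurrence matrix g(i, j) is
   built at distance 1, averaged over the four canonical directions. Four
   Haralick statistics are computed per band:

   - homogeneity  Σᵢⱼ g(i,j) / (1 + (i−j)²)
   - contrast     Σᵢⱼ (i−j)² g(i,j)
   - energy       Σᵢⱼ g(i,j)²
   - correlation  (Σᵢⱼ i·j·g(i,j) − μₓμᵧ) / (σₓσᵧ)

3. **Spectral features.** The per-band ROI-mean reflectances (the 6-value
   "MS" set), and a 3-value CIELAB set: the 680/570/500 nm band means are
   treated as a linear RGB triple, mapped to CIEXYZ by the standard
   D65-referenced 3×3 matrix, then to (L*, a*, b*) with the usual
   cube-root compression about the white point.

4. **Fusion and classification.** Feature blocks are z-scored
   (parameters fitted on training data only, re-fitted inside every
   cross-validation fold) and concatenated into six feature sets —
   MS (6), CIELAB (3), Texture (24), MS+Texture (30), CIELAB+Texture (27),
   MS+Texture+CIELAB (33). Each set is evaluated with LDA (SVD solver),
   linear SVM (C = 0.6, one-vs-one) and random forest (160 trees, √p
   features per split) using a stratified 445/110 calibration/prediction
   split and stratified 10-fold cross-validation, reporting accuracies,
   per-class precision/recall and confusion matrices.

Because no public beef-cut image set exists, the package ships a seeded
synthetic cube generator (`generate_sample()`, `generate_dataset()`) whose
class templates reproduce the qualitative spectral ordering and textures
above, so the whole pipeline is testable end to end.

## Worked example

```r
library(msifuse)

tpl <- default_class_templates()$sirloin
cfg <- generator_config(image_size = c(64L, 64L))
s   <- generate_sample(tpl, cfg, seed = 42)
cal <- calibrate(s$raw, s$frames)
cal
#> <msi_cube> 64 x 64 pixels, 6 band(s) [500/530/570/680/760/808 nm], calibrated reflectance

round(ms_features(cal), 4)
#>  ms500  ms530  ms570  ms680  ms760  ms808
#> 0.1311 0.1575 0.1700 0.3943 0.2886 0.4657
```

The band means recover this sample's jittered reflectance profile: darkest
at 500 nm and dipping at 760 nm relative to its neighbours — the sirloin
signature. `cielab_features(cal)` summarizes the same cube as
(L* = 53.48, a* = 19.61, b* = 15.94): a mid-lightness, reddish sample.
`extract_texture(cal)` adds the 24 texture values (e.g. at 500 nm:
homogeneity 0.57, contrast 1.78, energy 0.026, correlation 0.86 — strong,
spatially structured marbling).

A small experiment grid end to end:

```r
cfg <- pipeline_config(
  generator = generator_config(image_size = c(64L, 64L),
                               n_per_class = c(sirloin = 40L, flank = 32L,
                                               shank = 39L), seed = 7),
  split = split_spec(89, 22, seed = 7), seed = 7)
rep <- run_experiment(cfg, out_dir = "results/demo")
head(rep$summary, 9)
#>   feature_set n_features classifier cv_mean_accuracy prediction_accuracy
#> 1          MS          6       LSVM            97.78               95.45
#> 2          MS          6        LDA            97.78               95.45
#> 3          MS          6         RF            94.44               95.45
#> 4      CIELAB          3       LSVM            93.33               86.36
#> 5      CIELAB          3        LDA            93.33               81.82
#> 6      CIELAB          3         RF            86.53               77.27
#> 7     Texture         24       LSVM            98.89              100.00
#> 8     Texture         24        LDA           100.00              100.00
#> 9     Texture         24         RF            97.78              100.00
```

Each row is one grid cell: mean stratified 10-fold cross-validation
accuracy on the 89-sample calibration set and accuracy on the 22 held-out
prediction samples. The fused sets match or beat every single-modality
set; `rep$cells[["MS + Texture + CIELAB | LDA"]]$confusion` holds the
per-cell confusion matrix (a perfect diagonal in this run).

The same experiment can be driven from a shell via the thin wrapper in
`inst/cli/` (subcommands `simulate`, `features`, `evaluate`, `run`), with
a YAML configuration like `inst/extdata/example_config.yaml`.

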