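---
title: "Classifying milk NIR spectra with a variable cluster–SVM hybrid model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying milk NIR spectra with a variable cluster–SVM hybrid model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EU Regulation EC No. 1308/2013 defines marketable milk classes by fat
content: skimmed below 0.5 % m/m, semi-skimmed between 1.5 % and 1.8 %, and
whole above 3.5 %; milk with any other fat content carries no class
designation. Because fat manipulation (skimming, watering) is among the most
common dairy frauds, a rapid check that a labelled class matches the
spectroscopic fingerprint of the product is valuable. Near-infrared
absorbance spectra of milk in the 1350–2558 nm range are dominated by water
absorption (a broad band near 1450 nm and another near 1940 nm), with much
weaker fat, protein and lactose features; the classification task is to
recover the fat class from that weak constituent signal.

`lactospec` implements the full pipeline as a classic R modelling package:
the central fitting function `vcsvm()` returns a classed object with
`print`/`summary`/`predict`/`coef` methods, and `run_experiment()`
orchestrates the complete train/validate experiment.

## Pipeline and assumptions

1. **Replicate averaging** (`average_replicates()`). Twenty scans per sample
   are averaged on raw absorbance *before* any pre-treatment. Averaging
   first reduces uncorrelated scan noise by √20 and is the conventional
   order; it is pinned by tests so the behaviour cannot drift silently.
2. **SNV** (`snv()`, `preprocess()`). Each spectrum is centred and scaled to
   unit sample standard deviation (n − 1 denominator — a choice the
   `[1,2,3] → [−1,0,1]` test pins, since either denominator is defensible).
   SNV removes exactly any per-scan transform `a·x + b`, which is how
   multiplicative scatter (particle-size/path-length variation from fat
   globules and casein micelles) and additive offsets enter reflectance
   measurements. It does not remove wavelength-dependent drift such as a
   baseline tilt; that residual is part of what the classifier must
   tolerate.
3. **Savitzky–Golay derivatives** (`savgol()`) are provided as the
   alternative pre-treatment. Kernel coefficients come from
   `signal::sgolay`; edges are mirror-padded so the output length equals the
   input length; derivatives are scaled by the grid spacing to absorbance
   per nm (or nm²). The filter requires a uniform grid (relative tolerance
   1e-6) and errors otherwise, advising interpolation. Defaults
   (window 11, polynomial order 2) are conventional chemometric settings;
   no specific values were dictated by the source experiment.
4. **Variable clustering** (`varclus()`). A divisive VARCLUS-style
   procedure on the correlation matrix: repeatedly split the cluster with
   the largest second eigenvalue — variables follow whichever of the
   quartimax-rotated first two principal components they correlate with
   more strongly — then reassign variables to the cluster component with the
   highest squared correlation until stable (at most `max_passes = 25`
   passes; a warning is raised if that limit is hit). Each final cluster is
   summarized by the first principal component of its standardized
   variables. The published experiment used a proprietary implementation of
   variable clustering whose split/reassignment details are not documented;
   this package pins a fully specified algorithm in the same family and
   verifies it against dense eigendecomposition oracles for the k = 1 and
   k = p limits, block-correlation recovery, and monotonicity of variance
   explained in k.
5. **SVM** (`fit_svm()`, `tune_svm()`). A soft-margin SVM via `e1071`
   (libsvm): one-vs-one voting for the four classes, features centred and
   scaled to training statistics. Tuning evaluates a 7 × 7 log-spaced grid
   over C ∈ [0.01, 5] and γ ∈ [0.001, 0.5] (bounds included; the linear
   kernel tunes C only), scoring each configuration by mean accuracy over
   twenty re-seeded 5-fold cross-validation shuffles of the training set.
   Ties break toward smaller C, then smaller γ, making selection
   deterministic. An `epsilon` slot is carried in `svm_config()` for
   provenance only: the ε-insensitive band belongs to SVM *regression* and
   plays no role in soft-margin classification.
6. **Evaluation** (`confusion_matrix()`, `one_vs_all()`,
   `classwise_metrics()`). One-vs-all reduction uses the standard
   convention: TP is the target's diagonal cell, FN the rest of its actual
   row, FP the rest of its predicted column, TN the remainder. MCC with a
   zero denominator is 0 by convention; an undefined sensitivity or
   specificity is returned as `NA` rather than silently coerced. MCC is
   algebraically invariant under swapping FP with FN — the implementation
   pairs the denominator factors so this holds bitwise — which matters when
   comparing against published binary tables whose orientation is
   ambiguous or transposed: the MCC survives transposition even though
   sensitivity and precision exchange roles.

## Leakage control

Model selection and all fitted statistics use training data only: the
50/50 split (stratified by class, training receiving the odd sample, so 73
samples divide 37/36) happens before `varclus()` is fitted, and the
standardization constants, cluster loadings, SVM feature scaling and
hyperparameter selection are all learned on the training half and then
applied frozen to the validation half. Selecting hyperparameters on
validation accuracy would overstate performance; the tuning criterion is
therefore internal cross-validation accuracy, and validation metrics are
computed exactly once per kernel, after selection.

## Class boundary semantics

`milk_class_from_fat()` is strict at the whole-milk boundary (exactly
3.5 % is no-class) and at the skimmed boundary (exactly 0.5 % is
no-class), while the semi-skimmed interval is inclusive. Regulatory texts
can be read either way at 3.5 %; the thresholds are exposed in
`milk_thresholds()` so an inclusive reading is one argument away. Whether
any real sample sits exactly on a boundary is immaterial in practice —
labelled fat contents are quantized to 0.1 % — but the convention is
declared and tested.

## The synthetic generator

No spectra from the original experiment are publicly deposited, so
`simulate_milk_spectra()` generates datasets with the statistical structure
the analysis assumes:

* **Composition.** 73 samples (whole 19, no-class 9, semi-skimmed 34,
  skimmed 11). Fat is drawn per class from normal distributions with the
  label statistics of the study population (mean ± sd: whole 3.71 ± 0.35,
  no-class 0.98 ± 0.12, semi-skimmed 1.59 ± 0.04, skimmed 0.17 ± 0.18 %),
  truncated by rejection to the class's regulatory interval so the
  generating class always equals the regulatory label (material for
  skimmed, whose untruncated distribution would produce negative values;
  the no-class group is drawn in the 0.5–1.5 % gap where its observed mean
  lies). Carbohydrate (4.95 ± 0.15 %) and protein (3.35 ± 0.25 %) carry no
  class dependence, so they act as pure nuisance variation.
* **Spectra.** A clean spectrum is a 0.25 AU baseline plus Gaussian bands:
  water at 1450 nm (amplitude 1.0 AU, the dominant peak) and 1940 nm
  (0.55 AU) with *fixed* amplitudes — deliberately not scaled by water
  fraction, so that ablating the fat bands removes all class information —
  and constituent bands scaled by concentration: fat at 1730/1765/2310 nm
  (0.018/0.014/0.020 AU per % fat), protein at 2055/2180 nm (0.008 AU/%),
  lactose at 2100 nm (0.006 AU/%). These are conventional NIR
  overtone/combination assignments; amplitudes keep every constituent band
  more than tenfold below the water peak, matching the qualitative
  observation that milk constituent bands are hard to see against water.
* **Replicates and artifacts.** Each of the 20 scans per sample is
  corrupted by multiplicative scatter (sd 0.05), an additive offset
  (sd 0.02 AU), a linear tilt about the grid midpoint (sd 5e-6 AU/nm) and
  white noise (sd 0.001 AU per point) — magnitudes chosen as realistic for
  a warmed-up compact FT-NIR instrument, with scatter dominating noise so
  that SNV demonstrably reduces between-replicate dispersion.
* **Grid.** 1350–2558 nm in 8 nm steps (152 points), consistent with a
  16 nm optical resolution plus interpolation; the true detector point
  count of the original instrument is not public, so this is a convention,
  and it is configurable.

What the generator does *not* emulate: Beer–Lambert nonlinearity and
radiative transfer in a scattering emulsion, temperature and
hydrogen-bonding band shifts, correlated (pink) detector noise, and any
real covariance between fat and the other constituents. Consequently,
passing end-to-end tests demonstrates that the pipeline recovers classes
whose signature is a weak, localized, concentration-proportional spectral
signal under scatter artifacts — not that it would achieve any particular
accuracy on real milk.

## Numerical choices

* Eigenvector signs are fixed (largest-magnitude loading positive) so
  models are reproducible across linear-algebra backends.
* Cluster-split ties (second eigenvalues within `tol = 1e-8`) go to the
  cluster containing the smallest wavelength index; reassignment requires a
  squared-correlation improvement greater than `tol`, and moves that would
  empty a cluster are disallowed (the partition invariant admits no empty
  cluster).
* The quartimax angle is found by a 181-point grid over one period
  followed by local refinement — deterministic and ample for a
  two-column rotation.
* `split_spectra()` gives training `floor(fraction·n + 0.5)` samples;
  stratified remainders are allocated by largest fractional part with a
  seeded tie-break.
* The varclus JSON artifact stores doubles at jsonlite's full writing
  precision (15 significant digits); reloaded models reproduce scores to
  ~1e-12 relative and predicted labels exactly.
* All randomness (composition draws, artifact draws, splits, CV shuffles)
  derives from one master seed via a seeded sub-seed draw, and every
  seeded helper restores the caller's RNG state.

## Problem sizes

The test suite exercises the full study geometry — 73 samples × 20
replicates × 152 wavelengths, two kernels, the complete 7 × 7 × 20-repeat
tuning grid — in the acceptance tests, and smaller seeded configurations
(about 22 samples, 3–4 replicates, 3 × 3 grids) in the unit tests of the
workflow; oracle checks for the clustering use 20 × 10 to 50 × 12 matrices.

## Known limitations

* With 37 training samples and class fat gaps as narrow as ~0.2 % (no-class
  versus semi-skimmed), a margin classifier on six compressed features
  makes occasional boundary errors concentrated in the small no-class
  group; accuracy on simulated datasets varies with the seed even though
  the fat signal is fully present in the cluster scores. This mirrors the
  behaviour reported for the original experiment, where half of the
  validation no-class samples were misclassified.
* The divisive clustering is a pinned member of the VARCLUS family, not a
  reimplementation of any proprietary tool; partitions from other
  implementations may differ in detail while yielding similar variance
  explained.
* Only SNV, Savitzky–Golay derivatives and their SNV-then-derivative
  combination are offered (SNV after a derivative is deliberately not,
  since the pre-treatments were evaluated as alternatives); MSC,
  detrending and wavelet methods are out of scope.
* No probability calibration, class weighting, or additional kernels; no
  JCAMP-DX/SPC readers — spectra enter as wide CSV tables.
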