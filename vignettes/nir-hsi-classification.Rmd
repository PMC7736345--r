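---
title: "Methods: per-pixel NIR-HSI classification of submucosal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-pixel NIR-HSI classification of submucosal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirgist)
```

# The analysis

`nirgist` classifies every pixel of a near-infrared hyperspectral scan of a
resected gastric specimen as **gist** (gastrointestinal stromal tumor) or
**normal** tissue. The tumor is submucosal: a 0.4–2.5 mm layer of normal
mucosa can cover it completely, so the per-pixel spectrum is a mixture of
the covering tissue and the lesion beneath. The pipeline is:

1. **Calibration.** Raw counts are flat-field normalized against white and
   dark references, `R = (raw − dark)/(white − dark)`. Reflectance is
   stored as a fraction; values outside `[0, 1.5]` are clipped and counted,
   and positions with a degenerate denominator (`white ≤ dark`) are flagged
   per pixel rather than propagated as NaN.
2. **Spectral filtering.** Bands above 1600 nm are dropped (sensor
   sensitivity falls and water absorption dominates there); on the
   instrument's 6.3 nm grid from 1000 nm this keeps 96 of 215 bands, the
   last at 1598.5 nm. Pixels whose reflectance at the band nearest 1300 nm
   exceeds 0.70 (specular highlight) or falls below 0.10 (shadow) are
   masked. The thresholds retain exact boundary values; masking probes the
   pre-selection cube, which is equivalent to probing afterwards because
   1300 nm survives selection.
3. **Features.** Reflectance is converted to absorbance
   `A = −log10(max(R, floor))` — the representation in which layered tissue
   contributions add (Beer–Lambert) — then each retained pixel's spectrum is
   SNV-standardized: `z = (x − mean(x))/std(x)`.
4. **Training data.** A pathologist-style annotation supplies a closed
   boundary polyline (inside = gist, outside = normal), class-pure training
   boxes, and the specimen extent. Box pixels that survive the masks become
   labeled training spectra.
5. **Classifier.** A two-class SVM with RBF kernel
   `K(x_i, x_j) = exp(−‖x_i − x_j‖²/σ²)`, bandwidth fixed by the median
   heuristic `σ² = median{‖x_i − x_j‖² : i < j}`, regularization `C = 1`.
6. **Evaluation.** Leave-one-specimen-out cross-validation: each specimen
   is predicted by a model trained on all other specimens' boxes. Pixels
   within Euclidean distance `2t` of the boundary polyline (`t` = drawn
   line thickness) are excluded from the confusion counts, because a
   freehand line carries positional error; specificity, sensitivity and
   accuracy are computed from the pooled counts (count-weighted, not
   macro-averaged) and reported per specimen with half-up rounding to one
   decimal. Specimens without normal tissue have undefined
   FPR/specificity, rendered as dashes.

# The SVM: reduction and solver

The classifier is specified as the joint multiclass hinge formulation

$$\min_{w,\xi}\; \tfrac12\sum_{n=1}^{k}\|w_n\|^2 + \frac{C}{m}\sum_{i=1}^m \xi_i
\quad\text{s.t.}\quad \langle x_i, w_{y_i}\rangle - \langle x_i, w_n\rangle
\ge 1 - \delta_{y_i,n} - \xi_i .$$

With `k = 2`, writing `v = w_gist − w_normal` and coding gist as `s = +1`,
the constraints become `s_i⟨x_i, v⟩ ≥ 1 − ξ_i` and the regularizer is
minimized at `w_gist = −w_normal = v/2`, giving
`min ¼‖v‖² + (C/m) Σ hinge`. This is exactly a **bias-free** binary
soft-margin SVM; its dual is the box-constrained QP

$$\max_\alpha\; \textstyle\sum_i \alpha_i - \tfrac12 \alpha^\top Q \alpha,
\qquad 0 \le \alpha_i \le C_b,\qquad Q_{ij} = s_i s_j K(x_i, x_j),$$

with **no equality constraint** (there is no intercept). The solver is a
decomposition method: at each step the dual coordinate with the largest
KKT violation is updated to its exact univariate maximizer and clipped to
the box; since `K_ii = 1` for the RBF kernel the update is closed-form, and
the gradient `1 − Qα` is maintained incrementally so one iteration costs
`O(m)`. Convergence is declared when the largest violation falls below the
tolerance (default `1e-3` on kernel scores; iteration cap `1e7`). Because
the dual has no coupling constraint, single-coordinate decomposition is the
natural exact scheme — pairwise working sets are only needed when an
equality constraint must be preserved. The solver path is deterministic;
training rows are canonicalized (sorted by specimen, then pixel) first, so
the fit is independent of input order.

**Interpretation of `C`.** The joint formulation scales the loss by `C/m`,
which makes the dual box bound `2C/m`. For per-pixel training sets
(`m ≈ 10³–10⁵`) that bound is so small that *every* dual variable
saturates: the "SVM" degenerates into a difference of Parzen kernel
densities and cannot express a margin (we measure ~58 % training accuracy
in that regime). Practical decomposition solvers take `C` as the per-point
box bound, and reported results with `C = 1` on large pixel training sets
are only consistent with that convention. `svm_train()` therefore defaults
to `c_scaling = "absolute"` (box bound `C`) and retains
`c_scaling = "per_m"` as a switch; both are verified against a
projected-gradient QP oracle in the test suite.

**Class balance.** A bias-free SVM has no intercept to absorb class
imbalance, so an excess of one class in the pooled training boxes shifts
every prediction toward that class. The cross-validation driver therefore
balances each fold by default (`subsample = "balance"`: a seeded stratified
cap at the smaller class count; `NULL` uses every box pixel, an integer
caps both classes). With balancing, a no-signal cohort scores 49.7–50.9 %
across seeds — chance, as it must — where the imbalanced folds drifted
several points below.

**Decision rule.** Scores for the two classes are `±f(x)/2` with
`f(x) = Σ α_i s_i K(x_i, x)`; prediction is the argmax, and an exact tie
resolves to the first class code (`gist`).

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `max_nm` | 1600 | nm | band-selection cutoff |
| `probe_nm` | 1300 | nm | highlight/shadow probe wavelength |
| `hi`, `lo` | 0.70, 0.10 | fraction | highlight/shadow reflectance thresholds |
| `floor` | 1e-4 | fraction | reflectance floor for absorbance (caps A at 4) |
| `C` | 1 | — | SVM regularization (per-point box bound) |
| `sigma2` | `"median"` | squared SNV units | RBF bandwidth |
| `tol` | 1e-3 | kernel score | KKT violation tolerance |
| `boundary thickness t` | 2 | px | half the exclusion corridor half-width (`2t`) |
| `subsample` | `"balance"` | rows | per-fold stratified training cap |

SNV uses the population standard deviation (divide by `n`), the convention
of the SNV literature; the sample version differs only by a constant
per-spectrum factor and is available as a switch. SNV is applied after band
selection, so each spectrum is standardized over the analysis bands only;
filtering is specified before normalization, and this order keeps the
statistics of the retained bands independent of the discarded water band.
Features are SNV of **absorbance** by default (reflectance is a config
option): absorbance is where layered contributions add linearly.

# The synthetic-specimen generator

No imaging data are redistributable, so the package ships a generator that
emulates the statistical structure the analysis assumes, and the end-to-end
claims in the test suite are claims about these synthetic cohorts.

* **Geometry.** A 64 × 64 px specimen extent (desk scale; the full 215-band
  instrument grid is available) containing an elliptical lesion with a
  freehand-jittered boundary polyline of thickness `t = 2` px. Five of the
  default twelve specimens are entirely lesion, exercising the
  undefined-specificity reporting path. Training boxes (8 × 8 px; one gist,
  two normal for mixed specimens) are auto-placed clear of the exclusion
  corridor.
* **Spectra.** Smooth endmember absorptivity curves (sums of Gaussian
  bands with a shared water bump near 1450 nm). One total-tissue-path field
  `T ~ U(3, 5)` mm is drawn for *all* tissue pixels; normal pixels carry
  `A = T·ε_mucosa`, lesion pixels split the same path into mucosa cover
  `d ~ U(0.4, 2.5)` mm plus lesion layer:
  `A = d·ε_mucosa + (T − d)·ε_gist`. Sharing the path distribution is what
  makes the zero-separation control a true null — total absorbance carries
  no class information, only spectral *shape* does, and SNV removes the
  path scaling itself. Deeper cover means a smaller lesion fraction
  `(T − d)/T`, reproducing the depth-attenuation failure mode.
* **Contrast.** The gist curve is the mucosa curve plus a smooth seeded
  perturbation scaled (by root finding, to 0.1 %) so that the post-SNV L2
  distance between the curves equals `separation` (default `δ = 1.5`; an
  SNV spectrum has norm `√96 ≈ 9.8`, so this is a ~15 % relative shape
  difference — similar but separable, matching the observation that real
  GIST and normal spectra look alike).
* **Nuisance.** Per-pixel multiplicative gain `U(0.85, 1.15)` and additive
  offset `U(−0.05, 0.05)` on absorbance (the artifacts SNV removes —
  verified exactly on noise-free twins), additive Gaussian noise
  (sd 0.02 absorbance), and 1 % planted highlights plus 1 % shadows.
  A raw/white/dark triplet can be emitted to exercise the calibration path.
* **Not modeled.** Radiative transfer, wavelength-dependent penetration
  depth, spatially correlated speckle, specimen-edge thinning, instrument
  drift. Passing tests therefore demonstrate that the *pipeline* recovers
  lesions under the stated mixing/noise model; they do not certify
  performance on real tissue.

All generator randomness flows from one seed (sub-seeds are drawn below
2³¹); the caller's RNG state is saved and restored. Identical seeds yield
byte-identical cohort files, reports and pooled-count JSON.

# Numerical and convention choices

* Pixel and band indices are 1-based `(row, col)`, matrix-style, with the
  band axis last; boxes are inclusive `[r0, r1] × [c0, c1]`. Polygon
  membership uses the even-odd (ray crossing) rule evaluated at integer
  pixel centers — deterministic for centers on edges.
* The boundary-exclusion rule is geometric, not morphological: a pixel is
  excluded iff its center lies within Euclidean distance `2t` of the
  polyline. A distance rule reflects the "freehand line with positional
  error" rationale and is independent of any structuring-element shape.
* `nearest_band` breaks exact ties toward the lower index; 1300 nm on the
  6.3 nm grid resolves to 1302.4 nm.
* Constant spectra (population sd ≤ 1e-12) are rejected by SNV with the
  offending row identified; degenerate calibration positions are flagged,
  not silently NaN.
* Report rounding is half-up to one decimal (e.g. 86.15 → 86.2), matching
  how such tables are conventionally printed; unrounded values are
  available from `metrics()`/`glance()`.
* Problem sizes in the tests: module tests run on toy grids (≤ 48 × 48);
  the end-to-end checks use the package's default desk-scale cohort
  (12 specimens, 64 × 64 × 96), which gives ≈ 1.4–1.6 k training spectra
  per fold and ≈ 19 k evaluated pixels pooled — large enough for stable
  pooled metrics while keeping the whole suite under a minute.

# Known limitations

* The decomposition solver materializes the `m × m` kernel matrix;
  training sets beyond ~2 × 10⁴ spectra would need chunked kernels or
  shrinking. The stratified cap bounds `m` in the pipeline.
* The generator's endmembers are shape-plausible stand-ins, not measured
  tissue absorptivities; no conclusion about absolute reflectance levels
  should be drawn from them.
* With only 12 specimens, pooled null-cohort accuracy retains a few points
  of seed-to-seed variability even after balancing, because prediction
  errors are spatially correlated within a specimen.
* ENVI I/O supports little-endian float32/float64 files with in-header
  wavelength lists — the subset relevant to calibrated reflectance cubes.
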