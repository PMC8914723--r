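---
title: "Models and methods behind nirfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirfm)
```

`nirfm` discriminates foreign materials (FMs) from fresh-cut vegetables in
near-infrared absorbance spectra and multispectral image cubes. This
vignette explains the models it fits, the choices behind their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical conventions that matter when reading its output.

## The classification model

The classifier is PLS-DA: an ordinary PLS1 regression of the class code
(0 = vegetable, 1 = FM) on the absorbance matrix, thresholded at 0.5.
`fit_plsda()` uses the classical NIPALS sequence on the column-centered
(optionally unit-variance-scaled) data. For each latent variable (LV):

$$w_a = X^\top y / \lVert X^\top y\rVert, \quad t_a = X w_a, \quad
  p_a = X^\top t_a / t_a^\top t_a, \quad q_a = y^\top t_a / t_a^\top t_a,$$

after which $X \leftarrow X - t_a p_a^\top$ and
$y \leftarrow y - q_a t_a$. The factorisation satisfies
$X_c = T P^\top + E_x$ and the regression vector
$\beta = W (P^\top W)^{-1} q$, mapped back to raw units so that
score-chain and $\beta$-route predictions agree. With as many LVs as the
rank of $X$, the fit reproduces ordinary least squares — one of the
oracle checks in the test suite.

NIPALS was chosen over SIMPLS deliberately: its score/loading recursion
matches the decomposition stated above term for term, which makes every
intermediate quantity directly testable (score orthogonality, exact
reconstruction, OLS equivalence at full rank).

Why a 0.5 threshold: the class codes are 0 and 1, and the decision
baseline sits at their midpoint. Ties go to the FM side (`score >= 0.5`),
the conservative direction for a food-safety screen. Centering is always
on; per-variable autoscaling is off by default and switched on where the
method requires comparable coefficient magnitudes across wavelengths
(weighted regression coefficients, below).

The LV count is chosen by stratified k-fold cross-validation
(`choose_n_lv()`, 10 folds by default) with a parsimony tie-break: the
smallest count attaining the minimal CV misclassification. Published
model tables report LV counts without stating a rule; cross-validation
with parsimony is the defensible default, and the package makes no
attempt to reproduce any particular table's counts.

### Vegetables are the positive class

Throughout the package `tp` counts correctly recognised vegetables and
`tn` correctly recognised FMs, so sensitivity is vegetable recall and
specificity FM recall. This matches how inspection-model tables in this
field are laid out, but inverts the common "contaminant = positive"
habit; it is stated prominently in `?confusion_counts`. A metric whose
denominator is zero raises an error rather than returning a sentinel 0 or
100, because a silent sentinel corrupts model-comparison tables.

## Preprocessing

Seven treatments, all row-wise: mean, max and range normalization, SNV,
MSC, and Savitzky–Golay first and second derivatives. Conventions worth
stating:

* **SNV** uses the $n-1$ standard-deviation denominator (the dominant
  chemometrics convention); any consistent choice passes the
  affine-invariance property the tests assert.
* **MSC** regresses each spectrum on the mean spectrum (or a supplied
  reference) and inverts the fitted affine map; a slope below `1e-10`
  is an error rather than a division.
* **Savitzky–Golay** defaults to window 11, polynomial order 2 — a
  common chemometric choice, exposed as arguments. Derivatives divide by
  the grid spacing, so units are absorbance·nm⁻¹ (or nm⁻²) and results
  do not change with grid resolution for smooth inputs. Edge points come
  from the off-center rows of the projection matrix, i.e. the polynomial
  fitted in the terminal window.

## The five waveband selectors

* **WRC** (`wrc_select()`): ranks local extrema of $|\beta|$ from an
  autoscaled fit, greedily accepting by magnitude subject to a minimum
  pairwise separation (default 30 nm — tight enough to keep neighbouring
  water features ~40 nm apart both eligible). The coefficients are
  compared in the standardized-variable space ($\beta_j \cdot s_j$);
  comparing raw-scale coefficients would re-impose the units the
  autoscaling removed.
* **VIP** (`vip_scores()`, `vip_select()`): standard Wold VIP with
  normalized weights, $\mathrm{SSY}_i = q_i^2\, t_i^\top t_i$. The mean
  of the squared scores is exactly 1, which is what makes "keep
  VIP ≥ 1"-style cut-offs meaningful; the identity is asserted for every
  fitted model in the tests. `vip_select()` scans cut-offs 0.8–1.5 in
  steps of 0.1 and keeps the one maximising CV accuracy, ties to the
  fewest variables.
* **SFS** (`sfs_select()`): greedy forward wrapper selection; the
  criterion is stratified k-fold CV misclassification of a PLS-DA on the
  candidate set with LVs = min(set size, 5), 20 folds by default.
* **SPA** (`spa_select()`): builds minimally collinear chains on the
  centered calibration matrix — from every start column, repeatedly add
  the column with the largest norm after projection onto the orthogonal
  complement of the chosen span — then scores every chain prefix between
  the size bounds (2–10 by default) by CV misclassification.
* **iPLS** (`ipls_select()`): tiles the axis into intervals (width 1 by
  default, i.e. single wavelengths), adds the best interval per step, and
  stops when the CV error no longer strictly decreases.

### The tie-break, and why it exists

On cleanly separable data — which well-designed synthetic data is, and
which the published calibration tables suggest real data can be — many
candidate wavelengths reach CV misclassification 0, and "pick the
minimum" degenerates into "pick the lowest wavelength index". All three
search selectors therefore break error ties by the cross-validated mean
squared error of the predicted score: a margin-sensitive, continuous
criterion under which the most strongly separating wavelength wins. SPA
keeps its published tie order (fewer variables first, lexicographic
last) with the MSE inserted before the lexicographic step. This is a
design choice of this package; with noisy real spectra where CV errors
rarely tie, it changes nothing.

### Reduced-model refits

`refit_with_bands()` restricts the **raw** (unpreprocessed) spectra to a
selection, refits PLS-DA and evaluates on held-out data — the procedure
used to validate a filter set before committing to multispectral
hardware, where per-spectrum preprocessing of a full curve is no longer
available.

## The imaging stage

`detect_fms()` chains the per-scene steps:

1. **Band extraction** — nearest band center per requested wavelength.
2. **Background removal** — Otsu threshold on a single band's intensity.
   The default band is the one nearest 1730 nm: every organic material,
   produce and contaminant alike, absorbs there well above a conveyor
   belt, whereas thresholding inside a water band removes dry
   low-absorbance FMs together with the background. This failure mode is
   real, not hypothetical: a near-flat reflector like metal sits so close
   to the belt at every band that single-band background removal swallows
   it — which is why the demo scenes exclude metal and why `remove_background()`
   exposes a fixed-level alternative.
3. **Per-pixel classification** — a PLS-DA fitted on band-restricted
   training spectra scores each foreground pixel; ≥ 0.5 means FM. A 3×3
   median filter over the integer label map (configurable off) suppresses
   isolated speckle, the minimal counterpart to instrument noise in real
   line-scan images.
4. **Object scoring** — FM pixels group into 8-connected blobs; blobs
   under `min_blob` pixels (default 5) are discarded; a ground-truth FM
   is detected iff a surviving blob overlaps its mask by ≥ 1 pixel, and
   every surviving blob with no FM overlap is one false positive. These
   three knobs (connectivity, minimum blob size, 1-pixel overlap) are
   this package's operationalisation of object-level counting; published
   tables give only the counts, not the adjudication rule.

Cubes default to absorbance units, consistent with the spectral tables.
Overall accuracy pools scenes: $100 \cdot \sum \text{detected} / \sum
\text{total}$.

## The synthetic-data generator

No public spectra exist for this task, so the generator is a first-class
module. A material is a linear baseline plus Gaussian absorption bands;
each realisation is multiplied by $e^{\mathcal N(0,\sigma_s)}$ (log-normal
multiplicative scatter) and perturbed by additive white noise. This is
the minimal model that reproduces the artefacts SNV and MSC exist to
remove, which is what makes preprocessing meaningfully testable.

Band *positions* in `material_presets()` follow standard NIR
assignments: vegetable water bands at 1190/1450/1940 nm, cellulose at
1730 nm, plastic methyl features near 1156 nm and in 1720–1770 nm, a
near-flat metal, broad weak stone bands. Band *amplitudes* and noise
levels are synthetic fixtures chosen once at magnitudes typical of
diffuse NIR absorbance (bands 0.1–1.2 AU, additive noise sd 0.01 AU,
log-scatter sd 0.05–0.1), encoding only the ordinal claims that matter:
water bands dominate for produce, and everything else is weaker. The
`film_mimic` preset is a deliberately adversarial synthetic construct — a
vegetable water profile whose 1450 nm band is replaced by a narrow
matched-height 1400 nm band — so that exactly one band separates it from
produce; it drives the five-versus-six-band comparison.

Scenes (`scene_spec()`, `simulate_hypercube()`) place ellipses and
rectangles on a constant-background belt; every object pixel draws an
independent realisation of its material. Masks are exact, and objects of
different classes may not overlap (an FM lying *on* produce would create
ambiguous ground truth at the pixel level).

What the generator does **not** emulate: radiative transfer, specular
highlights, detector nonlinearity, wavelength-correlated noise, moisture
gradients within a vegetable piece, or partial-pixel mixing at object
edges. Passing tests on this data therefore demonstrate that the
algorithms are implemented correctly and respond to planted structure as
designed — not that any particular accuracy would be achieved on real
produce.

## Problem sizes and determinism

The test and acceptance workloads run on a 157-point grid (1000–2500 nm),
100–200 spectra per model, 48×48-pixel scenes at the 5.876 nm line-scan
band spacing, and 4–20-fold cross-validation — sizes at which every
oracle comparison (exhaustive scans, closed forms, least-squares
equivalence) is exact and the whole suite completes in well under a
minute. The full-resolution defaults (1557-point grid, 320-pixel scan
lines) use the same code paths and are exercised by the round-trip tests.

Every stochastic routine takes an explicit integer seed and draws from a
single seeded stream (`withr::with_seed`), so identical inputs reproduce
identical outputs bit for bit; `run_pipeline()` additionally writes a
manifest (config hash, seeds, package version) with each run directory.

## Known limitations

* Autoscaled coefficients interact with multiplicative scatter: the
  per-variable standard deviation is inflated near strong bands, which
  can shift $|\beta|$ extrema from band centers onto shoulders. The WRC
  defaults (separation constraint, CV-chosen LV count) temper but do not
  remove this; selections on the 1920-nm-side shoulder of the 1940 nm
  water band are expected behaviour, on synthetic and real data alike.
* Single-band Otsu background removal loses any FM whose intensity at
  the chosen band approaches the belt's (metal being the canonical
  case); a multi-band or fixed-level rule is the practical remedy.
* The per-pixel classifier treats pixels independently; there is no
  spatial regularisation beyond the 3×3 median filter.
* PLS2 multi-class models, kernel PLS, backward iPLS and
  genetic-algorithm selection are out of scope.
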