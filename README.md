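# nirfm

Chemometric discrimination of foreign materials (FMs) in fresh-cut
vegetables from near-infrared spectra, with multispectral waveband
selection and image-based detection.

Fresh-cut produce lines are contaminated by plastics, wood, paper,
insects, stones, rubber and metal. In the 1000–2500 nm range, produce is
dominated by the O–H water bands near 1450 and 1940 nm (fresh vegetables
are 70–90 % water), while most contaminants share C–H features instead:
cellulose near 1730 nm (wood, paper, insects), methyl groups near 1156 nm
and in the 1720–1770 nm window (plastics). `nirfm` implements the full
workflow a spectroscopist uses to turn that contrast into a deployable
multispectral inspection system:

1. **Preprocessing** — mean/max/range normalization, SNV, MSC,
   Savitzky–Golay first and second derivatives, applied per spectrum.
2. **Classification** — PLS-DA fitted by NIPALS (PLS1): for each latent
   variable `w = Xᵀy/‖Xᵀy‖`, `t = Xw`, `p = Xᵀt/(tᵀt)`, `q = yᵀt/(tᵀt)`,
   deflating `X ← X − tpᵀ`, `y ← y − qt`; the regression vector is
   `β = W(PᵀW)⁻¹q`. A sample is called an FM iff its predicted score is
   ≥ 0.5, the midpoint of the 0/1 class codes.
3. **Waveband selection** — five standard algorithms: weighted regression
   coefficients (WRC), variable importance in projection (VIP,
   `VIPⱼ = √(J Σᵢ (wⱼᵢ/‖wᵢ‖)² SSYᵢ / Σᵢ SSYᵢ)`), sequential forward
   selection (SFS), the successive projections algorithm (SPA) and
   forward interval PLS (iPLS).
4. **Imaging** — band extraction from line-scan hypercubes, Otsu
   background removal, per-pixel PLS-DA classification, 8-connected blob
   grouping and object-level FM detection scoring across band
   combinations.
5. **Synthetic data** — a seeded generator for labeled spectra (Gaussian
   absorption bands + log-normal scatter + white noise) and ground-truthed
   multispectral scenes, so the whole pipeline is testable end to end.

A note on conventions: class 0 is *vegetable* and class 1 is *foreign
material*, and the **vegetable is the positive class** — sensitivity is
the vegetable recall and specificity the FM recall. This follows the
standard layout of inspection-model report tables in this field and
inverts the usual "contaminant = positive" habit; `?confusion_counts`
documents it.

## Worked example

```r
library(nirfm)

res <- run_pipeline(default_config(seed = 1L), "demo_run")
dplyr::select(res$model_report, partition, n, n_lv, tp, fn, tn, fp, accuracy)
#>   partition       n  n_lv    tp    fn    tn    fp accuracy
#> 1 calibration   122     3    56     0    66     0      100
#> 2 validation     53     3    24     0    29     0      100
```

The pipeline simulates a labeled two-class spectra set, applies SNV,
splits 70/30 per class, picks the latent-variable count by stratified
cross-validation (3 here), and classifies every calibration and
validation sample correctly — on clean synthetic spectra the two classes
are linearly separable, which is exactly what the planted water-band
contrast is meant to produce. The five selectors then compress the
spectrum:

```r
readr::read_csv("demo_run/selected_wavebands.csv")
#> method n_selected wavelengths
#> wrc    5          1164.5; 1290.3; 1450; 1725.8; 1933.9
#> vip    42         1416.1; ... ; 2006.5   (two water-band windows)
#> sfs    1          1938.7
#> spa    2          1309.7; 1938.7
#> ipls   5          1967.7; ... ; 1987.1
```

Every method lands on at least one water band (1450/1940 nm) — the
synthetic analogue of the clustering of published selections in the
1900–1925 nm region — and WRC adds the plastic (1164 nm) and cellulose
(1726 nm) features. Refitting PLS-DA on each reduced set reproduces the
full model's perfect validation accuracy. Finally the band subsets are
tested on simulated multispectral scenes:

```r
dplyr::select(res$imaging, -report)
#>   bands                              n_bands overall_accuracy false_positives
#> 1 1150, 1400, 1450, 1731, 1880, 1920       6            100                 0
#> 2 1150, 1400, 1731, 1880, 1920             5             71.4               0
```

Dropping the 1450 nm band costs roughly a quarter of the detections: the
scenes contain a thin film whose spectrum mimics produce at every other
band, so only the second water band separates it. That is the behaviour a
six-band filter set buys over five.

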