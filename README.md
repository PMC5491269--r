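# dermalign

Quantitative analysis of dermal collagen architecture in skin fibrosis, and
of its transcriptomic and cell-migration correlates.

In fibrotic skin (systemic sclerosis, bleomycin-challenged mouse skin) the
healthy basket-weave organization of dermal collagen — two interleaved bundle
populations at distinct angles — gives way to bundles aligned along a single
axis. `dermalign` measures this from stained histology sections and connects
it to gene expression and fibroblast motility:

* **Histology**: segments collagen bundles from a stained image, recovers the
  epidermal boundary, and computes three per-sample dermal metrics — dermis
  thickness (area / epidermal contour length), total collagen (stained
  fraction of the dermis) and bundle alignment.
* **Alignment score**: bundle orientations are axial angles θ ∈ [0°, 180°)
  measured relative to the epidermis. Doubled angles 2θ are fitted with a
  two-component von Mises mixture by EM,

  f(2θ) = w₁ · vM(2θ; 2μ₁, κ₁) + (1 − w₁) · vM(2θ; 2μ₂, κ₂),

  and the alignment score is the weight of the dominant peak,
  max(w₁, 1 − w₁) ∈ [0.5, 1]: 0.5 is a perfect basket-weave, 1.0 a fully
  aligned dermis (fits whose two peaks merge are scored 1.0).
* **Gene signatures**: per-metric signatures are built by intersecting pooled
  differentially expressed genes (mean normalized count > 3 for mouse skin or
  > 4 for human fibroblasts, |fold change| > 1.5, Benjamini–Hochberg adjusted
  p < 0.05, any treatment-vs-control contrast) with genes whose squared
  correlation to the metric exceeds a per-metric cutoff (r² > 0.7 for
  thickness, > 0.4 for total collagen and alignment).
* **Migration**: per-cell net displacement, accumulated distance and
  directionality from time-lapse trajectories (8-minute frames over 4.5 h),
  control-normalized group means, and Welch/Mann–Whitney condition tests.
* **Synthetic data**: seeded generators for stained slides with ground-truth
  bundle tables, negative binomial count matrices with planted
  metric-correlated genes, and persistent-random-walk trajectories with
  substrate anisotropy and knockdown effects — every stage is testable
  against known truth with no external data.

## Worked example

Simulate a fibrotic slide whose true dominant-peak weight is 0.79, then
recover it blind from the image:

```r
library(dermalign)

fibrotic <- orientation_mixture_spec(mu1 = 40, mu2 = 130, kappa = 8, w = 0.79)
slide <- generate_slide(fibrotic, n_bundles = 200, canvas = c(800, 1100),
                        seed = 42)

bundles <- segment_bundles(slide$image)
geom    <- extract_epidermis(slide$dermis_mask)
angles  <- bundle_angles(bundles, geom, fold = FALSE)
fit_two_peaks(angles, seed = 1)
#> peak_decomposition (n = 200): mu = 39.4 / 129.8 deg, w = 0.789 / 0.211,
#>   kappa = 11.21 / 9.56
#> alignment score: 0.789

dermis_thickness(geom)        # 768.6 px: dermis area / epidermal contour
collagen_fraction(geom, slide$image > 0.5)   # 0.059: stained dermis fraction
```

All 200 planted bundles are segmented; the fitted dominant-peak weight 0.789
recovers the generating weight 0.79 — the score that separates fibrotic
(unimodal, high-weight) from healthy (balanced bimodal, ≈ 0.5) sections.

The end-to-end synthetic study (slides → metrics → signatures → migration)
runs from one config:

```r
cfg <- pipeline_config(out_dir = "study")
run_simulate(cfg)   # images, counts, trajectories + ground truth + manifest
run_full(cfg)       # slide_metrics.csv, signature_*.txt, migration_*.csv,
                    # report.json
```

or from a shell via the thin wrapper `inst/cli/dermalign`
(`dermalign simulate|full [--config cfg.yaml] [--out DIR]`).

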