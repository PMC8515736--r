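# nanozone

Quantification of the nanoscale organization of synaptic proteins from
multi-channel super-resolution (STED / Airyscan-class) fluorescence images —
for cell biologists and microscopists who need the ensemble-raster analysis
behind statements like *"the target protein forms nanodomains whose length
and intensity differ between the pre-, post- and perisynaptic compartments."*

The package implements, as tested and reusable R functions:

* **Sequential segmentation** of synaptic functional zones — active-zone
  cytomatrix (CAZ), postsynaptic density (PSD), endocytic zone (EZ) —
  by threshold → size filter → connected-component labeling, with
  **mask-transfer classification** (positive / negative / false-positive)
  between channels, including the confocal-PSD × STED-Dynamin workflow that
  defines synapse-associated endocytic zones and the Clathrin validation of
  Dynamin regions.
* **Nanodomain morphometry**: per-domain length as the maximum Feret
  diameter (measured on the half-maximum sub-region by default, i.e. a
  discrete FWHM), background-corrected integrated intensity, zone
  assignment, and centroid-to-centroid line profiles.
* **Resolution-scaled colocalization**: RSP (Pearson correlation of the
  resolution-matched channel pair) and RSE (root-mean-square intensity
  error after least-squares photometric rescaling `α·T + β` and Gaussian
  resolution-scaling blur `G_σ`), per segmented region, aggregated as
  mean ± SEM:

  `T' = G_σ ⊗ (α·T + β)`,  `RSP = cor(G_σ ⊗ T, R)`,
  `RSE = sqrt(mean((T' − R)²))`, with σ fitted by minimizing RSE.

* **The statistical battery** used in this literature: Kruskal–Wallis +
  Dunn (Bonferroni), one-way ANOVA + Tukey HSD, two-sided Mann–Whitney
  (exact where feasible), Welch's *t*, median/IQR and mean ± SEM summaries,
  with `***` / `**` / `*` / `ns` bands at p ≤ 0.001 / 0.01 / 0.05.
* **A synthetic-field simulator** with exact emitter/zone ground truth
  (elliptical zones, Gaussian nanodomains with lognormal sizes and
  amplitudes, per-channel Gaussian PSFs, Poisson shot + Gaussian read
  noise), so the whole pipeline is testable without any acquired data.

See `vignettes/nanozone-methods.Rmd` for the model, defaults and their
rationale, and known limitations.

## Worked example

Simulate a field of 40 synapses, run the zone analysis, and compare
nanodomain length across compartments:

```r
library(nanozone)

cfg <- zone_run_config(
  sim = sim_config(field_size_px = c(512, 512), n_synapses = 40, seed = 7),
  outdir = "zone_run")
res <- run_zone_analysis(cfg)
#> simulated 120 zones, 1632 emitters [0.6s]
#> zone pre (caz): 39 regions
#> zone post (psd): 41 regions
#> zone peri (ez): 40 regions
#> target channel: 66 candidate nanodomains
#> assigned nanodomains: peri=20, post=17, pre=19
#> done [14.1s]

sapply(split(res$nanodomains$length_nm, res$nanodomains$zone_class), median)
#>      peri      post       pre 
#> 119.63944  90.13878  90.13878

res$stats$length_kw_dunn
#> <test_result> Kruskal-Wallis + Dunn: statistic = 1.415, p = 0.493 [ns]
#>   pairwise (adjusted):
#>     peri vs post: p = 1 [ns]
#>     peri vs pre: p = 0.8424 [ns]
#>     post vs pre: p = 1 [ns]
```

Per-record output is a tidy table (`zone_run/nanodomains.csv`): one row per
nanodomain with `zone_class`, `length_nm` (Feret/FWHM), `intensity_au`
(integrated, background-corrected), area, centroid and provenance.
`zone_run/coloc.csv` holds one row per zone region with `rsp`, `rse`,
`alpha`, `beta`, `rsf_sigma_nm`, `n_pixels`. Here all three compartments
were simulated with identical nanodomain statistics, so `ns` everywhere is
the correct answer; planting a smaller postsynaptic population
(`zone_length_dist = list(post = ...)`) makes the post-vs-pre and
post-vs-peri Dunn comparisons significant (see the acceptance script).

A command-line front end with subcommands `simulate`, `segment`,
`nanodomains`, `coloc`, `stats`, `run-all` lives at `inst/cli/nanozone`.

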