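---
title: "Methods: nanoscale quantification of synaptic protein organization"
author: "nanozone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale quantification of synaptic protein organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanozone)
```

## Scope and model

`nanozone` quantifies how a target synaptic protein (in the motivating
application: Nicastrin, the substrate-receptor subunit of γ-secretase) is
organized at the nanoscale relative to the functional zones of excitatory
synapses — the cytomatrix at the active zone (CAZ, marked by Bassoon), the
postsynaptic density (PSD, Shank2/PSD95) and the perisynaptic endocytic zone
(EZ, Dynamin validated by Clathrin) — in multi-channel super-resolution
(STED/Airyscan-class) images. The pipeline is ensemble-raster based: it works
on intensity images, not single-molecule localizations.

Four analysis stages sit behind one reproducible run:

1. **Sequential segmentation.** Each channel is thresholded (Otsu by default),
   size-filtered and labelled into connected regions. Cross-channel
   *mask transfer* classifies regions: a target region overlapping a reference
   region is *positive*, one without overlap *false positive*, and a reference
   region with no qualifying target is a *negative*. The synapse-associated
   EZ is the union of endocytic-marker regions positive against the
   (confocal) PSD mask; a second endocytic marker can further filter regions
   via `filter_by_partner()`.
2. **Nanodomain morphometry.** Target regions assigned to a zone (centroid
   containment by default) yield one record each with a length (maximum Feret
   diameter, nm) and a background-corrected intensity (integrated by
   default).
3. **Resolution-scaled colocalization.** Per segmented region, the target
   channel is photometrically rescaled (least-squares gain/offset) and
   resolution-matched to the reference channel through a Gaussian
   resolution-scaling function (RSF) of fitted width σ; RSP is the Pearson
   correlation of the resolution-scaled pair and RSE the root-mean-square
   intensity error. Region values are aggregated as mean ± SEM.
4. **Statistics.** Kruskal–Wallis + Dunn (Bonferroni) across the three zones
   for length/intensity; one-way ANOVA + Tukey HSD for RSP/RSE; Mann–Whitney
   and Welch's *t* for two-group partner comparisons; significance bands
   `***`/`**`/`*`/`ns` at p ≤ 0.001 / 0.01 / 0.05.

## The synthetic-data generator

No imaging data accompany this package, so every stage is exercised against
simulated fields with exact ground truth. The generator emulates:

* **Zone geometry.** Each synapse is a CAZ/PSD ellipse pair apposed across
  the cleft plus an EZ ellipse offset laterally from the PSD. Defaults: CAZ
  and PSD 300 × 120 nm (full axes) separated by 180 nm centre-to-centre —
  thin, edge-on apposed discs whose 2D projections barely overlap, matching
  the reported ~150–180 nm Bassoon-to-Shank2 centroid separation — and a
  200 × 150 nm EZ at 150 nm from the PSD edge. Same-class zones are placed
  without overlap by rejection sampling; a field that cannot host the
  requested synapse count is rejected with the count that did fit.
* **Emitters.** Nanodomains are isotropic Gaussian spots. Ground-truth size
  is parameterized by the emitter FWHM (lognormal, median 80 nm by default)
  and the channel PSF enters by adding variance:
  σ_eff² = σ_emitter² + σ_PSF², FWHM = 2.355 σ. The *measurable* length of a
  spot is the FWHM of its rendered profile, `effective_fwhm_nm()`; recovery
  is scored against it, since no image-domain measurement can undo the PSF.
  Amplitudes are lognormal (median 150 a.u.), which at the default
  background (10) and shot noise puts the median spot at SNR ≳ 10.
* **Resolution.** PSFs are Gaussian surrogates: 60 nm FWHM for STED-like
  channels, 250 nm for the confocal PSD channel used by the EZ workflow.
  Real STED PSFs have heavier tails; the Gaussian keeps the RSF parametric
  and is the standard desk-scale surrogate.
* **Counts and noise.** Per-zone emitter counts are Poisson (target density
  1.5/zone, marker density 12/zone); rendering adds Poisson shot noise on
  the noiseless expectation, then Gaussian read noise, clipped at zero.
* **Determinism.** One RNG stream per simulation with documented draw order
  (geometry → marker emitters → target emitters → process emitters);
  rendering noise uses a sub-seed derived from the seed and the channel
  name. Identical config + seed gives bit-identical ground truth, images
  and therefore pipeline outputs.

The nanodomain density default deserves a note: at STED-like resolution,
spots of ~100 nm effective FWHM inside a 300 nm zone merge when more than
about two are present. A mean of 1.5 per zone keeps most simulated domains
resolvable — the premise of the imaging modality being emulated. Merging
still happens (as in real data) and is part of what the recovery tests
tolerate.

What the simulator does **not** emulate: 3D structure, STED depletion
physics, drift or chromatic offsets, labeling stochasticity, vesicular
background structure. Passing recovery tests therefore show the pipeline is
internally consistent and unbiased under idealized imaging, not that it is
robust to every artefact of acquired data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixel_size_nm` | 25 | nm | Nyquist-ish for a 60 nm PSF |
| `psf_fwhm_nm` | 60 (STED) / 250 (confocal) | nm | effective resolutions of the emulated modalities |
| threshold method | Otsu | — | no threshold is reported for the original workflow; Otsu is parameter-free and recorded in provenance |
| size filter | [4 px, 1 µm²] | px | excludes single-pixel noise and merged mega-regions; both bounds configurable |
| connectivity | 8 | — | common particle-analysis behaviour for diagonally touching puncta |
| `min_overlap_px` | 1 | px | mask transfer is a presence/absence call |
| assignment rule | centroid | — | unambiguous for domains straddling a mask edge; overlap-fraction rule available |
| `length_halfmax` | TRUE | — | see below |
| intensity mode | integrated, background = median of sub-threshold pixels | a.u. | total molecular content per domain; mean mode available |
| RSF σ bounds | [0, 300] | nm | spans "no rescaling" to well beyond the confocal/STED resolution gap |
| Dunn adjustment | Bonferroni | — | conservative default; Holm and Šidák available |

## Numerical and design choices

* **Length = maximum Feret diameter** over pixel centres (convex-hull
  accelerated, all-pairs verified in tests); a single-pixel region has
  length one pixel by convention. "Length" had to be operationalized — the
  alternative (fitted-ellipse major axis) is exposed through the region
  properties but Feret is the default because it is what a caliper across
  an irregular punctum means.
* **Half-maximum refinement.** A global threshold sits wherever the image
  histogram puts it, so the thresholded footprint of a Gaussian spot is a
  level set at an arbitrary level — its Feret diameter would measure the
  threshold, not the spot. With `length_halfmax = TRUE` (default) the
  length is measured on the connected sub-region above half of the domain's
  background-corrected peak: a discrete FWHM, which is what "length of a
  nanodomain" means on a Gaussian-like profile and what makes recovery
  against `effective_fwhm_nm()` meaningful. Intensity is still integrated
  over the full thresholded region.
* **Otsu over exact unique values.** The threshold maximizes between-class
  variance over the observed unique intensities (not a binned histogram), so
  the foreground equals the exhaustive-scan answer exactly; ties break
  toward the smallest qualifying threshold.
* **Connected components as graph components** (igraph) with selectable 4/8
  connectivity; labels are consecutive integers in raster order.
* **RSP keeps its sign.** The least-squares gain would absorb a negative
  correlation (a perfectly anti-correlated pair would score +1 after
  rescaling), so RSP is computed as the Pearson correlation of the blurred
  test with the reference — Pearson is already invariant to the photometric
  rescaling — and RSE on the fully rescaled image. Consequence: RSP is
  invariant under positive-gain affine transforms of the test image and
  flips sign under negative gain.
* **RSF fitting.** RSE(σ) is minimized with the gain/offset refit at every
  candidate σ; the objective can be multi-modal for dissimilar channel
  pairs, so a 25-point coarse grid brackets the minimum before golden-
  section refinement (0.5 nm tolerance), with σ = 0 and both bounds always
  evaluated. A boundary optimum is flagged.
* **Per-region scope.** RSP/RSE are computed per segmented reference region
  and averaged (mean ± SEM), because the compartment — not the field — is
  the unit of comparison; whole-field mode remains for diagnostics.
  Both channels here are super-resolved, unlike the classic use of
  resolution-scaled metrics to compare a super-resolved image against a
  reference acquisition; the adaptation (marker channel as reference,
  target rescaled) is deliberate and symmetric in resolution.
* **Zone cross-talk.** With apposed zones, a nanodomain centroid can fall in
  two (blur-widened) zone masks; the pipeline then keeps the record only in
  the zone holding the larger share of its pixels. With mutually exclusive
  masks no record is ever double-assigned.
* **Exact small-sample tests.** Mann–Whitney p-values are exact for
  tie-free data, exactly enumerated for tied data when the assignment count
  is ≤ 2 × 10⁵, and tie-corrected normal otherwise; the route taken is
  recorded. Welch's t on two zero-variance groups with equal means returns
  p = 1 by convention; with unequal means it errors rather than fabricating
  infinity. Quartiles use linear interpolation between order statistics
  (R type 7) — IQR values depend on this convention, so it is fixed and
  stated.
* **Statistical unit.** Captions in this literature are ambiguous about
  whether the unit is the punctum (thousands) or the biological repeat
  (3–4). The pipeline tests at the punctum level, which is what a single
  simulated field provides; per-field aggregation is a one-`aggregate()`
  step on the tidy output and intentionally not hard-wired.

## Problem sizes used in the shipped checks

The test-suite checks run at sizes chosen to make their statistical
assertions meaningful while staying desk-scale: morphometry recovery on
~600 isolated spots in a 1024² field; the planted postsynaptic deficit
(target FWHM median 55 nm and amplitude median 90 in the PSD vs 80 nm/150
elsewhere) on 380 synapses (≥ 500 ground-truth spots per zone); the matched
null calibration on 100 seeds of 16-synapse fields; type-I error of the
parametric tests on 1000 null replicates. The acceptance script reruns the
same computations from a user-supplied seed.

## Known limitations

* Segmentation-based counts undercount at high density (merging) and drop
  sub-threshold domains; the recovery tolerances quantify this at the
  default conditions only.
* The Gaussian RSF cannot represent asymmetric or heavy-tailed resolution
  mismatches.
* Co-registration of channels is assumed, never estimated.
* `extract_nanodomains()` at different zones shares one global target
  threshold; zone-local thresholds are not implemented.
* The simulator's planted "independent fraction" uses a hard guard radius;
  real partner proximity is graded.

## A minimal run

```{r example, eval = FALSE}
cfg <- zone_run_config(
  sim = sim_config(field_size_px = c(512, 512), n_synapses = 40, seed = 7),
  outdir = "zone_run")
res <- run_zone_analysis(cfg)
head(res$nanodomains)
res$stats$length_kw_dunn
```
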