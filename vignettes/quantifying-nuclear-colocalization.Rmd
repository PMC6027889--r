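---
title: "Quantifying locus-level chromatin-mark co-localization in single nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus-level chromatin-mark co-localization in single nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucoloc)
```

## The measurement

The assay this package quantifies pairs two live-cell reporters inside one
nucleus: a diffuse channel (YFP) from a modification-specific mintbody
that distributes over chromatin according to where its target histone mark
is, and a punctate channel (CFP) from fluorescent LacI bound to a LacO
array marking one locus. The scientific question — *is the marked locus
enriched for the modification?* — becomes two image-analysis questions per
nucleus:

* how correlated are the two channels across the nucleus (Pearson's r over
  nucleus pixels), and
* does a detected reporter spot coincide with the locus spot (a binary
  call)?

Cohorts of nuclei from different genotypes/conditions are then compared on
mean PCC (Student's t) and call frequency (Fisher's exact test).

Two assumptions are inherited from the assay design and worth keeping in
view. First, nuclei are treated as independent observations; animal-level
clustering is not modelled. Second, PCC is computed on raw intensities;
because Pearson's r is invariant under per-channel positive affine maps,
uniform background subtraction or detector gain cannot change it, which is
what makes the statistic comparable across cells that express the reporter
at very different levels.

## Segmentation

The nucleus edge is found from the diffuse channel alone: Otsu's
between-class-variance maximization on a 256-bin histogram, binarization
above the threshold, largest 8-connected component, hole filling. Class
means use bin midpoints and ties break toward the lower threshold, so the
result is reproducible against an exhaustive search over all candidate bin
edges. Hole filling matters because the locus or dark heterochromatin can
punch holes in the thresholded region, and the correlation domain must be
the full nuclear area, not the bright subset. "Auto-thresholding" is a
family, not an algorithm; Otsu is the canonical member, and the chosen
method name is recorded in every mask so isodata-style variants could be
added behind the same interface without ambiguity in old results.

Two guards define segmentation failure rather than a wrong answer:

* `min_area_px` (default 50 px): the largest component must be a plausible
  nucleus, not a noise speck.
* `min_separation` (default 3): the foreground/background mean gap must be
  at least 3 pooled within-class standard deviations. A threshold always
  exists, even for a structureless noise image — and on such an image the
  spurious foreground percolates into one large component that would sail
  past any area test. Requiring genuinely separable intensity classes is
  what makes "there is no nucleus here" a reportable outcome.

Restricting PCC to the mask is not cosmetic: including extranuclear
background correlates the channels through shared nucleus geometry and
inflates r. One of the package's property tests checks exactly this
divergence between whole-frame and in-mask PCC.

## Spot detection and the co-localization call

The visual judgment — "same morphology and location" — is operationalized
as multi-scale Laplacian-of-Gaussian blob detection in both channels,
restricted to the mask, followed by greedy nearest-neighbour centroid
matching. Default detection parameters:

* `sigma_range = c(1, 4)` px with 3 geometric scales (1, 2, 4 px — octave
  spacing): locus spots in this kind of data are diffraction-limited blobs
  a few pixels wide.
* `peak_rel_threshold = 0.3`: a peak must reach 30% of the strongest
  in-mask response, discarding shoulders of the dominant blob.
* `min_snr = 5`: a peak must also exceed 5× the median-absolute-deviation
  noise level of the in-mask response at its scale. This floor is the
  load-bearing half of the rule: a purely relative threshold cannot
  express "no spot present", because every image has *some* maximum, and
  in a spotless channel that maximum is a noise fluctuation surrounded by
  dozens of comparable ones. The MAD floor is what lets the unmarked
  (enrichment-zero) condition produce few or no reporter spots and hence
  a low false-call rate.
* `d_max_px = 2`: matched centroids must lie within 2 px, a closed bound
  (exactly 2 px matches). Calls are therefore monotone in `d_max_px`.
  Requiring a morphology (scale) match in addition to position is
  deliberately off by default: position alone is the lenient, auditable
  criterion, and the spot tables retain each spot's scale for stricter
  post-hoc filters.

Centroids are refined to sub-pixel precision by a 1-D parabolic fit per
axis on the response around the peak (offsets clamped to ±0.5 px), and
detections closer than one scale-sigma to a stronger one are suppressed.
LoG kernels are zero-meaned so a constant image yields an exactly zero
response, and convolution is circular via FFT with kernels cached per
image size.

## Cohort statistics

`fisher_exact_2x2()` follows the standard two-sided convention: with
margins fixed, sum hypergeometric probabilities of all tables no more
probable than the observed one (relative tolerance 1e-7 on that
comparison, guarding floating-point ties). `students_t_two_sample()` is
the classic pooled-variance t with n₁ + n₂ − 2 degrees of freedom —
equal-variance rather than Welch, because that is the test conventionally
reported with this assay. Both tests are two-sided — the conservative
reading where sidedness is not specified — and no multiple-testing
correction is applied: comparisons are reported as single pairwise
contrasts with raw p-values plus an α = 0.01 flag, mirroring how such
figures are annotated.

Nuclei whose PCC is undefined (zero variance in a channel inside the
mask) are excluded from mean-PCC statistics but retained, with call
`FALSE` unless spots matched, in the frequency denominators; segmentation
failures likewise stay in the denominator. Nothing is silently dropped —
every input nucleus appears in the results table with an explicit status.

## The synthetic image generator

The generator exists so that segmentation, PCC, calling and the cohort
statistics can each be validated against ground truth. Its noise-free
expectation is, for a nucleus disk of radius R at centre c:

* YFP: `bg_out` outside the disk; inside,
  `E · (yfp_nuc + Σ territory Gaussians + e · yfp_nuc · G_spot)` where `E`
  is the per-nucleus expression factor, `e` the enrichment, and `G_spot` a
  unit-peak Gaussian at the locus position;
* CFP: `bg_out + cfp_amplitude · G_spot` everywhere.

Noise is Poisson on the photon-scaled expectation (`poisson_gain` photons
per intensity unit) plus zero-mean Gaussian read noise (`read_sigma`),
clipped at zero and quantized to integer detector units — quantization is
what a camera does, and it is what makes the 16-bit TIFF round trip
bit-exact. Noise-free images skip quantization so they equal the analytic
expectation, which several oracle tests rely on.

Reference conditions (the defaults):

| parameter | default | rationale |
|---|---|---|
| `image_size` | 128 × 128 px | per-nucleus crops; 640 × 640 and 512 × 256 acquisition geometries remain available by argument |
| `nucleus_radius` | 40 px | a nucleus filling a 60× confocal crop |
| `bg_out` / `yfp_nuc` | 10 / 100 a.u. | 10:1 nuclear contrast, comfortably segmentable |
| `expression_scale_sd` | 0.3 | lognormal (mean 1) per-nucleus expression factor; reporter expression differs visibly cell-to-cell and animal-to-animal in this assay |
| `territory_count`, `territory_sigma` | 2, R/3 | broad chromosome-territory enrichments emulating the X-territory pattern, without claiming biological geometry |
| `spot_sigma_cfp` | 2 px | diffraction-limited locus spot |
| `cfp_amplitude` | 300 a.u. | bright, reliably detectable marker |
| `poisson_gain`, `read_sigma` | 1, 2 | shot-noise-dominated imaging with mild read noise |
| `enrichment` | preset-dependent | reporter amplitude at the locus, in multiples of `yfp_nuc` |

Enrichment is defined *relative* to the diffuse nuclear level so the
expression factor multiplies the whole in-nucleus YFP expectation; PCC,
being affine-invariant, then has the same expectation in dim and bright
cells — the property that makes pooling differently-expressing nuclei
into one cohort meaningful.

The condition presets map assay contrasts onto enrichment levels chosen
once to reproduce ordering and sign, not absolute values: `her1` (strongly
marked array, e = 4), `laco_only` (unmarked array, e = 0), `abts1b`
(weakly marked, e = 0.5), `rex1` (recruitment-element rescue, e = 3),
`male` (e = 0 with no X-territories, emulating the uniform nuclear signal
of cells lacking territory-level enrichment).

One generator design point deserves emphasis: the random locus position is
uniform over the **entire** nucleus disk. Confining it centrally (an
earlier draft used 70% of the radius) makes both channels share a central
radial profile — territories are interior, so a centrally-biased spot sits
where YFP expectation is high — and the "null" condition then has a
structurally positive mean PCC. Spatial unbiasedness of the locus position
is what makes enrichment = 0 a true null, and the package's calibration
test (mean in-mask PCC within 3 standard errors of zero across 200
unenriched nuclei) depends on it.

Time-lapse series emulate 30-minute-cadence imaging over 5 hours
(11 frames): the locus performs a Gaussian random walk (`walk_sd` px per
frame) reflected radially at a boundary two spot-sigmas inside the nucleus
edge, the expression factor and territory layout are drawn once per cell,
and pixel noise is independent per frame. Reflection (rather than an
error) at the boundary is the documented behaviour for large steps.

What the generator does **not** emulate: 3-D structure and z-sectioning,
photobleaching, chromatic shift between channels, nucleoli or other
unmodelled dark compartments, multiple nuclei per field, more than one
locus spot, and cell movement. Passing tests therefore demonstrate that
the pipeline's logic and statistics behave correctly under a faithful 2-D
image-formation model — they do not certify performance on real microscope
data, where segmentation and spot detection face artifacts the simulator
deliberately omits.

## Determinism and numerical choices

Every stochastic step is seeded. Cohorts derive one seed per nucleus from
the master seed, group index and nucleus index through a fixed affine
counter (kept below 2³¹), so cohorts are reproducible and nuclei are
independent without seed collisions. Latent variables are drawn in a fixed
order (expression factor, territory centres, spot position, then noise) so
the seed fully determines the image. Ties in the Otsu objective go to the
lower threshold; spot suppression processes peaks in descending response
order; greedy matching processes locus spots in descending response order
and consumes each reporter spot at most once. Fisher's p is computed
directly from `dhyper` with the ≤ (1 + 1e-7) probability comparison, and
is checked in the test suite against both exhaustive enumeration from
binomial coefficients and `stats::fisher.test`.

## Validation scale

The acceptance checks run at the package's reference sizes: 1,000 random
masked image pairs for the PCC oracle, 100 random histograms for the Otsu
oracle, every 2×2 table with both group sizes ≤ 30 for Fisher (245,025
tables), 20 seeds at signal-to-noise 5 for segmentation, 200 nuclei for
null calibration, 200 two-cohort repeats for empirical type-I error,
50 nuclei per level on the enrichment grid {0, 0.5, 1, 2, 4}, 100 repeats
of the 25-vs-25 contrast for power, and a 50-nucleus mixed cohort with a
60% enriched fraction for frequency recovery. These sizes were chosen as
the smallest at which the binomial/standard-error bounds in those checks
are meaningful.

## Known limitations

* Single nucleus per image; no instance segmentation.
* The call threshold `d_max_px = 2` presumes roughly diffraction-limited
  spots at this pixel scale; strongly oversampled data should scale it.
* Welch's t, mixed-effects worm-level models, and Manders/Costes-style
  coefficients are out of scope; the spot tables and per-nucleus PCC give
  downstream users the raw material for such extensions.
* Which auto-threshold variant a given published macro used is typically
  unstated; results can differ slightly between variants, which is why the
  method name travels with every mask.
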