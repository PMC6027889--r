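# nucoloc

Per-nucleus two-channel co-localization quantification for live-cell
imaging of locus-specific chromatin marks.

## The problem

A popular way to ask "does *this* locus carry *this* histone modification
in *this* living cell?" is to combine two fluorescent reporters: a
**mintbody** (a genetically encoded antibody fragment that binds the
modification, e.g. H4K20me1, and fills the nucleus diffusely, YFP channel)
and a **LacO/LacI** locus tag (an array of Lac-operator repeats at the
locus of interest, bound by fluorescent Lac repressor, which appears as a
single sharp spot, CFP channel). If the locus is modified, the mintbody is
locally enriched at the LacI spot; if not, the spot sits in — or is even
excluded from — the diffuse nuclear signal.

`nucoloc` turns single-nucleus two-channel confocal images of this assay
into numbers:

1. **Nucleus segmentation** — the diffuse mintbody signal is
   auto-thresholded (Otsu's between-class-variance criterion on a 256-bin
   histogram), binarized, reduced to its largest 8-connected component and
   hole-filled, identifying the nucleus edge.
2. **Pearson correlation (PCC)** — for each nucleus, the pixel-wise
   Pearson correlation between the two channels inside the nucleus mask:

   r = Σᵢ(Yᵢ − Ȳ)(Cᵢ − C̄) / √( Σᵢ(Yᵢ − Ȳ)² · Σᵢ(Cᵢ − C̄)² ),

   with i over mask pixels. Positive r indicates co-localization; r near 0
   indicates no association.
3. **Binary co-localization call** — multi-scale Laplacian-of-Gaussian
   spot detection in both channels, then a nearest-neighbour match of spot
   centroids: a nucleus is called co-localized when a reporter spot lies
   within 2 px (default) of a locus spot. This operationalizes the visual
   "same morphology and location" judgment.
4. **Cohort statistics** — groups of nuclei (genotypes, conditions, sexes)
   are compared on the frequency of co-localization calls (two-sided
   Fisher's exact test) and on mean PCC (two-sided equal-variance
   Student's t-test), with significance flagged at α = 0.01.

Because such microscope data are rarely public, the package ships a fully
seeded **synthetic image generator** that emulates the assay — a disk
nucleus with diffuse reporter signal, chromosome-territory enrichments, a
locus spot with tunable reporter co-enrichment, per-cell expression
variability, Poisson + Gaussian noise, and optional 11-frame time-lapse
series — with complete ground truth, so every stage of the pipeline is
testable without a microscope.

## Worked example

```r
library(nucoloc)

pairs <- simulate_cohort(list(
  cohort_group("her1",      preset_params("her1"),      12),   # enriched locus
  cohort_group("laco_only", preset_params("laco_only"), 12)),  # unmarked array
  seed = 42)
records <- analyze_cohort(pairs)
head(coloc_results(records)[, c("nucleus_id","status","area_px","pcc","coloc_call")], 3)
#>   nucleus_id status area_px       pcc coloc_call
#> 1   her1_001     ok    5025 0.6493653       TRUE
#> 2   her1_002     ok    5025 0.4863843       TRUE
#> 3   her1_003     ok    5025 0.6888308       TRUE

compare_groups(records, "her1", "laco_only")
#> <group_comparison> her1 vs laco_only (alpha = 0.01)
#>   coloc frequency: 12/12 (100%) vs 1/12 (8%), Fisher p = 9.61e-06 *
#>   mean PCC: 0.588 (sd 0.095, n 12) vs -0.014 (sd 0.064, n 12), t = 18.20, p = 9.52e-15 *
```

Every simulated nucleus was segmented (5025 px ≈ the true disk of radius
40 px), the enriched cohort shows strongly positive per-nucleus PCC and
100% co-localization calls, the unmarked cohort is near zero and 8%, and
both cohort readouts are significant at α = 0.01.

`run_analysis()` drives the same pipeline end-to-end from a config (YAML
or list) and writes `results.csv`, `comparisons.json`, `config.yaml` and
`run.log`; `run_timelapse()` analyzes an 11-frame, 30-minute-cadence
series and reports per-frame PCC plus the fraction of frames called
co-localized. Cohorts round-trip losslessly through two-page 16-bit TIFFs
with a manifest CSV (`write_cohort()` / `read_cohort()`). A thin CLI with
`simulate`, `analyze`, `compare` and `timelapse` subcommands lives at
`inst/cli/nucoloc.R`.

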