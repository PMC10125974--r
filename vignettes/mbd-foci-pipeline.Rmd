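---
title: "Methods: from MBD foci images to methylome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MBD foci images to methylome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igemscreen)
library(dplyr)
```

## The assay this package models

Human iPS cells carrying a methyl-CpG-binding domain (MBD) fused to a red
fluorescent protein report the nuclear spatial concentration of DNA
methylation as punctate foci: the more (and the brighter and larger) the
foci, the more concentrated the methyl-CpG signal.  A chemical screen reads
each treated well out as four parameters — nuclei count (blue channel,
Hoechst) plus foci count, summed focus area and summed background-corrected
focus intensity per nucleus (red channel) — each expressed as a ratio to a
0.1% DMSO vehicle control.  Downstream, chemicals are clustered into
hypomethylation (A), hypermethylation (B) and intermediate (C) categories,
their public toxicology-database activities are harmonised and ranked by
random-forest importance against the imaging parameters, and selected agents
are profiled genome-wide (array beta values, RRBS counts) and on a 100-gene
stemness expression panel.

Because the raw plates, arrays and sequencing runs are not shipped with the
package, a synthetic generator (`sim_config()` and the `sim_*()` family)
emulates every input with known ground truth.  All tests and the acceptance
script run against that generator.

## Image quantification

`segment_nuclei()` implements the nuclear segmentation step as Gaussian
smoothing (sigma 2 px), Otsu thresholding, hole filling and a
distance-transform watershed to split touching nuclei; border-touching
nuclei and regions outside a plausible area band are discarded.  Cell
segmentation is deliberately folded into nuclear segmentation: every
reported parameter is nuclear, so a separate cytoplasmic mask would add
parameters without adding information.  A guard rejects fields with no real
foreground/background contrast (a noise-only field otherwise still yields
an Otsu split of the noise).

`detect_foci()` is two-stage.  A difference-of-Gaussians band-pass
(`spot_sigma_px`, default 1 px against 2.5x that) *seeds* candidate spots
at pixels exceeding the nucleus median plus `k_threshold` (default 5)
robust standard deviations of the band-passed signal.  The focus footprint
itself is then measured on the **raw** image — pixels above the nucleus
median plus `k_measure` (default 2.5) robust sd — because band-pass
filtering convolves the spot with the filter kernel and would report
footprints of width `sqrt(sigma_spot^2 + sigma_filter^2)`, compressing any
area change toward one.  Background statistics exclude a dilated margin
around the seeds so that nuclei with many foci do not estimate inflated
thresholds (that coupling would make the area read-out depend on the focus
count).  Touching foci are split by an intensity watershed whose tolerance
is expressed in robust-sd units; every cut being relative to per-nucleus
robust statistics makes detection commute exactly with rescaling the
channel, which the tests assert.  Integrated intensity is
background-subtracted (nucleus median), so ratios to control cancel
residual offsets; we report integrated rather than mean intensity because
both are ratio-equivalent under pure amplitude scaling and integrated is
the natural "amount of signal" measure.

`measure_well()` sums over up to nine fields: nuclei count is the total;
each foci parameter is the per-nucleus mean with zero-foci nuclei counted
in the denominator.  Wells without nuclei are flagged undefined rather
than silently zero.

## What the image generator emulates — and what it does not

`sim_plate_images()` renders soft-edged nuclear disks plus Gaussian foci
over additive Gaussian noise.  Three modelling choices matter:

* **Multiplier semantics.** A chemical's effect multipliers apply to the
  *measured per-nucleus* parameters.  The generator therefore scales the
  Poisson focus count by the count multiplier, the per-focus footprint by
  area/count and the per-focus amplitude by intensity/area, so the
  per-nucleus sums scale by exactly (intensity, area, count).  Naively
  multiplying per-focus brightness and count independently would make the
  measured intensity ratio the product of the two.
* **Focus placement.** Foci repel each other softly (3x the focus radius,
  with a bounded number of retries).  Distinct MBD puncta are separate
  chromatin structures and rarely coincide; without the repulsion, Poisson
  crowding merges spots at a rate that grows with the count multiplier and
  biases count ratios toward one.  Nuclei where placement still ends up
  crowded are flagged in the ground truth so recovery tests can stratify.
* **Deterministic seeding** (`seeding_cv = 0` by default).  Per-well cell
  seeding variability is not reported for the assay, so it is exposed as a
  parameter rather than silently fixed.

Not modelled: illumination fields, point-spread optics, 3-D structure,
plate-position effects, or vendor image formats.  Recovery results on this
generator show that the measurement pipeline is unbiased under its
assumptions; they do not certify performance on real microscopes.

## Screen normalisation, clustering and categories

`ratio_to_control()` divides treated by control replicate means per
parameter with a delta-method standard error.  `viability_gate()` flags
chemicals whose nuclei ratio falls below 0.7 — "more than 70% viability"
is implemented inclusively (a ratio of exactly 0.70 passes), and the
boundary is configurable.  `cluster_chemicals()` uses 1 − Pearson
correlation between the four-ratio profiles with average linkage, cut at
k = 3; `assign_categories()` labels clusters by their mean foci ratio
(B above 1 + delta, A below 1 − delta, else C, delta = 0.05), forcing the
three labels distinct by ranking when k = 3.  We cluster first and label
second; the category definitions read naturally in that order.

A correlation distance on four values sees only profile *shape*.  The
hypo- and hyper-profiles are near-perfect anti-correlates — (−,−,−,+) vs
(+,+,+,−) after centering — but a truly null intermediate profile has no
shape at all: its centred direction is pure noise, and with dozens of such
chemicals some would inevitably land on the A or B shape and be absorbed
into those clusters.  The generator therefore gives intermediate agents a
small, reproducible signature (intensity +6%, area −6%, count and nuclei
unchanged) that is orthogonal, after centering, to the A/B axis.  That is
an explicit modelling decision: it encodes the view that "intermediate
epigenetic agents" perturb foci morphology subtly but consistently.  The
100% category recovery the tests demonstrate holds under that assumption
and the default noise (sd 0.02); it is not a general property of
correlation clustering on null profiles.

`dose_response_test()` wraps one-way ANOVA with Tukey honest significant
differences for concentration series.  `steel_dwass()` implements the
all-pairs nonparametric comparison: each pair is re-ranked jointly, the
rank-sum is standardised with the tie-corrected variance, and
`sqrt(2)|t|` is referred to the studentized range with k groups
(two-sided).  With k = 2 this collapses to the tie-corrected normal
Wilcoxon test, which the tests verify to 1e-6.  Against a Monte-Carlo
joint-permutation oracle the adjusted p agrees to < 0.01 in the tails; in
the mid-p range at eight observations per group the normal approximation
is liberal by up to a few hundredths — a property of the test itself, not
of this implementation — and the property tests document that band.

## Database harmonisation

`label_genotoxicity()`, `label_carcinogenicity()` and `merge_tox21()` are
total functions over closed vocabularies, and the tests enumerate every
input combination.  Two readings deserve note.  First, the Tox21 merge of
a parent compound with its hydrochloride maps the pair {active, inactive}
to *inconclusive* — we read the harmonisation rule literally, flag it
here, and keep the mapping in one small function so a different reading is
a one-line change.  Second, for IARC groups 2B/3 with *no* animal
records, "negative for all experiments" is vacuously true; we return
`inconclusive` and note the ambiguity.  Chemicals are joined across
databases only by an explicit identifier column — no fuzzy name matching —
trading recall for reproducibility.

## Importance ranking

`encode_activities()` codes labels ordinally (active 1, inconclusive 0.5,
inactive 0) with column-median imputation of missing cells, preserving
the full chemical set; one-hot coding is available as an alternative since
the right encoding is genuinely open.  `rf_importance()` fits a regression
random forest (500 trees, p/3 features per split) of a continuous imaging
ratio on the encoded activities and ranks by total node-impurity decrease
("increase in node purity").  Feature columns are put in a canonical order
before fitting and ties are broken by activity name, so the ranking is
deterministic given the seed and invariant to how the caller ordered the
columns.  The synthetic snapshot plants an enrichment of active
"CAR antagonist" and "H2AX phosphorylation" labels among hypermethylation
agents (odds ratio well above 5), and the tests check those activities
surface in the top ranks for the foci-intensity response.

## Methylome analytics

Beta values are floored at `eps = 1e-3` before log2 ratios.  The signed
differential score is `sign(delta_beta) * (-10 log10 p)`; a site is called
hypermethylated when the score strictly exceeds the score at p = 0.05
(13.0103, printed as 13), i.e. exactly when p < 0.05 with a positive
shift.  With one array per condition there is no within-condition
replication, so p comes from a declared Gaussian measurement-noise model
of beta (`sigma_beta = 0.03` per array): `p = 2 pnorm(-|db|/(sqrt(2)
sigma_beta))`.  This is a documented substitute for an unpublished
vendor model; it is monotone in |delta beta|, so threshold behaviour — the
part the pipeline depends on — is faithful.

`region_distribution()` reports called-site proportions per RefGene group
and CpG context (islands / shores / shelves / open sea);
`gene_panel_methylation()` averages log2 ratios over each panel gene's
probes; `common_hyper_genes()` intersects genes with a called site whose
beta fold change strictly exceeds 10 in both focal treatments (the fold
measure is a parameter; whether "fold change" means the beta ratio or a
score-derived quantity is not decidable from the assay description, and
the beta ratio is the default).  `methylation_expression_funnel()` counts,
within the commonly down-regulated genes, those gaining promoter
methylation under either and under both treatments.  Two choices make this
count stable.  The gain measure is the log2 ratio of the gene's *mean
methylation rate* (average the betas, then take the ratio) rather than the
per-site mean of log2 ratios: log ratios at nearly unmethylated probes
have heavy-tailed noise, and a single low-beta probe can otherwise flip a
gene's call.  And the threshold is `min_effect = 0.1` rather than a bare
"greater than zero": a zero threshold would classify unaffected genes by
the sign of their noise (about half would land positive), whereas 0.1 sits
several standard errors above the rate-ratio noise and well below the
planted effects.  The per-site mean is still reported alongside.

## RRBS

`rrbs_filter()` removes bases with coverage strictly below 10 and above
the per-sample 99.9th percentile (PCR-artifact guard); the band between
is never touched, which a test asserts.  `rrbs_normalize_coverage()`
scales each sample's coverage to the median of per-sample medians and
recomputes methylated counts from each site's fraction on the new
coverage, so the per-site fraction moves by at most 0.5/coverage — the
exact rounding bound.  `rrbs_tile()` sums counts in fixed 1000-base
non-overlapping windows anchored at position 1, strands merged
(non-directional protocol), conserving totals.  `rrbs_gene_methylation()`
pools the sites inside each tracked gene interval and, as for the array
panel, reports both the per-site mean log2 ratio and the log2 ratio of
pooled methylation rates, the latter being the confirmation measure.  The
confirmation threshold for a gene-level gain is `rrbs_min_effect = 0.3`
log2 — larger
than the array threshold because binomial counting noise at ~30-60x
coverage is far coarser than array noise; 0.3 sits more than four standard
errors above a null gene's mean and more than five below the planted
gains.

The RRBS generator draws coverage from a negative binomial (size 5, mean
30) with a 0.2% admixture of 12x-inflated sites to exercise the
percentile filter, and binomial methylated counts.  The tracked genes use
40 sites at doubled coverage — promoter CpG islands are exactly the
regions RRBS enriches — so gene-level calls are statistically stable.

## Expression panel

`expression_analysis()` forms per-gene RPKM fold changes against the
vehicle control (zero-control genes are flagged and excluded), clusters
treatments by Euclidean distance with average linkage, and reports the
genes decreased under both focal treatments.  The generator draws
repressed genes' true fold changes from (0.3, 0.8) and all other panel
genes from a mildly induced band (1.15, 1.5) under those treatments.  The
margin is deliberate: with fold changes symmetric around 1, measurement
noise alone would push roughly a quarter of unaffected genes below 1 in
both treatments and the "commonly decreased" set would not be a stable
quantity.  The cost is that the generator does not probe behaviour at the
fold-change-equals-1 boundary; the trivial-case tests cover that boundary
directly instead.

## t-SNE

The embedding (`tsne_embed()`) is an exact t-SNE written for the handful
of samples this pipeline embeds: perplexity calibrated by bisection
(capped at (n−1)/3, default 5), symmetrised affinities, early
exaggeration, momentum gradient descent, PCA initialisation plus a small
seeded jitter.  Fixed seed, fixed coordinates; duplicated samples embed as
the closest pair, and the hypermethylation agents separate from the other
treatments on the default generator, which the tests check with a
within/between distance comparison.

## Orchestration and problem sizes

`run_pipeline()` executes simulate → foci → screen → labels → assoc →
methylome → rrbs → expr → report, writing each stage's tables as CSV, a
resolved YAML copy of the configuration, and a plain-text log of every
threshold actually applied.  Reruns under the same configuration are
byte-identical; every random draw derives from the master seed plus a
stable per-generator offset, so adding one generator never perturbs the
draws of another.

Default problem sizes are chosen to keep a full run on a single CPU in
tens of seconds while leaving every recovery margin comfortable: 50,000
array probes, 20,000 RRBS sites per sample, 135 chemicals, and an imaging
stage of a few wells at 256x256 px with eight nuclei per field.  The
recovery checks for the imaging ratios use 20 wells of five fields per
arm, which puts the Monte-Carlo standard error of a ratio near 3%,
comfortably inside the 10% recovery band.

## Known limitations

* Category recovery depends on the intermediate-agent signature discussed
  above; truly null profiles cannot be recovered by shape-based
  clustering, and an intermediate chemical whose noise realisation happens
  to cancel the signature can still (rarely) be absorbed into a
  neighbouring cluster.
* The DiffScore p-model is a declared stand-in, not the vendor algorithm.
* The imaging model omits optics and illumination artefacts; absolute
  intensities are arbitrary units and only ratios are meaningful.
* Steel-Dwass adjusted p-values inherit the liberal mid-range behaviour of
  the normal approximation at very small group sizes.

```{r quick-tour, eval = FALSE}
# a complete run into a temporary directory
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)
res$report$category_counts   # A = 63, B = 36, C = 36
res$report$funnel            # 28 / 16 / 9
```
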