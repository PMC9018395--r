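---
title: "Quantifying heterogeneous MOMP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneous MOMP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mompscreen)
```

## The measurement problem

Dual-reporter apoptosis lines make mitochondrial outer membrane
permeabilization (MOMP) visible cell by cell. Venus-BAX is diffuse in the
cytoplasm of healthy cells and condenses into bright mitochondrial puncta
when apoptosis engages; OMI-mCherry sits inside mitochondria and is released
and degraded once a mitochondrion permeabilizes. Crossing the two readouts
yields four per-cell states:

* `BAX_POSITIVE` — BAX puncta, no retained OMI: complete MOMP (apoptotic);
* `INTACT` — OMI puncta, no BAX puncta: no MOMP;
* `DOUBLE_POSITIVE` — both kinds of puncta, *not colocalized*: some
  mitochondria permeabilized while others did not (heterogeneous MOMP, the
  imaging signature of the sublethal "minority MOMP" state);
* `NONDETERMINED` — reporter fluorescence below the analysis floor in both
  channels; these cells are segmented and counted but carry no phenotype
  information.

The package turns raw three-channel fields (DAPI / YFP / Texas Red) into
these labels, aggregates them into per-well fractions and per-gene screen
scores, and quantifies the companion clonogenic-survival assay.

## Imaging front end

**Nuclear segmentation** (`segment_nuclei()`): Gaussian smoothing
(`nucleus_smooth_sigma`, default 1 px — strong enough to suppress camera
noise, weak enough that small apoptotic nuclear fragments keep most of their
peak intensity), Otsu threshold, hole filling, watershed on the distance
transform to split touching nuclei, and removal of objects below
`min_fragment_area` (12 px², debris). Objects smaller than
`normal_nucleus_min_area` (200 px²; a normal nucleus at this magnification
is ≥ ~250 px²) are fragment candidates; candidates whose centroids fall
within `fragment_group_radius` (15 px) are merged by single linkage into one
nucleus object with `fragment_count > 1`. A nucleus is *fragmented* when its
total area is below `normal_nucleus_min_area`. Normal-size nuclei are never
merged, so two genuinely adjacent nuclei cannot collapse into one.

**Cell regions** (`assign_cell_regions()`): each nucleus mask is expanded by
at most `cell_expansion_radius` (20 px ≈ 13 µm at 0.65 µm/px); collisions
are resolved by geodesic propagation from the nucleus masks, i.e. a
nearest-nucleus rule. Published screen analyses rarely state how granules
are attributed to cells; nearest-nucleus expansion is our declared
substitute, and region disjointness is enforced by construction and checked
in the tests.

**Granule detection** (`detect_granules()`): a white top-hat at scale
`granule_tophat_radius` (7 px) removes everything wider than a punctum —
including the diffuse cytoplasmic reporter signal — after which pixels above
`granule_peak_cut` (500 counts) form candidate support, split by an
intensity watershed. A candidate is kept only if

1. its equivalent diameter `2*sqrt(area/pi)` lies in
   `granule_diameter_range` (2–10 px ≈ 1.3–6.5 µm, the mitochondrial puncta
   scale), **and**
2. its integrated background-free intensity exceeds
   `granule_intensity_threshold` (8000 counts), **and**
3. its centroid lies inside a cell region (it is then tagged with that
   cell's id).

The two keep-rules are deliberately the published granularity criteria — a
diameter window plus an integrated-intensity stringency threshold — with the
surrounding machinery (top-hat, watershed) being standard open
morphological operators. Because detection is linear in the image up to the
two thresholds, multiplying an image and all intensity thresholds by the
same constant leaves granule counts unchanged (tested); and raising the
intensity threshold or narrowing the diameter window can only remove
granules (tested).

## Phenotype rule and well summaries

`classify_cells()` applies, in order: both channels granule-positive →
`DOUBLE_POSITIVE`; only YFP → `BAX_POSITIVE`; only Texas Red → `INTACT`;
no granules and mean background-subtracted per-pixel intensity below
`fluorescence_floor` (40 counts) in *both* reporter channels →
`NONDETERMINED`; otherwise `INTACT`. Two choices deserve a note:

* *Fluorescent but granule-free cells are `INTACT`.* A cell with diffuse
  Venus-BAX and no puncta is by definition BAX-puncta-negative; treating it
  as intact is the conservative reading. The same goes for a cell whose OMI
  has been fully released and degraded in all mitochondria but whose BAX
  puncta fell below threshold — rare under default stringency.
* *Denominators include `NONDETERMINED` cells.* Well fractions are computed
  over all segmented cells, so the four label fractions sum to exactly 1;
  excluding nonfluorescent cells would silently rescale percentages between
  wells with different transfection efficiency. This sits behind the single
  summary function should a user want the other convention.

`summarize_wells()` pools cells across a well's imaging sites rather than
averaging per-site fractions, so a site with 5 cells does not get the same
weight as one with 80. Wells with fewer than `min_cells_per_well` (50)
analysed cells are flagged invalid and skipped downstream — a guard against
edge artifacts and toxic wells; the transfection-marker wells, which kill
most cells by design, fail this guard naturally.

## Screen statistics

**Z′ factor** (`compute_zprime()`):
`Z' = 1 − 3(σ_pos + σ_neg)/|μ_pos − μ_neg|` with sample standard deviations;
it errors rather than returning a value when either control group has fewer
than two wells or the means coincide. Note that Z′ measured on an imaging
assay scales with the number of cells imaged per well: the per-well
statistic is a binomial fraction, so halving the imaged cell count inflates
σ by √2. The acceptance script computes an assay Z′ from 6 simulated
etoposide-like and 6 untreated wells at 3 sites/well; at that depth values
around 0.3–0.7 are expected, and production-scale imaging (16 sites/well)
narrows the same assay toward the high values reported for real screens.

**Gene scores** (`score_genes()`): categories I and II use the fold-change
of %BAX-positive against the *same-plate* nontargeting-control mean — the
scale on which screen hits are usually described (threefold to fivefold
above or below controls); category III uses the raw %double-positive, the
scale on which sorted score plots are drawn. Replicate aggregation is
mean ± SEM (sd/√n); a gene reduced to a single valid replicate reports its
value with SEM 0 and `n_replicates = 1`. No plate normalisation beyond the
same-plate control division is applied (deliberately — the source protocol
applies none).

**Hit calling** (`call_primary_hits()`): a "10% cutoff in the score
distribution" admits two readings — top decile *by rank* or 10% of the
*numeric range*. Sorted-score figures with a tail cut support the rank
reading, so the default is `method = "rank"` with
`n_hits = floor(tail_fraction × n_genes)`; `method = "range"` is available.
Ties at the cutoff are broken lexicographically by gene id (deterministic)
and flagged `tie_degenerate`.

**Secondary screen** (`confirm_secondary()`): each of a gene's four
individual siRNAs is marked hit/miss by the same rule and threshold as the
primary category; `confirmed ⇔ hits ≥ 3`. Genes with missing siRNAs keep
the 4-sirna denominator (missing = non-concordant). If the per-siRNA
reproducibility is p, confirmation behaves binomially,
`P(confirm) = P(Bin(4, p) ≥ 3)` — the tests verify this calibration at
p = 0.9.

The manual-curation step that real screens interpose between primary hits
and the secondary assay (picking ~95 of ~200 hits by biological interest)
is not an algorithm; the pipeline emits the full ranked list and takes an
explicit include-list.

## Clonogenic arm

`measure_colony_area()` inverts the image (crystal-violet stain is dark on
a light background), restricts to the well disk, and applies Otsu's
threshold; covered area is stained pixels over disk pixels, in percent.
Only total area is reported, so colonies that merged during growth need no
splitting. Homogeneous wells (intensity spread below `min_contrast`) have
no two-class structure for Otsu; they are scored 0% or 100% by comparing
the median inverted intensity to `homogeneous_stain_cut`. Because Otsu on a
histogram over the data range commutes with affine intensity maps, the
measurement is invariant to global gain/offset changes when `min_contrast`
is scaled along (tested). An intensity-weighted readout is deliberately not
the default: the survival quantity is defined on area.

`compute_survival()` is `100 × treated/control` against the untreated
sorted population (100% growth); values above 100 are reported as-is.
`two_way_anova()` fits `survival ~ genotype * dose` by least squares and
reports Type II sums of squares (car::Anova), which handles the unbalanced
designs that arise when experiments are dropped; the interaction term is
included whenever every design cell has ≥ 2 replicates and dropped
otherwise, and both the inclusion and the dose pooling are explicit options
rather than silent defaults. A degenerate design with identical responses
everywhere reports F = 0, p = 1 (no evidence) instead of 0/0. The default
dose grid shipped with the simulator is 2.5 / 5 / 10 µM of ABT-737 or
ABT-199, the standard BH3-mimetic titration.

## The synthetic-data generator

The generator exists so that every stage above can be validated against
known truth; its defaults are the study conditions, not tuning knobs.

* **Geometry**: 1024 × 1024 px fields at 0.65 µm/px (a typical 20×
  widefield sensor), 16-bit; 384-well plates (16 × 24) with the two outer
  rows and columns excluded (240 usable wells, 8 of them controls → 232
  samples/plate, so 1318 genes need 6 plates per replicate).
* **Cells**: Poisson-distributed count per field (mean 60, inside the
  plausible 30–80 band for this cell density at imaging time — the true
  per-field density is not derivable from a seeding density of 1200
  cells/well, so it is a configurable estimate); centroids at least 40 px
  apart and 26 px from the border, so cells never overlap and puncta stay
  in-frame.
* **Nuclei**: soft-edged ellipses, radii 8–11 px (area ≈ 250–450 px²).
  Apoptotic (`BAX_POSITIVE`/`DOUBLE_POSITIVE`) cells carry a fragmented
  nucleus with probability 0.6: 2–4 blobs of radius 2.2–2.8 px within 6 px
  of the centroid. Each fragment (≈ 30–45 px² after edge growth) is well
  under 40% of the normal-nucleus minimum, and a maximal 4-fragment set
  stays below it in total, so the segmentation-side fragmentation rule is
  consistent with ground truth by construction.
* **Puncta**: 2-D Gaussians with FWHM equal to the true diameter (3–6 px)
  and peak amplitude 3000 ± 20% counts; counts per positive channel are
  `1 + Poisson(mean − 1)` (mean 8 for YFP, 10 for Texas Red) so a positive
  cell always has at least one punctum. Same-channel puncta keep ≥ 8 px
  separation; in `DOUBLE_POSITIVE` cells BAX and OMI puncta keep ≥ 6 px
  (non-colocalization, as seen in heterogeneous-MOMP cells).
* **Diffuse signal**: phenotype-dependent cytoplasmic haze (e.g. diffuse
  Venus-BAX at 200 counts in `INTACT` cells; zero in `NONDETERMINED`
  cells, which is what makes them nonfluorescent).
* **Noise**: constant background (200 counts) + Poisson shot noise at gain
  2 + Gaussian read noise (σ = 15). `noise_sigma = 0` switches the whole
  noise model off for pixel-exact contracts. Intensities are clipped to the
  16-bit range with a warning.
* **Determinism**: every (plate, well, site) derives its own RNG stream
  from the master seed by counter-based splitting (`derive_seed`), so any
  subset of a run regenerates bit-identically regardless of order.
* **Colony wells**: stained masks are sub-level sets of a signed distance
  field to colony seeds, with the level found by bisection against the
  requested covered fraction — realized coverage matches the request to
  ~0.1 percentage points, colonies merge naturally, and the ground-truth
  mask is recorded.

A linear illumination gradient is available
(`illumination_gradient = c(dy, dx)`) but flat illumination is the default.

What the generator does **not** emulate: optical point-spread functions,
cell crowding and overlap, autofluorescent debris, focus failures, or
plate-edge evaporation gradients. Passing tests therefore
demonstrate algorithmic correctness on clean, well-separated cells with
known truth — not robustness to every real-microscopy artifact. The
stringency thresholds exist precisely because real images contain debris
and background the synthetic fields lack.

## Numerical choices and degenerate inputs

* Coordinates are 0-free: (row, column), 1-based, pixel centres at integer
  positions; all raster objects are plain integer matrices.
* Blank or constant images segment to zero nuclei (not an error); flat
  reporter channels yield zero granules; empty wells are flagged invalid
  with a warning rather than dropped silently.
* Z′ errors on equal control means; survival errors on a zero-area control;
  ANOVA errors, naming the factor, when a factor has one level.
* Hit-calling ties are resolved lexicographically; `floor()` is used for
  the tail count so the call never exceeds the nominal fraction.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` run, per invocation: 20
default fields for detection fidelity (~1200 cells, ~11,000 puncta, with
per-cell phenotype agreement measured on the same fields); 12 simulated
wells for the assay Z′; 100 randomized control sets for the Z′ closed form;
brute-force hit-calling comparisons up to 10,000 genes; one 1318-gene
triplicate simulation with 20 spiked genes; colony wells at five covered
fractions; five randomized ANOVA designs against an independently computed
Type II table plus 1000 null simulations for type-I calibration; and two
byte-compared end-to-end image-mode runs at 288 × 288 px. These sizes were
chosen to exercise every contract at meaningful scale while keeping a full
validation run in the minutes range on a laptop core.

## Known limitations

* Granule-to-cell attribution uses nearest-nucleus regions; a commercial
  package's proprietary cell boundaries will differ near touching cells.
* The fragmentation rule is area-based; very large fragmented nuclei (total
  area above the normal minimum) would be scored normal.
* `NONDETERMINED` denominators, the rank-tail reading of the 10% cutoff,
  and control exclusion from the tail are conventions; all three are
  isolated behind single flags/arguments and documented above.
* The clonogenic arm begins at colony quantification: cytometry gating and
  sorting are upstream metadata (600 sorted cells per well), not analysis
  performed here.
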