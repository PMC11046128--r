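---
title: "Methods: CNN-scored morphological profiling screens on synthetic Cell Painting images"
author: "morphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN-scored morphological profiling screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen in one paragraph

An image-based genetic screen perturbs one gene per cell line (CRISPR
knockout in an arrayed format), stains the cells with the five-channel Cell
Painting panel (Hoechst/nucleus, concanavalin A/endoplasmic reticulum,
SYTO 14/cytoplasmic RNA and nucleolus, phalloidin + WGA/F-actin-membrane-
Golgi, MitoTracker/mitochondria), images many fields per well, and asks a
simple question per gene and channel: *how well can a classifier tell this
line's single cells apart from non-targeting control cells?* The test-set
AUC of that classifier is the phenotype statistic — 0.5 means the knockout
is morphologically indistinguishable from control, 1.0 means perfectly
distinct. Averaging AUC over channels and replicates ranks genes by overall
morphological effect; the per-channel maximum attributes the effect to an
organelle; and comparing the AUC record sets of two genes under one GWAS
locus prioritizes the likelier causal gene.

`morphoscreen` implements this pipeline end to end, with a synthetic
image generator in place of the (undeposited) donor trabecular-meshwork
images, so that every stage is exercisable and testable against planted
ground truth.

## The synthetic image generator

`render_field()` draws non-overlapping elliptical cells and renders each
channel with parametric 2-D primitives rather than optical physics:

* **nucleus** — a smooth ellipse with a logistic soft edge and mild radial
  falloff;
* **endoplasmic reticulum** — band-limited Gaussian-filtered noise over the
  cytoplasm, suppressed inside the nucleus, plus a small number of brighter
  sheet fragments; the channel's effect axis is an ER-stress-like
  fragmentation (the continuous reticulum dims while fragments multiply);
* **RNA / nucleolus** — Poisson-distributed cytoplasmic puncta plus one or
  two bright nucleolar blobs;
* **actin / membrane / Golgi** — a boundary ring along the cell outline,
  Poisson-count filament strokes, and a perinuclear patch;
* **mitochondria** — elongated Gaussian strokes scattered in the cytoplasm,
  whose count, length and brightness are the mitochondrial parameters.

This is deliberate: the screen statistic only needs each channel to carry an
independent, perturbable morphology axis. The per-channel effect size
$\delta \ge 0$ acts multiplicatively on a small named parameter set per
channel (`delta_parameter_map()`); $\delta = 0$ reproduces the control
parameterization bit for bit, which is what makes null calibration a
meaningful test. Density-type parameters (mitochondrial punctum count,
filament count, RNA puncta) scale as $1 + \delta$ and carry most of the
signal; amplitude weights are kept small (e.g. mitochondrial brightness
$1 + 0.15\,\delta$) so that strong effects change *morphology* without
saturating the detector range.

Cell size is drawn from a truncated log-normal, as in real growing
populations. Beyond realism this skewed, shared covariance axis has a
statistical job: it anchors the QC filter's standardized reference profile
to the same direction in every line (see below), so that cell retention is
governed by genuine population structure rather than line-specific noise.

Nuisance variation mimics the confounders the real screen worries about: a
log-normal per-well multiplicative gain, a per-plate (batch) additive
background, and Gaussian read noise, all injected identically into control
and knockout lines so a classifier cannot exploit them. Because every image
is additionally standardized to zero mean and unit variance before
training, absolute brightness carries no label information by construction.

An `outlier_fraction` of cells per line is rendered as degenerate objects.
The default kind, `debris`, is an autofluorescent speckle blob whose
per-channel brightness inverts the stain pattern (bright where the panel is
normally dim) with high-frequency texture; `saturated` (uniform blob at
full range) and `empty` (near-blank stain) are also available. Debris is
the kind the Spearman filter is designed to catch; fully saturated blobs
are caught earlier, by the crop-level quality flags.

Everything is seeded: a manifest's master seed deterministically derives
per-well, per-field and per-replicate stream seeds (31-bit mixing, so any
small integer works), and identical manifests reproduce byte-identical
images and ground-truth tables.

The generator reproduces the *structure* of a Cell Painting screen, not its
biology: there are no overlapping or touching cells beyond the separation
bound, no focus drift, no spectral bleed-through, and the morphology
parameters of real knockout lines are unknown (the source screen publishes
no quantitative morphology parameters), so control baselines are free
choices documented in `control_baselines()`. Passing tests therefore
demonstrate that the pipeline recovers what was planted under this model —
not that it would perform identically on donor images.

## Segmentation, cropping and features

Segmentation follows the standard CellProfiler recipe in EBImage terms:
Otsu threshold on the blurred nucleus channel, connected-component seeds,
then watershed-style expansion (`EBImage::propagate`) over a cytoplasm mask
taken as the maximum of the non-nuclear channels. Area bounds (defaults
scale with the nominal cell radius) remove specks and merged objects, and
labels are renumbered densely from 1.

Crops are cut with one bounding box shared by all five channels, pixels
outside the cell's own mask are zeroed (so "single-cell morphology only" is
literally true of the data model), padded to a square, and scaled down only
when larger than the configured side (default 96 px; the synthetic
benchmarks use 32 px). Border-touching, under/over-sized, saturated
(> 35 % of mask pixels at full range in any channel) and near-blank cells
are flagged and excluded. Coordinates are 0-based, half-open, row-major
throughout.

The per-cell feature vector (schema version 1, 29 features) holds, per
channel, the mean/median/SD/integrated intensity inside the mask and the
mean gradient magnitude over the mask interior, plus mask area, perimeter,
eccentricity and solidity. Shape features are reported in field-pixel units
(crop downscaling is undone), so a planted ellipse with semi-axes $a, b$
yields an area within rasterization error of $\pi a b$.

## The Spearman cell filter

Each cell is scored by the Spearman rank correlation (midranks for ties)
between its feature vector and a frozen reference profile — the
element-wise median vector of its line (default) or of the whole screen
(`reference = "global"`) — and removed when $\rho <$ cutoff (default 0.15).

One design point deserves care. On raw features, the cross-feature rank
correlation of *any* cell with *any* reference is high (we measure
0.7–0.98): features live on wildly different scales, so mask area and the
integrated intensities occupy the top ranks of every cell's vector,
guaranteeing concordance regardless of cell quality. A cutoff of 0.15 is
then inoperative. `spearman_filter()` therefore standardizes each feature
column within the reference group by default before correlating. On
standardized columns the reference profile is the line's consensus
*deviation* pattern; typical cells correlate positively with it and
corrupted cells — which sit on the wrong side of every feature the
corruption touches — anti-correlate. On simulated lines with 30 % planted
debris, outlier recall at cutoff 0.15 is essentially 1.0, while 40–50 % of
ordinary cells are also removed. That collateral removal is not a defect of
the implementation so much as a property of the statistic: it matches the
22–70 % per-line removal the original screen reports at the same cutoff,
which is itself a hint that the original filter operated on normalized
CellProfiler features. The raw-scale variant remains available via
`standardize = FALSE`.

Because references are per line, a subtlety matters when the filtered cells
feed a classifier: with a fully per-line reference, the profile's dominant
direction — and even its *sign* on the strongest covariance axis, cell
size — is determined by that line's sampling noise. One line then retains
its larger cells and another its smaller cells, and a classifier can
separate two *identical* lines through the selection alone (we measure null
AUC up to ~0.7 this way). Four comparators are therefore available:

* `"line-median"` — fully per-line (the filter's default; the right mode
  when the question is a single line's artifact content, as in the
  outlier-recall benchmark);
* `"pooled-median"` — per-line standardization but one screen-shared
  profile, the pooled median of the per-line standardized table. Retention
  is then the same function of within-line deviation in every line, so
  filtering cannot manufacture line differences; this is the pipeline
  default, and under it two zero-effect lines classify at AUC 0.50;
* `"global"` — one screen-wide standardization and profile; degenerates
  when a strongly perturbed line redefines the screen consensus;
* `"control"` — anchored to the nontargeting line and applied screen-wide;
  fully shared, but a strongly perturbed line deviates from the control
  consensus deterministically and is nearly entirely removed.

The filter freezes its references (and standardization parameters) from the
pre-filter pass and returns them; re-applying with the frozen set removes
nothing further (idempotence). Cells with zero rank variance get an
undefined $\rho$ and are removed with an explicit flag.

## Datasets: balance, augmentation, splitting

Per gene × channel × replicate, `build_group()` assembles a 50:50
knockout-vs-control image set at a target size (3000 at full scale):

* at least `target` post-QC cells → sample `target` unaugmented cells;
* between `target/8` and `target` → 8-fold augmentation (rotations
  0/90/180/270° × optional horizontal mirror), subsampled to `target`;
* fewer than `target/8` → keep all `8 × raw` images and shrink the control
  side to match (the 221-cell line yields 1768 images per side).

The boundary `target/8` is forced by the group size: $8 \times 375 = 3000$.
The control draw uses a replicate-level, screen-wide seed, so within one
replicate the same control images face every knockout gene; across
replicates both sides are re-sampled.

`split_dataset()` assigns train/validation/test (80/10/10) at the
*source-cell* level: all eight transforms of a cell travel together.
Splitting augmented copies independently would leak near-duplicates of
training images into the test set and inflate AUC; cell-level splitting is
a deliberate strengthening over leaving the point unspecified.

## The classifier and its score

`train_classifier()` fits a compact convolutional network per gene ×
channel × replicate: two blocks of 3×3 convolution → ReLU → 2×2 max-pool
(widths 8 and 16), global average pooling, and a single sigmoid logit,
trained with Adam on binary cross-entropy. The backend is implemented in
RcppArmadillo inside the package; all randomness (He-initialized weights,
epoch shuffles) is injected from R's RNG, so training is bit-deterministic
given the seed. Validation loss is evaluated every epoch and the weights of
the best epoch are kept (best-so-far checkpointing — equivalent to saving
all epochs and selecting the minimum afterwards); training aborts with a
diagnostic on non-finite loss.

The full-scale protocol is 100 epochs at learning rate $10^{-4}$
(`train_config()` defaults). The synthetic benchmarks use 3–8 epochs at
$10^{-3}$ on 32-px crops: with a two-block network and a few hundred images
per side, the higher rate reaches the same plateau in a fraction of the
epochs, and each training finishes in roughly a second on one CPU. A wider
or deeper architecture (the original used a deeper stack) is a configuration
choice, not a code change; two blocks suffice for 32-px crops, where four
pooling stages would be impossible anyway.

`compute_auc()` is the rank-based AUC with half credit for ties,
$\mathrm{AUC} = (\text{concordant} + \tfrac12\,\text{tied})/(n_+ n_-)$,
verified against brute-force pair counting to $10^{-12}$.

## Aggregation, attribution, prioritization

`aggregate_gene()` averages a gene's AUC over all channel × replicate
records (25 at full scale) and keeps the sample SD; per-channel means over
replicates feed `attribute_organelle()`, which takes the argmax channel,
reports the margin to the runner-up, and breaks exact ties by the fixed
channel order (with a flag). Incomplete genes are reported, never silently
dropped.

`compare_locus_genes()` runs Welch's unequal-variance two-sample $t$ test
on the two genes' AUC records and prioritizes the higher-mean gene iff
$p < \alpha$ (default 0.05, uncorrected, as in the source screen). The
original publication reports locus $P$ values without naming the test or
its sample unit — its printed values are not reproducible from the printed
means and SDs under any obvious two-sample test — so Welch on the record
vectors is this package's documented choice, cross-checked in the test
suite against an exact/Monte-Carlo permutation oracle. Degenerate inputs
(zero variance in both groups) resolve exactly to $p = 1$ (equal means) or
$p = 0$.

## Benchmark scenarios and problem sizes

All scenarios (`benchmark_scenario()`) use 272-px fields with 18 cells of
radius 13 px, 32-px crops, and 2 % planted debris unless stated; these
sizes were chosen so that a full screen runs in minutes on a single CPU
while keeping test-set sizes large enough for the calibration bands to be
statistically meaningful:

* **null** — control + zero-effect line, 9 wells × 25 sites per line
  (~4000 cells/line planted, ~1900 post-QC), group target 1500, ten
  replicate seeds on the mitochondria channel, 5 epochs. With 150 test
  cells per side, the binomial SD of a null AUC is ≈ 0.033, so the
  [0.40, 0.60] band is a 3-σ check per replicate. The ten "seeds" are ten
  replicate dataset/training seeds on one simulated screen — the same
  replicate notion the full-scale protocol uses — rather than ten
  re-simulated screens.
* **graded** — mitochondrial $\delta \in \{0, 0.5, 1.5\}$, 4 wells × 14
  sites per line, target 400, 3 replicates, 8 epochs.
* **attribution** — ten genes, $\delta = 1.2$ planted in a known channel
  (each channel twice), 3 wells × 8 sites, target 200, 5 channels × 1
  replicate, 8 epochs. Channel axes were calibrated once so that a
  $\delta = 1.2$ perturbation is detectable in its own channel (single-gene
  AUC ≥ 0.8 in every channel) — without that the attribution statistic
  would measure rendering salience, not the pipeline.
* **locus** — per locus: one gene with $\delta = 1.3$ in *all* channels,
  one null gene, 3 wells × 8 sites, target 200, three channels × 2
  replicates (6 AUC records per gene, enough for the Welch test to have
  power at this scale — with 3 records per gene even a 0.3 AUC difference
  is rarely significant); ten independent locus screens. The matching
  type-I calibration runs 200
  *record-level* null loci (both genes' AUC records drawn from one null
  distribution, SD 0.05, matching the dispersion of pipeline null AUCs):
  the property under test there is the calibration of the Welch
  prioritization rule, and simulating 400 image-level screens would buy no
  additional information about it at ~100× the cost.
* **qc** — one line with 30 % debris, 1 well × 13 sites, Spearman filter at
  0.15 scored against planted outlier labels.

## Numerical and degenerate-input policy

* Seeds are 31-bit; every derived stream seed stays below $2^{31}$.
* Blank fields segment to zero cells (not an error); non-5-channel input,
  unplaceable cell counts, empty lines, empty splits, undersized control
  pools and degenerate masks all raise explicit errors naming the
  constraint.
* Ties: midranks everywhere a rank is taken (Spearman, AUC); attribution
  ties break by fixed channel order with a flag.
* 16-bit quantization applies only on TIFF write; in memory intensities are
  doubles in [0, 1].

## Known limitations

* The simulator's morphology baselines are invented; no claim is made that
  effect sizes map onto any real gene's phenotype.
* Null-fidelity holds *because* nuisance factors are injected symmetrically
  and images are standardized; a real screen with plate-confounded lines
  would need the well/batch randomization the original authors discuss.
* The spec-level quantities tied to the donor dataset (per-gene AUCs such
  as 0.851, per-line removal percentages) require the unreleased images and
  are deliberately out of reach; the package reproduces the arithmetic
  identities and the statistical behaviour of the method instead.
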