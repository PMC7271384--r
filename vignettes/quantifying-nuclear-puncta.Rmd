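---
title: "Quantifying punctate nuclear localization per cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying punctate nuclear localization per cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpuncta)
```

## The problem

Many signaling fragments — here, the intracellular domain of a
membrane-anchored protease released by intramembrane proteolysis —
appear in the nucleus as discrete bright dots against a diffuse nuclear
background. A useful readout must decide, cell by cell, how much of the
marker signal is concentrated in such puncta, and it must do so in a
way that is insensitive to the absolute brightness of the staining,
because exposure and labeling efficiency differ between coverslips.

`nucpuncta` implements that readout as a small, fully tested pipeline:
nuclei are segmented from the DAPI channel, and each nucleus is scored
independently on the marker channel.

## The per-nucleus statistic

For one nucleus with marker intensities $I(p)$ over its pixel set $R$:

1. **Baseline** $B$: rank the $n = |R|$ nuclear intensities; the
   *cutoff* is the $m$-th smallest with $m = \lceil f\,n \rceil$
   (default $f = 0.40$). $B$ is the mean of pixels strictly below the
   cutoff — the mean of the dim nuclear pixels, i.e. those outside the
   brightest 60%. If no pixel is strictly below the cutoff (a uniform
   nucleus), $B$ falls back to the mean of pixels at or below the
   cutoff, which always exists.
2. **Threshold** $T = k \cdot B$ with $k = 1.5$ by default.
3. **Positive pixels**: $p \in R$ is positive when the mean of
   $I$ over the $3\times 3$ window centred on $p$, *intersected with*
   $R$, strictly exceeds $T$. Pixels outside the nucleus never enter
   the window mean, so boundary pixels average over fewer than 9
   values and cytoplasmic signal cannot leak into the statistic.
4. **Score** $S = \sum_{p\,\mathrm{positive}} I(p) \,/\,
   \mathrm{mean}_{p \in R}\, I(p)$.

$S$ is dimensionless. Because $B$, $T$, the window means and the
nuclear mean all scale linearly with the image, $S$ is invariant under
multiplying the nucleus by any positive constant — bit depth and
exposure drop out. A uniform nucleus forces $S = 0$: with the fallback
baseline $B$ equal to the common intensity, every window mean equals
$B < 1.5B$. An all-zero nucleus would divide by zero; it is reported
as $S = 0$ with a `zero_mean` flag and a warning.

A worked example on a 5×5 nucleus, all pixels 1 except a centre pixel
of 100: the cutoff is 1, the strict-below set is empty, so $B = 1$ and
$T = 1.5$. Exactly the 3×3 block around the centre has window means
above 1.5 (each of those windows contains the 100), so the positive
sum is $100 + 8 = 108$, the nuclear mean is $124/25 = 4.96$, and

```{r}
img <- matrix(1, 5, 5)
img[3, 3] <- 100
reg <- structure(list(label = 1L,
                      pixel_coords = as.matrix(expand.grid(row = 1:5,
                                                           col = 1:5)),
                      area = 25L, bbox = c(1L, 1L, 5L, 5L),
                      touches_border = TRUE),
                 class = "nucleus_region")
nucleus_score(img, reg)$score   # 108 / 4.96
```

### Interpreting "below the top 60%"

The dim-pixel rule ranks pixels: the baseline excludes the brightest
60% of nuclear pixels and averages the remaining bottom 40% by rank
(`baseline_mode = "percentile"`, the default, with the cutoff as the
order statistic $m = \lceil f n \rceil$ and a strict `<` comparison).
A different reading — pixels below 60% *of the maximum intensity* — is
retained as `baseline_mode = "max_fraction"` (cutoff
$(1-f)\cdot\max I$), because an illustration of the original procedure
cannot distinguish the two readings mechanically. Both modes share the
fallback rule and are covered by the same brute-force oracle tests.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `baseline_fraction` f | 0.40 | fraction | dim-pixel fraction defining the baseline |
| `baseline_mode` | percentile | — | rank-based vs max-fraction cutoff |
| `threshold_multiplier` k | 1.5 | — | threshold above baseline |
| `neighborhood_radius` | 1 | px | 3×3 averaging window |
| `strict_comparison` | TRUE | — | `>` at the threshold ("greater than") |

## Segmentation

The statistic needs a nuclear region; how nuclei are delineated is a
free choice, so every step is explicit and configurable
(`segmentation_params()`): Gaussian smoothing (default sigma 1 px,
standard for DAPI; 0 disables it), a global Otsu threshold (or a fixed
one), hole filling, 8-connected labeling, a 50 px minimum-area filter,
optional removal of border-touching nuclei, and an optional
distance-transform watershed to split touching nuclei. Smoothing,
thresholding, hole filling and the watershed are delegated to EBImage;
labeling augments EBImage's 4-connected `bwlabel` with a diagonal-merge
pass because regions are defined 8-connected here. Border nuclei are
kept by default and touching-nuclei splitting is off by default, since
the synthetic fields place nuclei fully inside the canvas and
non-overlapping; on real crowded fields both switches matter.

Coordinates are 1-based `(row, col)` matrix indices and bounding boxes
are inclusive, the idiomatic conventions for R matrices.

## The synthetic-data generator

Real micrographs and omics tables are not needed to validate the
computations; the generator produces inputs with exhaustive ground
truth:

* **Fields** (`generate_nucleus_field()`): axis-aligned elliptical
  nuclei rasterized by centre-of-pixel inclusion, placed by rejection
  sampling so that centre distances exceed the sum of the larger
  semi-axes plus a separation margin (10,000 retries, then an error
  naming the violated constraint). The DAPI channel is uniform inside
  nuclei; the marker channel is a diffuse in-nucleus level plus
  puncta — single-pixel deltas or isotropic Gaussians — whose centres
  lie at least 1 px inside the nuclear boundary and a configurable
  distance apart. Noise is additive Gaussian truncated at zero
  (Poisson optional). The default field is 512×512 with 20 nuclei of
  semi-axes 12–18 px, so three fields per condition give ≥ 57 scoreable
  cells — the scale at which per-cell scores are pooled and compared
  here. Default intensities (diffuse 40, DAPI 120, punctum amplitude
  400 = 10× diffuse, noise SD 4) are ordinary fluorescence scales:
  clearly detectable dots over a visible diffuse background at ~10%
  background noise.
* **Expression tables** (`generate_expression_table()`): control FPKM
  uniform over a baseline range; a chosen set of rows multiplied by an
  exact fold with a fixed low p-value; null rows unchanged with
  uniform (or ≥ 0.5) p-values.
* **Spot tables** (`generate_spot_table()`): duplicate spot densities
  per condition scattered around the condition mean with a given CV
  (negative draws resampled, never emitted); hits centred at an exact
  fold over control.

What the generator deliberately does **not** emulate: optics (no
point-spread function, no 3-D stacks), crowded or touching nuclei,
uneven illumination, autofluorescence, or realistic RNA-seq count
noise. Passing tests therefore demonstrate the *computations* are
correct and well-behaved, not that the defaults match any particular
microscope or library preparation.

## Screening filters

`ma_transform()` reproduces standard MA-plot preparation for
FPKM-level tables: a pseudocount of 0.001 is added to the treated
sample, records with FPKM below 0.01 are discarded, and
$M = \log_2(\mathrm{treat}'/\mathrm{ctrl})$,
$A = (\mathrm{ctrl} + \mathrm{treat}')/2$ otherwise. The discard is
applied to both samples by default — it also protects the log ratio —
with `discard_scope = "treated"` as the alternative, since the rule
could defensibly attach to either sample. `A` is the arithmetic mean
by default with a geometric option. `select_degs()` flags hits with
$M > \log_2(\text{min\_fold})$ (strictly more than a twofold increase,
by default) *and* $p < \alpha$ (default 0.05), both strict, so
exact-boundary records never count. `cytokine_hits()` averages the two
duplicate spots per condition and calls hits at fold strictly above
1.2; a zero control mean makes the fold undefined — such analytes are
flagged and excluded rather than silently dropped. No reference-spot
normalization is applied before the fold change; tables are assumed
pre-normalized if the assay requires it.

## Group comparison

`compare_groups()` is an unpaired two-tailed t test via
`stats::t.test`; the default is the Student (pooled-variance) variant
with $n_a + n_b - 2$ degrees of freedom, matching how per-cell scores
are conventionally compared, with Welch available because score
variances of different conditions need not be equal. Both-constant
inputs are handled explicitly (equal means: $t = 0, p = 1$; unequal:
an error). `summarize_scores()` reports n, mean, sample SD and SEM
(undefined markers at $n = 1$). P-values are always two-tailed; no
multiple-testing correction is applied at this level.

## Numerical choices and edge cases

* Intensities are processed as doubles without rescaling; scale
  invariance makes bit depth irrelevant.
* Strict `>` at the detection threshold and strict `<` below the
  baseline cutoff; the uniform-nucleus fallback (`<=`) is the only
  non-strict rule, and only when the strict set is empty.
* The production scorer computes window means by shifted-array sums
  over the region mask; tests compare it exactly (set equality of
  positive pixels, 1e-9 relative on scores) against a naive per-pixel
  double-loop oracle on seeded random fields.
* Monotonicity: brightening a pixel strictly above the baseline cutoff
  can only grow the positive set and its intensity sum. The
  *normalized* score can legitimately decrease when a sub-threshold
  pixel is brightened without crossing the threshold (only the nuclear
  mean grows); the property suite therefore asserts monotonicity of the
  positive sum for above-cutoff bumps and of the score for bumps to
  already-positive pixels.
* Per-field seeds derived from a run seed stay below $2^{31}$.

## Problem sizes used in the checks

The test and acceptance workloads are sized for a laptop-class single
core: oracle equivalence on 20 random 64×64 fields (3 nuclei each);
component recovery and segmentation recovery on default 512×512
20-nucleus fields; and the power check on 100 replicates of a
two-condition design (5 vs 1 puncta per nucleus, three default fields
per condition, first 57 cells pooled per condition), which completes
in a few minutes.

## Known limitations

* Segmentation is classical (threshold + watershed); heavily
  overlapping nuclei or strong illumination gradients need a different
  front end, after which the scoring applies unchanged.
* The score has no background subtraction or flat-field correction;
  if cytoplasmic signal bleeds over the nuclear boundary it will be
  scored, since only the DAPI mask defines the region.
* The expression and spot filters consume precomputed abundance and
  p-value columns; alignment, quantification and differential-test
  p-values are upstream of this package.
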