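# nucpuncta

Per-cell quantification of punctate nuclear localization from
two-channel fluorescence micrographs, with the tabular screening steps
that typically accompany such an experiment and a synthetic-data module
that makes the whole pipeline testable without any external data.

Signaling fragments released by intramembrane proteolysis (and many
other nuclear factors) show up as bright sub-nuclear dots over a
diffuse nuclear background. `nucpuncta` turns that staining pattern
into a number per cell:

1. **Segment** nuclei from the DAPI channel (Gaussian smoothing → Otsu
   → hole filling → 8-connected labeling → area/border filters,
   optional watershed split; all configurable).
2. **Score** each nucleus on the marker channel. With nuclear pixel
   intensities I over region R (n = |R|):
   - baseline `B` = mean of the pixels ranking strictly below the
     `ceiling(0.40 · n)`-th smallest intensity (the dim pixels outside
     the brightest 60%; uniform nuclei fall back to `≤`),
   - threshold `T = 1.5 · B`,
   - a pixel is **positive** when the mean of its 3×3 window
     (restricted to R) strictly exceeds `T`,
   - score `S = Σ_{positive} I / mean_R I`.

   `S` is dimensionless, scale invariant (exposure and bit depth drop
   out) and 0 for uniform nuclei.
3. **Compare** conditions by pooling per-cell scores and applying an
   unpaired two-tailed t test (pooled-variance Student by default,
   Welch optional).

Screening utilities: `ma_transform()` (pseudocount 0.001 on the
treated sample, discard FPKM < 0.01, M = log2 fold change, A = mean
abundance), `select_degs()` (M > 1 and p < 0.05, both strict) and
`cytokine_hits()` (duplicate-spot means, fold > 1.2 strict).

Synthetic generators with exhaustive ground truth:
`generate_nucleus_field()` (elliptical nuclei, delta or Gaussian
puncta, truncated Gaussian noise), `generate_expression_table()` and
`generate_spot_table()`.

## Worked example

```r
library(nucpuncta)

spec <- synth_field_spec(n_nuclei = 20, puncta_per_nucleus = 3, seed = 3)
fld  <- generate_nucleus_field(spec)
head(score_field(fld$dapi, fld$marker), 3)
#>   nucleus_label area baseline threshold positive_count positive_sum
#> 1             1  835 36.14614  54.21921             27     2286.654
#> 2             2  505 36.25950  54.38925             27     2314.915
#> 3             3  617 36.22479  54.33718             27     2279.588
#>   nucleus_mean    score
#> 1     41.60823 54.95676
#> 2     42.39909 54.59822
#> 3     42.04513 54.21764
```

Each row is one nucleus: with 3 single-pixel puncta per nucleus each
punctum lights up its 3×3 neighborhood (27 positive pixels), and the
score is the positive intensity sum normalized by that nucleus's mean
intensity. A high-puncta condition separates cleanly from a low-puncta
one:

```r
lo <- generate_nucleus_field(synth_field_spec(puncta_per_nucleus = 1, seed = 11))
hi <- generate_nucleus_field(synth_field_spec(puncta_per_nucleus = 5, seed = 12))
compare_groups(score_field(hi$dapi, hi$marker)$score,
               score_field(lo$dapi, lo$marker)$score)
#> Unpaired two-tailed t test (student)
#>   group a: n = 20, mean = 88.61
#>   group b: n = 20, mean = 18.68
#>   t = 224.6, df = 38, p = 5.851e-61
```

And the worked 5×5 micro-example (24 pixels at 1, centre 100) gives
baseline 1, threshold 1.5, the 3×3 centre block positive, and score
`108 / 4.96 ≈ 21.774` — see the vignette for the arithmetic.

A thin command-line wrapper over these functions is included at
`inst/cli/nucpuncta.R`
(`simulate | segment | score | compare | screen-filter | run`).

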