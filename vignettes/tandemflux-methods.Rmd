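---
title: "Methods: quantifying autophagic flux with the tandem LC3B reporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying autophagic flux with the tandem LC3B reporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemflux)
```

## The measurement model

The tandem mCherry-EGFP-LC3B reporter separates the two vesicle
populations of the autophagy pathway by color. EGFP is quenched at
lysosomal pH while mCherry is not, so an autophagosome (AP) is a red+green
double-positive punctum and an autolysosome (AL) is red-only. The
pipeline therefore measures, per field of view:

1. the number of cells, proxied by nuclei in the nuclear-stain channel;
2. red and green vesicle detections;
3. a one-to-one red–green colocalization that splits the red population
   into AP (matched) and AL (unmatched);
4. per-cell normalized counts `AP/nuclei` and `AL/nuclei`.

Flux interpretation rests on the standard bafilomycin logic: a flux
inducer raises AL/cell on its own, and raises AP/cell over bafilomycin
when co-treated with it (newly made autophagosomes cannot fuse and
accumulate); a fusion blocker raises AP/cell without an AL increase.
`interpret_flux()` encodes exactly this pair of rules on Tukey-adjusted
contrasts from a one-way ANOVA across the four arms, with
*indeterminate* as the residual verdict. The two contrasts are assessed
independently rather than through an interaction ANOVA; this mirrors how
such experiments are usually argued and keeps the verdict auditable, at
the cost of not modelling the full 2×2 structure.

### Assumptions

- The three channels are registered; chromatic offsets are small relative
  to the colocalization radius.
- Vesicles are diffraction-limited, approximately isotropic spots of
  known scale.
- The field of view is the unit of replication. Per-cell vesicle
  assignment is deliberately out of scope: counts are normalized by the
  field's nucleus count, not attributed to individual cells. All nuclei
  in the field enter the denominator, including any reporter-negative
  cells — with stable or high-efficiency expression the distortion is a
  roughly constant factor that cancels in between-condition contrasts,
  but it is a known approximation.

## Detection pipeline and its parameters

All detection settings live in one `quant_params()` block that is
serialized next to batch results for provenance. Units are pixels and
16-bit intensity counts (0–65535).

| parameter | default | role |
|---|---|---|
| `nuclei_smooth_sigma` | 2 px | pre-smoothing before Otsu thresholding |
| `nuclei_min_area` | 40 px | discards debris after watershed splitting |
| `punctum_sigma` | 2 px | expected spot sigma; sets windows and NMS |
| `log_sigma` | 1 px | scale of the LoG filter (see below) |
| `min_contrast` | 40 | spot peak above local background |
| `min_area`, `max_area` | 3, 400 px | support-area gate per spot |
| `background_radius` | 15 px | median-filter local background |
| `coloc_radius_px` | 2 px | red–green matching distance (≈ spot radius) |

Nuclei: Gaussian smoothing, global Otsu threshold, hole filling, and a
distance-transform watershed to split touching nuclei; connected objects
below `nuclei_min_area` are dropped. A blank or constant channel yields
count 0 with a `"no nuclei"` qc flag, and such fields report `NA`
per-cell values so they can be excluded from statistics.

Puncta: the local background is a median filter (robust to the spots
themselves), and candidate spots are 3×3 local maxima of a
scale-normalized Laplacian-of-Gaussian response, kept when the
background-subtracted peak exceeds `min_contrast` and the half-contrast
support area passes the area gate. Centroids are intensity-weighted
(sub-pixel). Detections are sorted by (row, col) and all coordinates are
0-based.

Two numerical choices deserve explanation:

- **LoG scale below the spot scale.** Two equal Gaussian spots of width
  σ merge into a single intensity maximum once their centres are 2σ
  apart — separation 2σ is the exact bifurcation point. A detector
  filtered at the spot scale broadens the effective width to √2σ and
  cannot resolve pairs near the generator's minimum separation of 3σ.
  Filtering at `log_sigma = 1` (half the spot sigma) keeps the response
  width at √(σ² + 1) ≈ 2.24 px, for which 3σ = 6 px pairs produce two
  clearly separated maxima.
- **Non-maximum suppression at 1.5σ.** Duplicate maxima of one noisy
  spot fall within about one `log_sigma` of each other; distinct spots
  are at least 3σ apart minus pixel quantization. 1.5σ cleanly separates
  the two regimes.

Colocalization is object-based (centroid matching), not pixel-overlap
based: it is robust to small chromatic shifts and mirrors the
object-level notion of a double-fluorescent vesicle. The matching is
greedy in ascending distance with deterministic tie-breaking (red index,
then green index). Greedy matching can differ from the
minimum-total-distance assignment on adversarial geometries; the test
suite compares it against a brute-force assignment oracle on small random
instances and documents that the two coincide on the large majority,
while counts (`n_AP + n_AL = n_red_total`) are conserved always. A red
punctum is called green-positive only via an independently detected green
punctum — green intensity sampled under the red spot is never used, which
avoids a second ad-hoc intensity threshold; the corollary is that the
quenched green amplitude must stay below the detector's contrast gate.

`n_AP` is nondecreasing and `n_AL` nonincreasing in `coloc_radius_px`;
the radius default of 2 px equals the spot radius at the default scale.

## The synthetic-data generator

`generate_field()` renders what the detector assumes, plus realistic
camera noise: nuclei as non-overlapping disks (radius ~ N(9, 1) px) with
a mild parabolic falloff, vesicles as isotropic Gaussian spots
(σ = 2 px, peak 120 counts on a background of 10), AP spots rendered
identically in red and green, AL spots at `green_quench_factor = 0.15`
of the green peak (quenched amplitude 18 < contrast gate 40, so classes
are recoverable by design), per-cell counts Poisson with means 3/3
AP/AL, and optional Poisson shot noise plus additive Gaussian read noise
(the "moderate noise" setting used in the tests is shot noise plus
σ = 6, i.e. 5 % of the spot peak). Spots are placed uniformly in a
cytoplasmic annulus 2–14 px outside the parent nucleus with a minimum
centre separation of 3σ, enforced by rejection sampling; ground truth
records exactly what was rendered, so truth counts always equal rendered
counts. Placement failures (a bounded number of rejection attempts) drop
the punctum from both image and truth; overcrowded nucleus configurations
raise an error instead of silently overlapping.

Magnification and cell density are free parameters of the simulation,
not calibrated to any instrument: defaults (256×256 px, 12 cells) were
chosen once as a plausible confocal field at moderate confluence.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: out-of-focus light and z-structure,
photobleaching, stage drift, chromatic aberration beyond sub-pixel
offsets, heterogeneous reporter expression, vesicle shape variation, and
clustered (non-Poisson) vesicle placement. Results on real images depend
on tuning `min_contrast` and the scales to the instrument.

Ct tables are drawn from `Ct = baseline − log2(expression) + ε`,
ε ~ N(0, sd), reference genes fixed at fold change 1; xenograft cohorts
draw per-arm Gaussian percent volume changes truncated at −100 %. Both
are exact-inversion testable at zero noise.

## Statistics

- ANOVA/Tukey use the standard one-way machinery (`aov`, `TukeyHSD`);
  degenerate inputs (zero pooled within-group variance, groups smaller
  than 2) raise explicit errors rather than returning NaN.
- Fold-change tests are one-sample t-tests on the log scale against
  log(1): ratios are multiplicative, and symmetric changes (0.5, 2)
  must cancel. A constant sample exactly at the null returns t = 0,
  p = 1; a constant sample away from the null is a degenerate-input
  error.
- ΔΔCt combines the two reference genes by the arithmetic mean of their
  Ct values — equivalent to the geometric mean of their expression and
  therefore scale-consistent; technical replicates are averaged at the
  Ct level first. Per-condition fold change is `2^(−mean ΔΔCt)`, i.e.
  the geometric mean of per-sample fold changes, which keeps the
  identity `fold_change = 2^(−ΔΔCt)` exact on every output row and
  pins the control condition at 1 by construction. "Not detectable" is
  a missing Ct or one above 40 cycles; an undetectable target is
  flagged and excluded, an undetectable reference gene is a hard error.
- Xenograft response uses the volume thresholds exactly as adapted for
  zebrafish (PD ≥ +20 %, PR ≤ −30 % of baseline volume, boundaries
  inclusive); no diameter conversion is attempted, and the category
  between the thresholds is reported as SD (stable disease) as the
  residual class.

## Problem sizes

The test and acceptance runs use sizes chosen to make the statistical
checks sharp while remaining quick on a laptop: 20 fields per noise
regime for detector benchmarks, a 100-field fuzz suite for conservation,
50 seeded cohort replicates (4 conditions × 10 fields, on ground-truth
counts) for verdict recovery, 2000 null simulations for ANOVA
calibration, and 100 seeds for Ct recovery. Cohort-level verdict
simulations run on the generator's fast ground-truth path
(`render = FALSE`), which reuses the rendered path's RNG sequence and is
tested to produce identical truths.

## Known limitations

- No per-cell vesicle attribution, 3-D analysis or deconvolution.
- Greedy matching is not a globally optimal assignment (see above).
- The flux verdict uses two marginal contrasts, not an interaction test.
- qPCR assumes perfect amplification efficiency (no Pfaffl correction).
- The simulator's simplifications listed above bound what the green
  tests imply about real microscopes.
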