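# tandemflux

Quantitative analysis of **autophagic flux** from tandem
mCherry-EGFP-LC3B reporter microscopy, with companion tools for
2^−ΔΔCt qPCR quantification and RECIST-adapted zebrafish xenograft
response scoring.

## The problem and who this is for

Autophagy delivers cytoplasmic cargo to the lysosome through
double-membrane autophagosomes. Whether a drug *induces* flux (more
material reaching the lysosome) or *blocks* it (vesicles piling up before
fusion) cannot be read off a single vesicle count. The tandem
mCherry-EGFP-LC3B reporter disambiguates the two: LC3B is fused to an
acid-stable red and an acid-quenched green fluorophore, so

- **autophagosomes (AP)** fluoresce red **and** green,
- **autolysosomes (AL)** fluoresce **red only** (EGFP quenched after
  lysosomal fusion).

A rise in red-only vesicles per cell means increased flux; a rise in
double-positive vesicles with no AL increase means impaired
autophagosome–lysosome fusion. Co-treatment with the late-stage inhibitor
bafilomycin A1 provides the confirmatory arm: a true flux inducer raises
AP counts over bafilomycin alone, because de novo autophagosomes
accumulate when fusion is blocked.

The package is aimed at cell biologists running such reporter assays
(e.g. HDAC-inhibitor studies in neuroblastoma lines) who want a
reproducible, scriptable equivalent of a semi-automated ImageJ
quantification, plus the surrounding statistics.

## What it computes

**Image quantification** (`quantify_field`, `quantify_batch`) per field
of view: nuclei count (Gaussian smoothing → Otsu threshold → hole filling
→ distance-transform watershed), red/green vesicle detection
(median-filter background, Laplacian-of-Gaussian blob detection, contrast
and area gates), object-based colocalization (greedy nearest-centroid
one-to-one matching within a radius; matched red = AP, unmatched red =
AL), and per-cell normalization (counts ÷ nuclei).

**Flux statistics** (`anova_tukey`, `interpret_flux`): one-way ANOVA with
Tukey HSD across control / drug / bafilomycin / drug+bafilomycin, and the
decision rule

- *flux induced* ⇔ AL/cell ↑ (drug vs control) **and** AP/cell ↑
  (drug+baf vs baf), both at Tukey-adjusted p < 0.05;
- *flux blocked* ⇔ AP/cell ↑ (drug vs control) without an AL increase;
- otherwise *indeterminate*.

**qPCR** (`delta_delta_ct`, `fc_report`): relative expression by the
2^−ΔΔCt method against the mean of two reference genes (default SDHA and
HPRT), with a configurable 40-cycle detectability cutoff and one-sample
t-tests of fold changes against 1 on the log scale.

**Xenografts** (`volume_change`, `classify_response`, `cohort_summary`):
percent tumor-volume change from baseline, RECIST-adapted calls
(PD ≥ +20 %, PR ≤ −30 %, SD between), per-arm response rates and
waterfall plots.

**Synthetic data** (`generate_field`, `generate_cohort`,
`generate_ct_table`, `generate_xeno_cohort`): seeded simulators with
ground truth for every stage — rendered reporter fields (nuclei disks,
Gaussian vesicles, Poisson + Gaussian camera noise, EGFP quenching),
Ct tables and xenograft volume tables — so the whole pipeline is
testable without any external data.

## Worked example

```r
library(tandemflux)

# one synthetic field, quiet camera, and its recovery
fld <- generate_field(sim_field_params(n_cells = 6, seed = 7))
fld$truth
#> <ground_truth> 6 nuclei, 21 AP + 17 AL puncta
quantify_field(fld$image)
#> <field_quantification> sim_seed7
#>   nuclei: 6 | red vesicles: 38 (AP 21, AL 17) | green-only: 0
#>   per cell: AP 3.500, AL 2.833

# a four-arm cohort designed as a flux inducer, interpreted on true counts
spec <- cohort_spec(
  c("control", "drug", "baf", "drug_baf"),
  list(control = c(AP = 1,   AL = 1),
       drug    = c(AP = 0.5, AL = 3),
       baf     = c(AP = 3,   AL = 0.3),
       drug_baf = c(AP = 9,  AL = 0.3)),
  n_fields = 10, seed = 11)
tab <- cohort_truth_table(generate_cohort(spec, sim_field_params(n_cells = 8),
                                          render = FALSE))
interpret_flux(tab)
#> <flux_verdict> flux_induced (alpha = 0.05)
#>   AL drug vs control:      diff +6.088, Tukey p = 0 *up*
#>   AP drug+baf vs baf:      diff +15.387, Tukey p = 0 *up*
#>   AP drug vs control:      diff -1.500, Tukey p = 0.00153
```

The detector recovers the simulated field exactly (21 AP, 17 AL across
6 nuclei), and the designed cohort — AL tripled under drug, AP tripled
over bafilomycin by the combination — is called `flux_induced` because
both rule contrasts are significant increases.

```r
rec <- generate_xeno_cohort(
  data.frame(label = c("ctrl", "combo"), n_fish = c(8, 8),
             mean_pct_change = c(15, -35), sd = c(20, 15)), seed = 3)
cohort_summary(rec)
#> <xeno_summary>
#>   combo (n = 8): PD 0% | SD 12% | PR 88%
#>   ctrl (n = 8): PD 25% | SD 75% | PR 0%
```

A command-line wrapper ships in `inst/cli/tandemflux.R`
(subcommands `simulate`, `quantify`, `fluxstats`, `qpcr`, `xeno`; see
`?flux_cli`).

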