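# splicegrade

Splice-isoform ratio analysis and malignancy gene classification for
graded tumour cohorts.

## What this package is for

The majority of astrocytomas express the intermediate-filament protein
GFAP, whose two main splice isoforms, GFAPα and GFAPδ, differ in their
C-terminal exon. In grade IV astrocytoma (glioblastoma) GFAPα falls
while GFAPδ stays flat, so the per-patient stoichiometry statistic

    r_i = GFAPδ_i / GFAPα_i

increases with malignancy grade. `splicegrade` implements, as a tested
reusable pipeline, the inference chain that links this ratio to
grade-associated gene programs:

* **ratio statistics** — per-sample δ/α with grade-wise Mann–Whitney U
  tests and Benjamini–Hochberg FDR;
* **microarray preprocessing** — two-colour spot intensities from
  isoform-perturbation experiments (GFAPα+/GFAPδ+ overexpression,
  GFAPα−/GFAPpan− knockdown) filtered for flagged spots, quantile
  normalized, probe-collapsed and intensity-filtered (log2 > 6);
* **moderated differential expression** — empirical-Bayes shrunken
  variances with posterior `s̃²_g = (d0·s0² + d_g·s²_g)/(d0 + d_g)` and
  the joint gates FDR < 0.1, |FC| ≥ 1.5, applied to both the in-vitro
  contrasts and the patient grade contrasts;
* **concordance classification** — direction-concordant intersection of
  in-vitro responders with patient grade-DE genes, then a
  correlation-sign-pattern rule (positive to GFAPα, negative to δ/α,
  null for GFAPδ → *low-malignant*; mirrored → *high-malignant*);
* **survival screening** — within-grade median-split Kaplan–Meier with
  log-rank tests and FDR flags at 0.05 (significant) / 0.1 (trend) for
  overall and progression-free survival;
* **GO overrepresentation** — one-sided Fisher (hypergeometric) tests
  against the analysis universe with the elim parent–child
  decorrelation scheme.

Because the original cohort and array data live in external archives, a
first-class synthetic-data module (`cohort_spec()` /
`generate_cohort()` / `generate_microarray_batch()`) emulates the study
design — 55/105/150 patients per grade, a 45% grade-IV GFAPα decrease, a
2.2-fold ratio increase, array replicates 8/8/8 and 6/5/5, per-grade
censoring of 94.6/77.4/34.7% — with planted, recoverable effects and
ground-truth labels, so every stage is verifiable at desk scale.

## Worked example

```r
library(splicegrade)

co  <- generate_cohort(cohort_spec(seed = 42))
res <- grade_isoform_tests(co$isoforms, co$clinical)
print(res, digits = 3)
#>   measure  contrast     U  p_value      fdr percent_change median_a median_b
#> 1   alpha III_vs_II  3064 5.27e-01 5.27e-01           93.0 4.28e+03 4.30e+03
#> 2   alpha  IV_vs_II  6553 1.12e-10 1.67e-10           53.0 4.28e+03 2.27e+03
#> 3   alpha IV_vs_III 12578 4.96e-16 1.49e-15           57.0 4.30e+03 2.27e+03
#> 4   delta III_vs_II  2483 1.47e-01 4.38e-01          117.8 1.91e+02 2.20e+02
#> 5   delta  IV_vs_II  3728 2.92e-01 4.38e-01          111.7 1.91e+02 2.19e+02
#> 6   delta IV_vs_III  8091 7.10e-01 7.10e-01           94.8 2.20e+02 2.19e+02
#> 7   ratio III_vs_II  2552 2.29e-01 2.29e-01          119.6 4.54e-02 5.28e-02
#> 8   ratio  IV_vs_II  1996 1.55e-08 2.33e-08          239.7 4.54e-02 9.32e-02
#> 9   ratio IV_vs_III  4529 7.86e-09 2.33e-08          200.5 5.28e-02 9.32e-02
```

Reading the table: `percent_change` is `100 × mean(B)/mean(A)` for the
contrast `B_vs_A`. GFAPα in grade IV sits at 53% of its grade II mean
(the planted 45% decrease), GFAPδ does not differ between grades (all
FDR > 0.1), and the δ/α ratio in grade IV is ~2.4× grade II and ~2×
grade III at FDR < 1e-7 — the planted grade pattern recovered from one
seeded cohort.

The full chain — array simulation and preprocessing, in-vitro and
patient DE, concordant overlap, classification, survival screen, GO —
runs from one config:

```r
res <- run_pipeline(run_config(seed = 42, out_dir = "run42"))
table(res$classification$label)   # planted 40 low- + 40 high-malignant genes
#> high-malignant  low-malignant
#>             40             40
```

Every stage writes plain TSVs into `out_dir` plus a JSON manifest with
per-stage gene counts and file checksums; rerunning the same config
reproduces identical checksums. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

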