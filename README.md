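# SigScan

Prognostic gene-expression signatures for relapse-free survival, built the
way large integrated microarray cohorts are analysed in clinical
transcriptomics: screen every gene, weight it by the direction of its
hazard, average, and then refuse to commit to a single arbitrary
dichotomization point.

## Who this is for

Researchers who have (or simulate) a multi-dataset cohort of nonnegative
gene-level intensities (MAS5-scale arrays harmonized to a shared probe set)
with relapse-free survival follow-up, and who want a tested, reproducible
implementation of the weighted-signature / optimal-cutoff workflow rather
than a website or a pile of one-off scripts.

## The method

For gene *g* with expression *x<sub>g</sub>*, a univariate Cox
proportional-hazards model for relapse-free survival gives a hazard ratio
HR<sub>g</sub>. The gene's weight is

> w<sub>g</sub> = +1 if HR<sub>g</sub> > 1,  −1 if 0 < HR<sub>g</sub> < 1

and the signature score of sample *s* is the average weighted expression

> score(s) = (1/|G|) Σ<sub>g∈G</sub> w<sub>g</sub> · x<sub>g</sub>(s).

To avoid the information loss of one arbitrary cutoff, every observed
score value *v* between the lower and upper quartiles is tried as a
dichotomization point (low: score ≤ v; high: score > v). Each cutoff
yields a high-vs-low Cox HR and p-value; the family of p-values is
corrected by the Benjamini–Hochberg false discovery rate, which absorbs
the optimism of then selecting the minimum-p cutoff. The selected split
is rendered as Kaplan–Meier curves, replicated dataset by dataset (shared
weights, within-dataset cutoff), and defended against clinical covariates
with paired bivariate Cox models (signature + one covariate at a time, on
that covariate's complete cases).

A synthetic-cohort generator with known per-gene log-hazard effects,
per-dataset batch shifts and censoring calibrated to a target rate makes
every stage testable end to end without any external download.

## Worked example

```r
library(SigScan)

sim <- simulateCohort(simConfig(n_samples = c(150, 150, 150), seed = 42))
sim$cohort
#> SurvCohort: 200 genes x 450 samples, 3 dataset(s), 111 events (24.7%)

res <- analyzeCohort(sim$cohort)      # screen -> score -> scan -> KM
res$scan
#> CutoffScan: 224 cutoffs scanned in [Q1, Q3); selected cutoff 108.5
#>   (HR = 6.93, p = 3.6e-22, FDR = 3.4e-20)
#>   HR range over scan: 5.68 - 16.6

w  <- res$weights                     # shared signature definition
pd <- perDataset(sim$cohort, w)
pd[, c("dataset_id", "n", "events", "hr", "p", "direction_consistent")]
#>   dataset_id   n events        hr            p direction_consistent
#> 1  dataset01 150     36 10.955571 7.536919e-10                 TRUE
#> 2  dataset02 150     33  5.492840 2.645914e-06                 TRUE
#> 3  dataset03 150     42  7.798749 5.301788e-08                 TRUE
```

Reading the output: the scan tried every observed score between the
quartiles; the selected cutoff splits the cohort into a high-score group
with about 7-fold relapse hazard, significant after FDR correction over
the scanned family, and the direction (higher signature → worse outcome)
replicates within each simulated dataset. `runPipeline()` drives the same
stages from a YAML config and writes every table (TSV), figure (SVG) and
an MD5 manifest; tables are byte-identical across re-runs with the same
config and seed.

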