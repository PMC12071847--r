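# rbclifespan

Estimate the mean lifespan of red blood cells created **before** the start
of CDK4/6-inhibitor therapy, using nothing but routine longitudinal
complete blood counts (RBC count, MCV, MCHC).

## The problem and who this is for

CDK4/6 inhibitors (palbociclib, ribociclib, abemaciclib) make newly
produced erythrocytes larger. Because a mature red cell keeps an
essentially fixed volume for life, a treated patient's measured MCV is a
mixture average over two cell populations — small pre-treatment ("old")
cells and large on-treatment ("new") cells — and the **speed of the MCV
rise encodes how fast old cells die**. A shortened lifespan (the
compensated-hemolysis concern raised by CDK6-knockout mouse data) would
make MCV climb quickly; a normal ~118-day lifespan makes it climb slowly.
This package is for hematology/oncology researchers and biostatisticians
who want to quantify drug effects on red-cell kinetics from laboratory
data that every clinic already collects, without invasive cell-labeling
studies.

## The model

For patient $i$ at time $t$ (days since first dose), each observable
$X \in \{N_{RBC}, \mathrm{MCV}, \mathrm{MCHC}\}$ follows

$$X_i(t) \sim \mathrm{StudentT}\big(\nu_X,\ w_{old}(t)\,X_{i,old} +
(1-w_{old}(t))\,X_{i,new},\ \sigma_X\big),$$

where the old-cell weight is 1 before treatment and follows the LogNormal
residual survival law afterwards:

$$w_{old}(t) = 1 - \Phi\!\left(\tfrac{\log t - \mu_s}{\sigma_s}\right),
\qquad t > 0 .$$

Patient-level values $X_{i,old}, X_{i,new}$ are drawn from population
Normal hierarchies; the mean lifespan of pre-treatment cells is
$\exp(\mu_s + \sigma_s^2/2)$; hemoglobin is derived per posterior draw via
$\mathrm{Hgb} = N_{RBC}\cdot\mathrm{MCV}\cdot\mathrm{MCHC}/1000$. The
probabilistic kernel is written in the JAGS modelling language and fitted
by Gibbs sampling via `rjags`; diagnostics (split-R̂, rank histograms,
posterior predictive checks, PSIS-LOO with Pareto k̂) are built in. See
`vignettes/rbc-lifespan-methods.Rmd` for the full account.

Because the motivating clinical dataset is not public, the package ships
a calibrated synthetic-cohort generator (`generate_cohort()`) reproducing
the study conditions — 122 patients, ~16 blood draws each on a baseline +
biweekly + monthly schedule, median 7.2 months of continuous treatment —
so the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(rbclifespan)

# a synthetic cohort calibrated to the study population
cohort <- generate_cohort(cohort_config(seed = 20250505))
cohort
#> <rbc_cohort> 122 patients, 2018 blood draws (mean 16.5/patient), median duration 6.4 months

# eligibility -> model -> posterior, in one call
res <- run_pipeline(pipeline_config(
  cohort = cohort_config(seed = 20250505),
  fit    = fit_config(n_chains = 2, n_warmup = 1000, n_sampling = 1000,
                      seed = 4242)))
res
#> <rbc_pipeline> 122 patients (2018 records, mean 16.5 CBCs/patient), median duration 6.4 months
#>   mean RBC lifespan: 118.7 days (95% CdI 117.2-120.3)
#>   convergence: FAIL | khat > 1.0: 0

res$recovery
#> # A tibble: 7 x 7
#>   quantity     unit      truth  median conf.low  conf.high covered
#>   <chr>        <chr>     <dbl>   <dbl>    <dbl>      <dbl> <lgl>
#> 1 lifespan     days    118     119.     117.    120.       TRUE
#> 2 mcv_pre      fL       87.8    86.7     85.9    87.5      FALSE
#> 3 mcv_post     fL      100.    100.      99.2   101.       TRUE
#> 4 mcv_delta    fL       12.4    13.4     12.2    14.8      TRUE
#> 5 mchc_delta   g/dL      0.690   0.732    0.490   0.981    TRUE
#> 6 rbc_decrease 10^12/L   0.77    0.830    0.697   0.958    TRUE
#> 7 hgb_delta    g/dL     -0.447  -0.467   -0.910   0.000126 TRUE
```

The lifespan row is the headline: the posterior median of the mean
lifespan of pre-treatment red cells (generating truth 118 days, the value
measured in healthy adults — i.e. no evidence of drug-induced hemolysis
in the generating scenario). `mcv_pre`/`mcv_post` are the population mean
MCV of old and new cells; the `*_delta` rows are per-draw post-minus-pre
contrasts (`rbc_decrease` is pre-minus-post). Two honest footnotes on this
output: the `mcv_pre` interval narrowly misses the generating value for
this particular cohort realisation (one miss among seven 95% intervals is
unremarkable), and the `convergence: FAIL` verdict reflects the strict
bulk-ESS > 400 acceptance rule, which this reduced two-chain demo
configuration does not reach for every parameter (its max split-R̂ is
1.006; the 4-chain × 2000-draw default is the configuration the rule is
written for). Note the hemoglobin contrast is *derived* from the other
three indices by the product identity; the methods vignette explains why
its generated value is a small decrease.

For real data, point `pipeline_config(cohort = "my_cbc.csv")` at a tidy
CSV with columns `patient_id, t_days (or date + first_dose_date),
rbc_1e12_per_L, mcv_fL, mchc_g_dL`, optionally with a dispensing table
for continuous-treatment windows. A thin command-line front end lives at
`inst/scripts/rbclifespan.R`
(`Rscript rbclifespan.R simulate|fit|diagnose|report|all ...`).

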