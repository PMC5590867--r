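# indexminer

Systematic "index mining": construct **every** cumulative,
PCA-loading-weighted index a survey's variables admit, and screen each
one for association with second-year mortality under complex-survey
weighting. The package is aimed at methodologists studying composite
measures (frailty-type indices, risk scores) who want to quantify how
much nominal statistical significance a purely data-driven aggregation
sweep produces — and therefore why `p < 0.05` alone cannot validate a
novel index.

## The method

With $N$ standardized variables $x_i$ and the loading vector $L$ of
principal component $pc$ of the survey-weighted correlation matrix, the
component score is $\mathrm{PC}_{pc} = \sum_{i=1}^{N} L_i x_i$. Sorting
variables by descending $|L_i|$ (ties by column order) and truncating
the sum defines the cumulative index family

$$\mathrm{Index}_{pc.n} = \sum_{i=1}^{n} L_{(i)} x_{(i)}, \qquad n = 1,\dots,N,$$

whose last member is the component score itself — $N^2$ indices in all
(134,689 at $N = 367$). Each index enters a discrete-time event-history
model of quarterly death (person-period logistic: quarter intercepts,
index main effect, index-by-quarter interactions; survey weights;
PSU-clustered sandwich variance), unadjusted and adjusted for age, sex
and race, and the Wald p-value of the index main effect is extracted.
Results are summarized by index size, and the count of significant
indices is converted into the publication-cycle arithmetic (4 indices
per researcher-year, 66 articles per journal-year). A fitted index
coefficient $\beta$ transmits to implied per-variable coefficients
$\beta L_{(i)}$.

Because the real pooled survey panels behind the original analysis are
restricted, the package ships a first-class synthetic cohort generator:
a latent risk-factor model with configurable effect on the quarterly
death odds, MEPS-style reserved codes ($-1$ inapplicable, $-2$ carried
forward, $-3/-7/-8/-9$ missing), designed rank-redundant duplicates,
lognormal survey weights and a strata/PSU layout, calibrated to a 0.62%
cumulative second-year death rate at its defaults.

## A worked example

```r
library(indexminer)

coh <- generate_cohort(cohort_config(
  n_subjects = 3000, n_continuous = 6, n_nominal = 2, n_ordinal = 1,
  nominal_levels = c(3, 4), redundancy_pairs = 2, seed = 11))
coh
#> survey_cohort: 3000 subjects x 11 variables (8 continuous, 1 ordinal, 2 nominal)
#>   deaths in year 2: 22 (0.73% unweighted)
#>   design: 100 strata x 2 PSUs, weights sum 2.8e+08

fit <- index_screen(coh, seed = 3)
fit
#> index_screen: 13 variables -> 169 cumulative weighted indices
#>   significant (both, p < 0.05): 27 / 169 (15.98%)
#>   significant (adjusted, p < 0.05): 28 / 169 (16.57%)
#>   significant (unadjusted, p < 0.05): 27 / 169 (15.98%)
```

The 11 raw variables expand to 13 PCA columns after the 2 redundant
duplicates are filtered and the nominals are reference-coded
(6 continuous + 1 ordinal + (3−1) + (4−1) indicator columns, with the
recoded "inapplicable" level adding one more). 169 = 13² indices are
then each fitted twice (unadjusted/adjusted). Even in this small cohort
with a genuine latent mortality signal, dozens of distinct "significant
indices" emerge — the method's point in miniature. `summary(fit)` prints
the size-binned significance table (bins 1, 2–30, 31–70, ≥71 variables)
and the publication-impact quotients; `coef(fit)` returns the per-index
coefficient table; `plot(fit)` draws p-values against index size.

Lower-level entry points mirror the pipeline stages:
`recode_reserved()`, `choose_log_transform()`,
`spearman_redundancy_filter()`, `impute_chained()`, `expand_nominal()`,
`center_scale_weighted()`, `fit_weighted_pca()` / `predict_scores()`,
`rank_variables_by_loading()`, `enumerate_index_specs()`,
`index_catalog()`, `build_index()`, `implied_coefficients()`,
`expand_person_periods()`,
`fit_discrete_time()`, `screen_all()`, `weighted_km()`,
`summarize_by_size()`, `publication_impact()`, `export_report()`,
`write_cohort()` / `read_cohort()`.

## Reviewing novel indices

The methodological counterpart to the mining exercise is a reporting and
review framework for proposed indices: any new composite should state
the objective of aggregation, justify the variable weighting (equal
weights are a strong assumption, not a default), name the outcome(s) it
was screened against and the database characteristics, and disclose how
many candidate aggregations were examined. This framework is a
documentation practice, not a computation, and is therefore not part of
the package's API.
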