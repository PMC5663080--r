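# raiqc — data quality evaluation for interRAI home and community care data

`raiqc` is an R package for evaluating the quality of longitudinal interRAI
assessment data — RAI-HC records from home care and interRAI CHA records
from community support services — the way large provincial data holdings
are audited: not with field psychometrics, but with statistical screens
computed from the records themselves. It is aimed at analysts who maintain
or consume these administrative datasets and need reproducible evidence
that the data can be trusted for planning and quality monitoring.

The framework combines five screens:

* **Trend tables** — annual rates of demographic, clinical, service and
  resource indicators (e.g. % with CPS ≥ 3), summarized as mean (SD) of the
  annual values;
* **Convergent validity** — yearly Pearson correlations for five scale
  pairs expected to be related and stable: ADLH×CPS, IADL(capacity)×CPS,
  IADL(performance)×CPS, Pain×DRS, CHESS×Pain;
* **Reliability** — yearly Cronbach's alpha,
  α = k/(k−1) · (1 − Σᵢ var(xᵢ)/var(Σᵢ xᵢ)),
  for four parallel-form scales (IADL performance, IADL capacity, DRS, ADL
  Long Form);
* **Auto-population detection** — the share of within-year reassessment
  pairs identical on six indicator sets (summed informal-care hours, 9 ADL
  items, 7+7+14 IADL items, 9 mood items), after excluding pairs at the
  floor at both time points;
* **Indicator-battery comparison** — a fixed battery of correlations and
  alphas computed per cohort and compared across cohorts via R² (squared
  Pearson correlation of the paired values).

The package scores the interRAI summary scales from raw ordinal items (ADL
Long Form 0–28, ADL Hierarchy 0–6, IADL performance 0–9 and capacity 0–6,
DRS 0–14, CPS 0–6, CHESS 0–5, Pain 0–3, MAPLe levels 1–5) and ships a
synthetic cohort generator — persons with correlated latent health
dimensions, year-over-year drift, within-year reassessments, injectable
carry-forward and record defects — so the whole pipeline is testable
without confidential data. See `vignettes/data-quality-methods.Rmd` for the
model and every design decision.

## Worked example

```r
library(raiqc)

cfg <- synth_config(n_persons = 2000, years = 2010:2013,
                    reassessment_prob = 0.3, autopop_fraction = 0.15,
                    seed = 42)
records  <- generate_cohort(cfg)
eligible <- filter_eligible(records)
#> filter_eligible: retained 9948 of 10358 records (excluded 305
#> hospital-version, 108 missing-identifier)

scored <- score_assessments(select_annual(eligible))
validity_trends(scored)[["ADLH & CPS"]]
#> Trend table: ADLH & CPS (pearson_r)
#> # A tibble: 4 × 3
#>    year value     n
#>   <int> <dbl> <int>
#> 1  2010 0.427  1941
#> 2  2011 0.396  1934
#> 3  2012 0.402  1943
#> 4  2013 0.425  1948
#> Mean (SD) of annual values: 0.41 (0.02)
```

The functional-loss × cognition correlation sits near 0.4 every year — the
stable, moderate association one expects from a healthy dataset; a year
where it collapsed would flag a data problem, not a clinical change.

```r
pairs <- pair_within_year(eligible)
autopopulation_rates(eligible, pairs) |>
  dplyr::filter(set == "iadl_both")
#> # A tibble: 4 × 5
#>   set        year  rate n_eligible n_identical
#>   <chr>     <int> <dbl>      <int>       <int>
#> 1 iadl_both  2010  17.2        501          86
#> 2 iadl_both  2011  16.5        546          90
#> 3 iadl_both  2012  18.7        524          98
#> 4 iadl_both  2013  17.6        574         101
```

About 17% of reassessment pairs are identical on all 14 IADL items. The
cohort was generated with 15% injected carry-forward, so the detector is
reading back the injection plus the small chance-identity baseline.

```r
other <- score_assessments(select_annual(filter_eligible(
  generate_cohort(synth_config(n_persons = 2000, years = 2010:2013,
                               seed = 99)))))
compare_batteries(indicator_battery(scored), indicator_battery(other))
#> Battery comparison over 30 shared indicators: R^2 = 0.998
```

Two cohorts drawn from the same population structure agree almost
perfectly across the 30-statistic battery — the pattern that, between two
real jurisdictions, is read as "the instrument behaves the same way in
both".

The same analyses run from the shell via the thin CLI at
`inst/scripts/raiqc.R` (subcommands `run`, `simulate`, `score`, `trends`,
`validity`, `reliability`, `autopop`, `battery`, `compare`), or end-to-end
with `run_pipeline()`, which writes one CSV per table family plus a JSON
manifest carrying the seed and config hash.

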