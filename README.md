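# wqharmonize

Harmonization of heterogeneous, multi-organization nutrient water-quality
records into a standardized, comparable daily concentration dataset.

Monitoring data pooled from many organizations — the style of result-level
export produced by the Water Quality Portal — mixes chemical bases
(elemental "as N" vs molecular "as NO3"), unit dialects (mg/L, ug/L, ppm,
and units with no mass-per-volume meaning), duplicate monitoring sites,
censored "non-detect" results encoded as zeros, negatives or blanks, and
quality-control rows masquerading as field measurements. `wqharmonize`
implements a nineteen-step harmonization cascade that resolves sites,
filters uninterpretable metadata, converts every concentration to mg/L as
N or as P, imputes censored values, averages duplicates to the daily
level, combines sample fractions into total nutrients, and applies a
filtered-vs-unfiltered consistency check. Two tables come out:

* a **harmonized dataset** — one row per (site, date, nutrient parameter),
  with concentration, outlier and imputation flags; and
* a **flagged audit dataset** — every raw row with a keep/drop/`NA` flag
  per step, so any rule can be revisited without rerunning the download.

The statistical core is multiple imputation of left-censored
concentrations under a lognormal model. For each group of observations
sharing a site, nutrient parameter and year,

    log c_i ~ Normal(mu, sigma^2),   mu ~ Normal(0, 1000^2),
    sigma^2 ~ InvGamma(0.001, 0.001),

with censored values drawn by Gibbs data augmentation from the normal
truncated above at log(DL); K = 10 retained draws per censored value are
averaged on the concentration scale. Groups with ≥ 80% non-detects are
left missing and flagged. Non-detects lacking a detection limit get a
conservative common limit per nutrient-year: the largest, across
organizations reporting limit-less non-detects, of each organization's
minimum detected value.

A synthetic raw-record generator with a latent-truth sidecar emulates the
full mess (spelling variants, site duplicates, unit dialects, molecular
reporting, censoring, metadata faults) so that every pipeline stage is
testable without any external download — each generated row carries its
expected fate through the pipeline.

## Worked example

```r
library(wqharmonize)

spec <- generator_spec(n_sites = 10, n_years = 3, seed = 42)
d    <- generate_dataset(spec)        # raw WQP-style table + latent truth
res  <- run_pipeline(d$raw)           # full 19-step harmonization
print(res)
#> Water-quality harmonization run
#>   raw records:        187
#>   harmonized records: 148
#>   cascade drops:      30
#>   imputed non-detects: 16 (left missing: 22)
#>   combined observations added: 0
#>   inconsistent filtered/unfiltered daily pairs dropped: 0
```

Of 187 raw rows, 30 were dropped by the metadata cascade (bad medium,
missing date, unknown chemical form, uninterpretable value/units,
contamination codes, ambiguous fraction, QC activity, estimated results);
16 non-detects were imputed from their site-nutrient-year groups and 22
sat in groups at or above the 80% censoring cutoff and stay missing.

```r
head(res$harmonized[, c("MLI", "date", "nutrient_parameter", "conc",
                        "conc_units", "impute_flag")])
#>             MLI       date           nutrient_parameter        conc conc_units impute_flag
#> 1 SITE-0001-ALT 2000-03-24      total nitrogen_filtered 0.747210329  mg/L as N    detected
#> 2 SITE-0001-ALT 2000-04-02 kjeldahl nitrogen_unfiltered 1.600611630  mg/L as N    detected
#> 3 SITE-0001-ALT 2000-08-12      orthophosphate_filtered          NA  mg/L as P     imputed
#> 4 SITE-0001-ALT 2001-03-02 kjeldahl nitrogen_unfiltered          NA  mg/L as N     imputed
#> 5 SITE-0001-ALT 2001-04-12    total phosphorus_filtered 0.224542229  mg/L as P    detected
#> 6 SITE-0001-ALT 2001-06-20    total phosphorus_filtered 0.005687987  mg/L as P     imputed
```

Row 3 is a non-detect left missing (group too censored to impute — its
flag marks the provenance); row 6 is an imputed value, guaranteed to lie
in (0, DL]. The run report tallies the unit flows and the fraction of
observations standardized per nutrient basis:

```r
print(res$report)
#> Harmonization report
#>   standardized: N 86.7%, P 83.1%
#>   unit flows (top rows):
#>       basis  raw_unit   outcome  n
#> 1 (unknown)      mg/l   dropped  2
#> 2 (unknown)       ppm   dropped  1
#> 3         N mg/l as n mg/L as N 43
#> 4         N      ug/l mg/L as N 17
#> ...
```

`run_pipeline(raw, config, out_dir = "out")` additionally writes
`snapd.csv` (harmonized), `flagged.csv` (audit), the report tables and a
run log. A thin command-line wrapper ships in `inst/cli/harmonize`
(`harmonize run`, `harmonize generate`, `harmonize dump-registries`).
Thresholds and registries (merge distance, censoring cutoff, unit
registry, vocabularies, alias tables) live in an editable configuration:
see `default_config()` and `load_config()`.

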