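---
title: "Harmonizing heterogeneous nutrient water-quality records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous nutrient water-quality records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqharmonize)
```

## The problem

Result-level nutrient records pooled from many monitoring organizations are
not directly comparable. The same nitrate measurement may arrive as
elemental nitrogen ("nitrate as N") or as the whole molecule ("nitrate as
NO3", 4.43 times heavier per mole of N); concentrations appear in mg/L,
ug/L, ppm, or units with no mass-per-volume meaning at all; a physical site
may carry several location identifiers, and one identifier several
coordinate pairs; censored results ("non-detects") are encoded as zeros,
negative numbers, or missing values, with or without a detection limit; and
quality-control samples, estimated values and ambiguous filtration metadata
hide among valid field measurements.

`wqharmonize` turns such a table into a standardized daily dataset of
concentrations in mg/L as N or as P, one row per site, date and nutrient
parameter (nutrient name plus sample fraction, e.g. `ammonia_filtered`).
Every raw row is also returned with per-step keep/drop/NA flags, so no
information is destroyed: a user who disagrees with any rule can re-cut the
data from the flagged table.

## The procedure

The pipeline applies, in order:

1. **Organization names** are trimmed, case-folded for lookup and mapped
   through an editable alias table. This never drops rows.
2. **Site resolution.** For an identifier reported with several coordinate
   pairs, the pairs merge to the first-appearing pair when every pairwise
   Euclidean distance is within 400 m (a distance of exactly 400 m merges;
   the boundary had to be assigned to one side and a single rule is easier
   to audit). Larger separations are treated as genuinely different
   sampling locations and left alone. Then, identifiers sharing one exact
   coordinate pair collapse to the first-appearing identifier. Coordinates
   are resolved first because merging can create the exact equality the
   identifier pass keys on. Inputs are assumed to be projected in meters
   (an equal-area projection); no geodesic distances are computed.
3. **Filter cascade** (steps 3–11): medium must be water; the date must
   parse; the chemical form must be recoverable (below); the concentration
   must be a positive number unless the record is a non-detect — zero and
   negative values without non-detect metadata are unexplainable and
   dropped; units must convert to mg/L (non-detects with no reported value
   are exempt, their detection limit carries the units); detection codes
   indicating contamination drop the record; the sample fraction must map
   to filtered, unfiltered, particulate, inorganic or organic ("dissolved"
   counts as filtered, "total" as unfiltered); quality-control activity
   types drop; result types containing "approximation" or "educated guess"
   drop. Once a rule fires, later flags on that row are the literal string
   `NA` — each row carries at most one drop reason.
4. **Chemical form and units** (steps 5, 7, 12): the form is taken from the
   nutrient name when it carries an "as X" suffix, else from the unit text,
   else from a small analytical-method registry; molecular values are
   multiplied by fixed factors (NH3 0.822, NH4 0.776, NO3 0.225, PO4 0.326)
   to the elemental basis, at the printed three-decimal precision — the
   factors are conventions of the reporting standard, not re-derived from
   atomic masses. Units convert by registry (ug/L ×0.001, ppm ×1 under the
   dilute aqueous convention). Molar units (umol/L) are deliberately
   unconvertible: the molar mass depends on a form that is often unknown.
   Units are applied before form factors; both are scalar multiplications,
   so the order is fixed purely for determinism.
5. **Non-detects** (steps 8, 14, 15), described in the next section.
6. **Outliers** (step 16): per nutrient parameter, pooled over all years,
   concentrations outside the 1st–99th percentile band (type-7 linear
   interpolation) are flagged `potential_outlier` but kept. Groups with
   fewer than three values have degenerate thresholds and are left
   unflagged. Flagging runs before daily averaging, on per-record values;
   a daily average inherits the flag when any member carried it.
7. **Duplicates** (step 17): records identical up to the reporting
   organization collapse to one, under the lexicographically first
   canonical name. Remaining same-day values for a site and nutrient
   parameter — with or without timestamps — average arithmetically into
   one daily value; when the average mixes detected and imputed members it
   is flagged `imputed`.
8. **Fraction combination** (step 18): where a site-date has filtered and
   particulate totals but no unfiltered total, their sum is added as a new
   unfiltered observation flagged `calculated_by_combining`.
9. **Consistency QC** (step 19): a filtered concentration greater than or
   equal to its same-site-date unfiltered counterpart is physically
   impossible; both members are flagged and excluded. Both are dropped,
   not one, because either could be the wrong one.

## The censored-lognormal imputation model

A non-detect is identified by two joint conditions: the reported value is
zero, negative or missing, *and* the detection code or text says
non-detect. Its true concentration lies somewhere in (0, DL]. Simple
substitutions (zero, DL/2, DL) bias group statistics, so censored values
are multiply imputed under

$$\log c_i \sim \mathrm{Normal}(\mu, \sigma^2), \qquad
  \mu \sim \mathrm{Normal}(0, 1000^2), \qquad
  \sigma^2 \sim \mathrm{InvGamma}(0.001, 0.001),$$

per group of observations sharing a site, nutrient parameter and year —
only values from the same site inform a site's imputations. A Gibbs
sampler augments the censored values as latent draws from the normal
truncated above at $\log \mathrm{DL}_i$ (so every imputed concentration is
in (0, DL]); after 1000 burn-in iterations, K = 10 draws are retained at a
thinning interval of 10 and averaged on the concentration scale into one
imputed value per censored record. Groups in which 80% or more of the
records are non-detects are too censored to support the model: their
non-detects stay missing (`conc = NA`) and are flagged so users can treat
them as they see fit. The truncated-normal draw uses the inverse-CDF method
down to six standard deviations and an exponential rejection sampler
beyond, so detection limits far below the group mean cannot produce
infinite or out-of-bound draws.

Non-detects reported without a detection limit receive a conservative
common limit per nutrient-year: among organizations that reported
limit-less non-detects that year, each organization's smallest detected
concentration bounds its method's limit from above, and the largest of
those minima — the least sensitive plausible method — is assigned. When no
such organization has any detected value, the limit is unassignable; those
records stay in the flagged output as non-detects but are excluded from the
harmonized table, because a harmonized row for them could state neither a
concentration nor a detection limit.

Two presentation choices follow from the schema invariants: harmonized
rows whose group crossed the 80% cutoff keep `impute_flag = "imputed"`
with a missing concentration (the flag marks non-detect provenance, and
their outlier flag is `NA` because no determination is possible), and in
the flagged table `new_conc` carries the imputed value for imputed
non-detects so the audit trail shows what entered the daily averages.

## The synthetic generator

There is no small "real" input that exercises all of this, so the package
generates its own: latent sites in a projected window, lognormal latent
concentrations per nutrient parameter, and a reporting layer that corrupts
them the way multi-organization exports do — molecular-basis values (the
exact inverse of the conversion factors), unit dialects (including ug/L
rescaling and unconvertible units), censoring below a per-org-nutrient-year
detection limit placed at the `nd_rate` quantile of the latent
distribution (so the censored share matches the nominal rate), non-detects
encoded as zero/negative/missing with detection codes and sometimes no
limit, organization spelling variants, duplicate coordinates offset
uniformly in (0, 800) m so both merge branches occur, duplicate
identifiers, sub-daily repeats, verbatim cross-organization duplicates,
and per-record metadata faults feeding every cascade step. A truth sidecar
records each row's latent site, true elemental concentration and expected
fate.

Two structural choices keep the truth exact rather than probabilistic: a
nutrient appears at most once per site-date among naturally drawn records
(same-day repeats and filtered/unfiltered pairs are *injected*, never
accidental), and injected pairs sit alone on their site-date so the
step-19 comparison involves exactly the two members, neither of which is
ever censored. Under any single corruption family the expected fates are
exact; when many families are combined, rare interactions are resolved in
cascade order and the defaults keep them negligible.

Default study conditions: 6 organizations, 25 sites, 8 years from 2000,
about 6 records per site-year (Poisson), 20% censoring with 30% of
non-detects lacking a limit, and single-digit percentage rates for each
fault family — a deliberately messy but realistic mix in which roughly
three quarters of records survive. What the generator does **not**
emulate: spatial autocorrelation, seasonality, trends, inter-nutrient
correlation, or organization-specific reporting culture. Passing tests
therefore demonstrate that the *rules* are implemented faithfully on data
whose truth is known, not that any particular real export will survive in
similar proportions.

## Determinism and numerical choices

All randomness (the imputation sampler) flows through one generator seeded
from `rng_seed` in the configuration; imputation groups are processed in
sorted key order, so a fixed input and configuration give byte-identical
outputs. Concentration text is parsed strictly (anything non-numeric is
"nonsensical"); generated values are printed with 15 significant digits so
unit/form round-trips recover the truth to well under 1e-9 relative error.
Detection limits with a value but no units are assumed already in mg/L.
CSV outputs write missing values as empty strings, except in flag columns
where the literal string `NA` is itself a flag value meaning "already
dropped at an earlier step".

The test suite and the acceptance script run the full pipeline on
generated tables of roughly 1,200–4,000 rows and the imputation
simulation at 50 replicates of a 200-observation group with 30% censoring
— sizes chosen so the whole battery completes in a few minutes while
every group structure (censored shares on both sides of the cutoff,
multi-member daily groups, both merge branches) still occurs.

## Known limitations

* The analytical-method registry is a small static table; a production
  deployment against a real export would extend it (it is plain config
  data).
* The raw-column dialect is a documented canonical header set; exports
  with other headers must be renamed on the way in.
* Hydrolyzable and soluble-reactive phosphorus names are mapped
  unknown-form by default (they straddle harmonized categories); the
  vocabulary is user-editable.
* The imputation model is univariate; no covariates, no trend, no
  Kaplan–Meier or regression-on-order-statistics alternatives.
* The flagged table reports group-level imputation flags, so an
  individual detected row in an imputed group reads `impute`; the
  harmonized table distinguishes members by `impute_flag` after
  averaging.
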