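---
title: "The equivalent-value workload model for village doctors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The equivalent-value workload model for village doctors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evworkload)
```

## The problem

China's National Essential Public Health Services (NEPHS) program delivers
twelve types of free primary public health services — resident health
records, health education, immunization, child / maternal / elderly health
management, hypertension, type II diabetes and severe-mental-illness care,
infectious-disease reporting, traditional-Chinese-medicine management and
health-supervision assistance — through township hospital centers (THCs)
and the village clinics below them. Policy requires THCs to delegate **no
less than 40%** of this workload to village doctors. Service items are
wildly heterogeneous (a record update takes minutes; an annual
health-education plan takes days), so raw service counts cannot be compared
or summed, and the delegated fraction cannot be read off volumes alone.

The equivalent-value (EV) model solves this with a time-based common
currency: the **standard clinic visit**, a family physician consulting one
patient for 15 minutes, defined to have EV 1. Every service item is scored
by its person-minutes:

$$EV_i = \frac{\text{person-minutes}_i}{15}.$$

With $A_i$ the EV of item $i$, $B_i$ its annual delivery volume, and
$C_i \in [0,1]$ the fraction of that volume carried out by village doctors,

$$Y = \sum_i A_i B_i, \qquad X = \sum_i A_i B_i C_i, \qquad
\text{share} = \frac{X}{Y} \times 100\%,$$

summing over every surveyed (THC, item) pair in scope. The share is a
volume-and-weight-adjusted delegation rate: the percentage of total
standardized workload actually performed at the village level. It can be
computed at any scope — item, service type, THC, province, or overall —
because $X$ and $Y$ are exactly additive over any partition of the
(THC, item) pairs.

## The catalog

`builtin_catalog()` ships the 2016 catalog: 38 items in the 12 service
types, with person-minutes fixed separately for two workload regimes,
`mid_east` (eastern and central China, combined because their time costs
were close) and `western`, where lower population density and mobile
delivery raise the time cost of many items. EVs are **derived** from the
minutes at load time; the stored EV column in a catalog file is only a
checksum, rejected if it strays more than 0.05 (half a display decimal)
from minutes/15. All shipped minutes are multiples of 1.5, so the derived
EVs are exact at one decimal. One cell deserves a note: the mid-east
minutes for discovery/registration of infectious diseases are typeset
ambiguously in the published catalog table; the reading 114 minutes
(EV 7.6) is the only one consistent with the printed EV.

EVs are carried **unrounded** through every aggregation; rounding happens
exactly once, at report rendering (EV totals in millions to 2 decimals,
by-type shares to 2 decimals, by-province shares to 1 decimal). This
matters: the published by-type table is internally inconsistent at display
precision (its rounded EV columns give 4.19/7.35 = 57.01 against a printed
57.00, and column sums of 42.33/18.51 against printed totals of
42.32/18.50), which is exactly the signature of computing on unrounded
values and rounding only for display. The package reproduces that behavior,
and its tests check recomputation from rounded columns only to the
rounding-induced tolerance of ±0.6 percentage points.

## Survey data model

A survey is a long table of (THC, item) rows carrying the sampling
hierarchy (province / prefecture / county / THC), the THC's catalog region,
the annual volume $B$ and the village-doctor fraction $C$. Choices made
where the data format was genuinely open:

* **Fractions inside, percent outside.** Shares are stored as fractions in
  [0, 1] because the $X$ formula needs fractions, but every file and report
  surface uses percent, which is how such figures are reported and read.
* **Missing items are zeros, not errors.** A THC with no row for an item is
  treated as not delivering it (volume 0, share 0); the aggregates are
  unchanged whether or not the zero rows are materialized
  (`complete_survey()` materializes them for display).
* **Volumes are non-negative reals**, not integers, since departments may
  report apportioned or annualized figures.
* $C$ is interpreted as the fraction of each item's **raw volume**
  delivered by village doctors. Whether the reporting departments weighted
  by EV when estimating it is unknowable from the published materials; raw
  volume is the minimal reading and the one the formulas use.

Validation is strict and row-addressed: alien item ids, unknown regions,
negative volumes, shares outside [0, 1] (or [0, 100] in percent form), and
THC ids that appear under two hierarchy positions are all rejected with the
offending rows listed.

## The synthetic generator

The THC microdata behind the published 2016 aggregates were never released,
so the package ships a seedable generator that emulates the study design
and is the substrate for all end-to-end testing.

* **Sampling frame**: 6 provinces × 5 prefectures × 2 counties × 5 THCs
  = 300 THCs, the study's stratified frame.
* **Regions**: the published results never map the anonymized provinces
  1–6 to regions. The default assigns provinces 1–4 to `mid_east` and 5–6
  to `western` — a labeled assumption (four of the six sampled provinces
  were eastern/central), overridable per profile.
* **Share targets**: province × service-type village-doctor share targets
  are the published provincial share matrix divided by 100
  (`published_shares_by_province()`).
* **Base volumes**: the published results report aggregate EVs only, never
  raw volumes, so per-item mean volumes are invented — but not arbitrary:
  each type's published EV total (across 300 THCs) is split equally across
  the type's items in EV terms and converted to a per-THC annual count via
  the frame-weighted mean EV. The default dataset therefore totals ~42
  million EVs with the published per-type composition.
* **Noise**: volumes are log-normal around the item mean with coefficient
  of variation 0.4 (between-THC catchment-size variation), rounded to whole
  counts and then multiplied by the province's `volume_scale` (scaling
  after rounding keeps share invariance under rescaling exact). Shares are
  Beta-distributed with mean equal to the target and precision
  (`share_concentration`) 100, i.e. a between-THC standard deviation of
  roughly 5 percentage points around the provincial target; precision
  `Inf` degenerates to the target exactly. One share draw per service type
  per THC is applied to all the type's items, mirroring one delegation
  estimate per THC department. Both families are the minimal distributions
  with the required supports; nothing in the published materials constrains
  them further.
* **Seeding**: one master seed; each THC draws from its own sub-stream
  derived deterministically from the master seed and the THC's frame
  position, so datasets are byte-reproducible and independent of
  generation order, and the caller's RNG state is untouched.

**What the generator does not emulate.** Each province's *volume
composition* is common across provinces (only targets and scale differ),
because the published data do not reveal per-province volume mixes. A
consequence worth understanding: synthetic provincial *totals* converge on
the EV-weighted mean of that province's per-type targets
(`expected_province_totals()`), not on the published provincial totals,
which embed the real, unpublished volume mixes. Parameter-recovery tests
therefore compare against the EV-weighted means. The generator also omits
survey nonresponse, measurement error in $C$, within-type heterogeneity of
delegation across items, and THC staffing structure. Passing tests show
the pipeline is correct and the estimator unbiased under this design — not
that real surveys are free of those complications.

## Numerical choices

* Shares with $Y = 0$ are **undefined** (`NA`), never 0 or 100; they render
  as an em dash, and are excluded from min/max footers and compliance
  counts.
* The 40% requirement is a **closed** bound ("no less than"): a share of
  exactly 40 is compliant.
* An $X > Y$ (possible only if some upstream share exceeds 1) triggers a
  classed warning rather than silent clamping.
* Scope descriptors compose conjunctively (e.g. province AND service type);
  the empty scope is the overall aggregate.
* Min/max summaries break ties by first occurrence in catalog /
  configuration order.

## Problem sizes in the tests

The test suite builds everything in code: a 3-item toy catalog for
hand-checkable sums and oracle comparisons (a naive triple loop reproduces
engine $X$, $Y$ and share to 1e-12 on random ≤ 5-THC datasets), small 8-THC
frames for I/O round trips, and the full 300-THC frame for the study-design
and parameter-recovery checks, the latter across 20 seeds (recovered
provincial totals are required to sit within 2 percentage points of their
EV-weighted expectations; observed errors are well under 1). The whole
suite runs in well under a minute.

## Limitations

The model measures *assigned* workload as reported by THC departments;
village doctors' own accounting of their workload could differ, and the
delegation fraction is an estimate, not a time-and-motion measurement. The
catalog's person-minutes are 2016 expert-consensus values for two broad
regions; applying the model elsewhere or later requires re-scoring the
catalog, which `load_catalog()` supports with any region list. Shares are
reported without sampling uncertainty, matching how such survey aggregates
are published.
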