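---
title: "Constructing and validating small-area food insecurity risk indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating small-area food insecurity risk indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodriskindex)
```

## The problem

Household food insecurity in England varies at a very fine spatial scale:
pockets of high risk sit inside otherwise affluent neighbourhoods, and the
pressures differ between urban areas (low income, benefit dependence, poor
mental health) and rural ones (distance to stores, sparse public transport,
slow internet, remote employment). `foodriskindex` builds composite risk
indices at the LSOA scale (Lower Super Output Areas, census small areas of
roughly 1,500 residents; 32,844 in England) from openly published
indicators, ranks every area so that rank 1 marks the population most at
risk, and quantifies how well each index agrees with external deprivation
criteria.

Four index variants share one construction machinery:

* **Simple Index** — benefit-claimant domain + household-type domain,
  equally weighted;
* **Complex Index** — a *Compositional* domain (claimant %, low-income
  household %, no-qualifications %, mental ill-health score) plus a
  *Structural* domain (travel time to employment, download speed, bus-stop
  density, distance to large grocery stores), equally weighted;
* **Compositional Domain** and **Structural Domain** as single-domain
  indices.

## The construction pipeline

For each index variant the stages are:

1. **Orientation.** Each indicator is aligned so that the smallest value
   marks the theorised highest risk (`orient_for_risk()`): risk-increasing
   indicators (claimant %, travel time, store distance, ...) are negated;
   risk-decreasing ones (download speed, bus-stop density) pass through.
   Negating *before* ranking means no stage downstream needs direction
   metadata.
2. **Rankit scoring.** Every indicator is mapped to normal scores
   (`rankit_scores()`): the value with ascending rank $r$ among $n$ areas
   receives $\Phi^{-1}\!\big((r - 0.5)/n\big)$. The $(r-0.5)/n$ plotting
   position is the canonical Rankit choice; ties take the mean of the ranks
   they span, which keeps the scores antisymmetric about zero. This puts
   indicators with incommensurable units and denominators on one scale
   before they are combined.
3. **Domain scores.** Scores in a domain are summed with equal weights
   (`domain_score()`); no evidence base supports unequal indicator weights.
4. **Unit scaling.** Raw domain scores are rank-scaled onto $(0,1)$ by
   $(n - r + 0.5)/n$ with most-at-risk $\to$ largest value
   (`scale_to_unit()`). The formula keeps values strictly inside the open
   interval so the next stage never evaluates $\ln$ at its endpoint.
5. **Exponential transformation.** `exponential_transform()` applies
   $X = -c\,\ln\!\big(1 - s\,(1 - e^{-R/c})\big)$ with scaling constant
   $c = 23$ and range constant $R = 100$, the transform used by the Index
   of Multiple Deprivation. It maps $[0,1]$ onto $[0,100]$, is strictly
   increasing and convex, and therefore reduces *cancellation*: an area
   with one extreme-risk domain and one low-risk domain outranks an area
   with two middling domains whose plain average would tie it.
6. **Combination and ranking.** Transformed domain scores are summed with
   equal domain weights (`combine_domains()`; each of two domains
   contributes 50% of the composite), ranked with competition ties
   (`rank_index()`: tied areas all take the lowest applicable rank), and
   cut into deciles (`assign_deciles()`: decile $d$ holds ranks in
   $((d-1)n/10,\; d\,n/10]$, decile 1 = most-at-risk tenth).
7. **MSOA aggregation.** Validation criteria published only at the MSOA
   scale (~7,000 residents) are compared against the index aggregated by
   *summing* each domain's transformed LSOA scores within the MSOA
   (`aggregate_to_msoa()`), then combining and ranking as before.
   Summation, not averaging, is the documented aggregation of the source
   methodology; it does give more weight to MSOAs containing more LSOAs,
   a property we preserve rather than correct.

### Orientation of the transformed scale

Two conventions are self-consistent: the IMD convention, where the
most-at-risk area carries the *largest* scaled and transformed score (so
rank 1 attaches to the largest composite), and the mirrored presentation
where the most-at-risk area carries the smallest score. The published
description of this method mixes the two ("rank 1 = the lowest score"
alongside an IMD-style transform), so `build_index()` exposes
`orientation = "risk-high"` (default) or `"risk-low"`. The method is
always *computed* in the risk-high orientation; `"risk-low"` mirrors the
reported columns ($s' = 1 - s$, $X' = R - X$) and ranks the smallest
composite first, which guarantees the two orientations produce identical
rank sets. MSOA aggregation always sums the risk-high transformed scores:
summing mirrored scores would add an offset proportional to the number of
LSOAs in each MSOA.

### Numerical and degenerate-input choices

* Rankit requires $n \ge 2$ finite values; a constant vector yields all-tied
  scores of 0.
* Decile assignment requires $n \ge 10$; a tied block spanning a decile
  boundary shares its minimum rank and so falls in the earlier
  (higher-risk) decile.
* Areas with a missing value in any selected indicator are excluded from
  that index build with a logged count; no imputation is applied.
* All agreement statistics are computed on rank vectors, not raw scores,
  with rank 1 = least desirable outcome on both sides.

## The validation battery

`validate_index()` compares an index ranking with a criterion ranking
(an IMD-like deprivation score at area level; free-school-meals % and
child-obesity % at MSOA level), overall and stratified by the urban/rural
flag:

* **Spearman rank correlation** (`spearman_rank_corr()`): Pearson
  correlation of tie-averaged ranks.
* **Decile chi-square** (`decile_chi_square()`): Pearson $\chi^2$ on the
  10×10 decile cross-tabulation, no continuity correction (irrelevant at
  this table size); empty decile levels are dropped with the degrees of
  freedom adjusted, and a full table has 81 df. For identical decile
  vectors with uniform marginals the statistic is exactly $9n$.
* **ICC(A,1)** (`icc_agreement()`): single-rater absolute-agreement
  intraclass correlation from the two-way ANOVA decomposition of the
  $n \times 2$ rank table,
  $(MS_{rows} - MS_{err}) / (MS_{rows} + MS_{err} + \tfrac{2}{n}(MS_{cols} - MS_{err}))$,
  with the McGraw–Wong F-based 95% confidence interval. Absolute agreement
  (not consistency) penalises systematic shifts between the two rankings.
  The point estimate is returned unclamped, so strong disagreement can
  produce negative values; published applications of this battery have
  printed values below $-1$, which the ICC(A,1) formula does not generally
  produce, and we document rather than reproduce that anomaly. No
  multiple-testing adjustment is applied to the reported p-values.

`top_decile_summary()` reports the regional and urban/rural composition of
decile 1, the most-at-risk tenth.

## The synthetic small-area generator

Real inputs (DWP benefit counts, census tables, IMD components, Ofcom
speeds, bus-stop and store coordinates) require national downloads, so the
package ships a seeded generator whose output has the joint structure the
analysis assumes — a linear-Gaussian latent model with monotone links, the
simplest structure that supports rank-based recovery tests:

* a nested geography (regions → MSOAs → LSOA-like areas) with planar
  centroids placed so that within-MSOA distances are smaller than
  between-MSOA distances, populations near 1,500, and
  $\lceil$`rural_proportion`$\cdot N\rceil$ areas flagged rural
  (default 0.2, a configurable stand-in — the national split is not a
  published constant of this model);
* a standardised *compositional* latent $L_{comp}$ with a region-level
  random intercept (sd 0.3, so regional top-decile summaries have
  non-trivial structure) and a standardised *structural/accessibility*
  latent $L_{struct}$ shifted by `rural_accessibility_shift` (default 1)
  in rural areas;
* indicators $= \lambda \cdot L + N(0, \sigma)$ (default loadings 0.8,
  default `noise_sd` 0.3) pushed through monotone links to natural scales:
  percentages affine and clipped to $[0,100]$ with means kept away from
  the bounds so clipping is rare and ranks are preserved; log-linear links
  keep travel time, speed, density and distance positive, decreasing for
  the two access indicators whose high values mean low risk;
* store and bus-stop point sets with urban intensity 10× rural, from which
  the pipeline *re-derives* the bus-stop density (stops per km²) and
  nearest-store Euclidean distance indicators, exercising the derivation
  code end-to-end;
* validation variables loading on $L_{comp}$ (defaults: IMD-like 0.9,
  FSM 0.75, obesity 0.65, ordered to echo the relative agreement strengths
  seen with real criteria), with the MSOA-level pair built from the mean
  latent of each MSOA's areas plus noise.

Everything is deterministic in `seed`: each stage derives its own
sub-stream, so identical configurations reproduce byte-identical tables.

**What passing tests do and do not show.** The generator controls rank
correlations through loadings in a clean linear-Gaussian world. Real
indicators are skewed, have point masses and disclosure-rounded counts,
spatially autocorrelated noise, and denominators that disagree between
sources. Tests on synthetic data therefore verify that the *machinery* is
correct (transform algebra, tie rules, aggregation, agreement statistics,
recovery of a known ordering) — they do not certify the empirical validity
of any specific index on real English data.

## Problem sizes used by the tests

The test-suite uses geographies of 500–5,000 areas: large enough for
Monte-Carlo checks of loading recovery (±0.1 at $n \ge 2000$) and null
calibration of the decile chi-square (500 independent pairs of $n = 1000$),
small enough to keep the whole suite quick. Latent-recovery acceptance runs
30 replicate datasets of 2,000 areas; the decile-sizing check uses the full
national count of 32,844 areas, where the most-at-risk decile must hold
3,284 areas.

## Known limitations

* Joint low-income household prevalence multiplies two census marginals
  under an independence assumption; no cross-tabulation exists to do
  better.
* Point-to-area assignment of bus stops is taken from the supplied
  mapping; polygon point-in-polygon tests and real boundary geometries are
  out of scope, as are travel-time computation, network routing, and
  geodesic distances (store access is planar Euclidean by design).
* MSOA aggregation by summation weights large MSOAs upward, as published.
* Ranks are relative: an area's rank says nothing absolute about the
  prevalence of food insecurity within it.
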