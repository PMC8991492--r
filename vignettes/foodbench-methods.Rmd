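---
title: "Benchmarking food-industry commitments and practices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking food-industry commitments and practices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodbench)
```

# The problem

Food-environment accountability studies score what companies *say*
(nutrition-related commitments, assessed with the BIA-Obesity tool across
six policy domains) against what they *do* (the nutritional quality of
their portfolios, their promotion practices, the placement of their
outlets), and then ask whether stronger commitments go with stronger
practices. The real inputs of such studies — national branded-food
composition databases, company documents, a year of collected supermarket
flyers, commercial retail-location data — are proprietary. `foodbench`
reimplements the full analysis pipeline and pairs it with a synthetic-data
generator whose ground truth is known, so every stage is testable at desk
scale.

# Nutrient profiling

## Nutri-Score

The 2017 points algorithm (the version in force in Belgium during
2019–2020) is implemented, not the 2023 revision. Unfavourable points
$N$ sum four components scored 0–10 (energy kJ, total sugars, saturated
fat, sodium; one point per threshold *strictly* exceeded); favourable
points cover fruit/vegetables/nuts (0/1/2/5 at >40/>60/>80%, doubled for
beverages), fibre (AOAC thresholds) and protein (0–5 each). The final
score is $N - P$; classes are A ≤ −1, B 0–2, C 3–10, D 11–18, E ≥ 19 for
foods and (water → A) B ≤ 1, C 2–5, D 6–9, E ≥ 10 for beverages. When
$N \ge 11$ protein points are dropped unless the product is a cheese or
scores maximal fruit/veg points. Added fats replace saturated-fat points
with a saturated/total-fat ratio scale whose bands step by 6 percentage
points from 10% to ≥ 64% with *inclusive* lower bounds — note the
asymmetry with the strictly-greater nutrient thresholds; both follow the
official tables, and the package's oracle panel
(`tests/testthat/helper-fixtures.R`) is hand-scored from them.

## WHO-Europe model

A configurable rule table maps each product's category to either an
outright marketing prohibition or a set of per-100 g maxima (energy, total
fat, saturated fat, total sugars, added sugars, salt, plus a
no-added-sweeteners flag). Decision semantics, fixed once and
boundary-swept in tests: **inclusive** limits (a value exactly at the
limit passes), complete violation lists (no short-circuiting), errors —
never silent permission — when a nutrient required by an active threshold
is missing. Salt is derived as sodium × 2.5/1000 when absent. The shipped
default table (`inst/extdata/who_rules.csv`) encodes the 17-category
structure of the published 2015 European model with illustrative default
thresholds; any threshold can be deactivated (`NA`), which is also how
added-sugar limits are handled when labels only report total sugars.
One deliberate deviation: the source model permits fresh/frozen fruit and
vegetables outright, but the package's table contract requires every
non-prohibited category to carry at least one threshold, so that category
carries a nominal 1 g salt limit that fresh produce cannot realistically
exceed.

## NOVA

The source studies hand-classified products; automation here is rule-based
with a precedence order: curated per-product override, then
ultra-processed marker tokens (flavouring, colour, emulsifier, sweetener,
hydrolysed protein, maltodextrin, glucose-fructose syrup, modified
starch → group 4), then category defaults, then a global fallback
(group 3). Group 4 defines "ultra-processed" everywhere downstream.

# Commitment scoring

Domain scores are $100 \cdot \sum \text{raw} / \sum \text{max}$ over the
applicable indicators of a domain; a domain whose indicators are all
inapplicable is *undefined* (`NA`), never zero — zero would penalise
inapplicability — and undefined domains trigger weight renormalisation in
the weighted overall score. The industry-specific domain weights of the
published tool are supplementary material not reproduced here; the shipped
default is uniform (1/6) and clearly illustrative.

Engagement is analysed with a one-sided Wilcoxon signed-rank test
(post > pre), dropping zero differences (classic convention; Pratt
handling is available); participant vs non-participant scores use a
two-sided rank-sum test. Both tests are exact up to combined n = 20 via
generating-function convolution over doubled midranks (tie-aware,
conditional on the observed ranks) and use a tie-corrected,
continuity-corrected normal approximation beyond, always reporting which
method produced the p-value.

# Performance indicators

Per company: ordinal median Nutri-Score class (A→1 … E→5; an even-n
midpoint rounds toward the *less healthy* class — a conservative
convention, since the source material never states its rule), %A/B, %D/E,
%UPF, %not-permitted, %displaying the label. Portfolios under 3 products
are computed but flagged `reported = FALSE` (mirroring the exclusion of a
2-product portfolio from the source study's performance results) and are
excluded pairwise from correlations. Industry aggregation is
median/min/max. Flyer promotions are analysed per supermarket over all
records and cover-only records; "fresh fruit and vegetables" is a coded
flag on the record rather than an inference from the WHO category, which
also contains frozen and legume items counted separately. Outlet
accessibility is the proportion of a company's outlets within 500 m
shortest-path distance of the nearest school entrance of a given level;
locations snap to road-graph nodes, disconnected outlets count as beyond
the radius with a warning, and companies with fewer than 3 outlets are
flagged, mirroring the source study's exclusion of a 2-outlet chain.

# Linkage statistics

Spearman's ρ is the Pearson correlation of midranks. For n ≤ 8 the
two-sided p-value is exact over all n! permutations; beyond that the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ is used, with the method
reported. Constant inputs yield an undefined-ρ row (the "no correlations
could be calculated" case) rather than a dropped one. The suite computes
exactly the benchmark's pairings — formulation score vs {%A/B, %D/E,
median class as its 1–5 code, %UPF}; promotion score vs %not-permitted —
with no multiplicity correction (the convention of the source analyses); a
Holm-adjusted column is emitted alongside, clearly marked as an extension.

# The synthetic world

Each company draws a latent healthiness $\theta \sim N(0,1)$. The
coupling $c \in [-1, 1]$ enters through two side latents,
$u = c\theta + \sqrt{1-c^2}\,\varepsilon_1$ (commitments) and
$v = c\theta + \sqrt{1-c^2}\,\varepsilon_2$ (portfolio), so the
$\theta$-side correlations equal $c$ by construction and the implied
population Spearman between a domain score and a continuous portfolio
indicator is $(6/\pi)\arcsin(c^2/2)$ (≈ 0.622 at $c = 0.8$), recorded as
`rho_target` in `truth.csv`. An earlier design gated the verified-stage
score uplift on the participation flag; that made the flag act as
unmodelled noise and broke the exact rank agreement the perfect-coupling
world must show, so the uplift (+0.7 latent units, emulating information
completion during engagement, roughly the observed 34% → 51% median shift)
applies to every verified sheet and the flag only selects which companies
enter pre/post and participant/non-participant comparisons.

Portfolios draw per-category truncated log-normals (σ = 0.4 on the log
scale) around per-category medians chosen so the default world lands in
the qualitative regime the source reports: majority ultra-processed,
majority not permitted, %A/B mostly between 10% and 60%, median classes
B–D. The company latent shifts unfavourable nutrients down and
fibre/fruit-veg up by $1.0\,v$ on the z-scale, and lowers the probability
of ultra-processed marker tokens by $1.0\,v$ on the logit scale. Company
counts default to the benchmarked panel (19 manufacturers, 5 supermarkets,
7 quick-service chains), participation to 18/31, portfolio sizes to
2–300 products, flyers to 52 weeks with ≈ 58 promotions/week/supermarket
(≈ 15 000 promotions/year over five supermarkets) with category and flag
frequencies anchored to the reported promotion mix (52% UPF, ≈ 20% premium
offers, ≈ 5% characters, < 2% showing a Nutri-Score, cover promotions
skewed healthier). The geo scene is a grid road network whose edge
lengths exceed node spacing by a random 0–15% curvature factor, so network
distance provably dominates Euclidean distance.

`noise_sd` (default 0.3) scales everything idiosyncratic below the
latents: indicator-level score wobble, a mild company-specific
category-mix tilt (at half scale — strong specialisation would attenuate
the coupling contract), and product-level draws. At `noise_sd = 0` the
generator collapses to a deterministic world — equal portfolio sizes, the
global mix, per-category quantile grids, cyclic marker-token assignment —
which is what makes the perfect-coupling example hold *exactly*.

**What a green test does and does not establish.** The generator emulates
the statistical shape of the study inputs, not real brands, market shares
or a real road network; log-normal nutrient distributions are a modelling
convenience (the distributional shape of real portfolio nutrients is not
published). Recovery tests therefore validate the pipeline's internal
consistency, not the field validity of any threshold table.

# Numerical choices and limitations

* All rank statistics use midranks; exact distributions are conditional on
  the observed (mid)ranks, with doubled ranks giving integer
  generating-function supports.
* Exact/approximate switchovers: n ≤ 20 (both Wilcoxon variants), n ≤ 8
  (Spearman permutation).
* Tertile bands in the report are rank-based thirds with a ceiling split
  and deterministic identifier tie-breaks; industries with fewer than
  three companies skip banding with a note.
* All randomness flows from one config seed through fixed per-stage
  substreams, so skipping a stage never changes another stage's output and
  rerunning a manifest-identical config is checksum-identical.
* Measured at coupling 0.8, the mean recovered ρ per pairing is ≈ 0.53–0.56
  in magnitude against the 0.622 target — finite portfolios (sizes down to
  2), indicator discreteness (the 5-level median class most of all) and
  score wobble attenuate the rank correlation; the recovery acceptance
  criterion (±0.1) passes with margins of ≈ 0.06–0.09, and those margins
  were measured before the test seeds were frozen, not tuned afterwards.
* The type-I acceptance criterion (coupling 0, n = 31, 500 replicate
  studies) observes per-pairing rejection rates of ≈ 0.03–0.06 at
  p < 0.05, inside the required [0.02, 0.08] band; the t-approximation is
  mildly conservative for the heavily tied median-class indicator.
* Sales-weighted healthiness metrics, per-serving evaluation, the 2023
  Nutri-Score revision and added-sugar estimation from total sugars are
  out of scope.
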