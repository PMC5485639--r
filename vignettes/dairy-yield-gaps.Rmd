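---
title: "Methods: benchmarking, frontier analysis and household simulation of dairy yield gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking, frontier analysis and household simulation of dairy yield gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairygap)
```

`dairygap` combines three complementary ways of asking how much more milk
smallholder dairy households could produce: an empirical benchmark (what
do the best farms already achieve?), an econometric frontier (how far is
each farm from the best practice its input bundle allows?), and a
bio-economic simulation (which concrete nutrition and breeding
interventions move a typical household toward those levels, and at what
profit?). This vignette documents the models, their assumptions, every
tunable constant, and the choices made where the design was genuinely
open.

## 1. Top-decile benchmarking

For each agricultural zone the *attainable yield* is the mean
per-head, per-lactation milk yield of the top 10% most productive farms,
and the *relative yield gap* is its difference from the zone mean,
absolute (kg/head/lactation) and as a percentage increase.

Decisions:

* **Decile size** is `ceiling(n/10)`, so small zones always contribute at
  least one farm; ties at the cutoff are broken by record order, making
  the selection deterministic and permutation-invariant in value.
* **Rounding** of the reported percentage is half-away-from-zero to an
  integer; the unrounded value is always kept alongside.
* **Published-table quirks.** Two cells of the published zone table do
  not recompute from its own printed means (an absolute gap of 1666 where
  the printed means give 1665, and a percentage of 219 where they give
  218.47); the upstream table was evidently computed from unrounded means
  that were not printed. `compute_yield_gap()` reports its own exact
  arithmetic; the discrepancy is noted in the function help.
* Ranking is by per-head yield only — survey records are not
  disaggregated by breed, so no breed stratification is attempted.

## 2. Stochastic frontier analysis

Farms produce several outputs (milk, livestock sales, other farm output)
from several inputs (land, herd, feed, labour, capital). A Cobb-Douglas
*output distance function* handles this: imposing linear homogeneity in
outputs by normalizing on one output $y_M$ gives the regression

$$-\ln y_{M,i} = \alpha_0 + \sum_k \beta_k \ln x_{k,i}
  + \sum_{m \ne M} \gamma_m \ln(y_{m,i}/y_{M,i}) + v_i + u_i,$$

with noise $v_i \sim N(0, \sigma_v^2)$ and one-sided inefficiency
$u_i \ge 0$ half-normal. The composed-error density is
$f(\varepsilon) = (2/\sigma)\,\phi(\varepsilon/\sigma)\,
\Phi(\lambda\varepsilon/\sigma)$ with
$\sigma^2 = \sigma_v^2 + \sigma_u^2$,
$\gamma = \sigma_u^2/\sigma^2$ and
$\lambda = \sqrt{\gamma/(1-\gamma)}$. At $\gamma = 0$ this collapses to
ordinary least squares, which the tests verify both analytically and on
simulated data.

Implementation choices:

* **Parameterization** is $(\sigma^2, \gamma)$, the convention of the
  classic frontier-estimation software lineage; internally $\gamma$ is
  optimized on a logit scale and $\sigma^2$ on a log scale so the
  optimizer works unconstrained.
* **Starting values** come from corrected OLS: slopes from least squares,
  $\sigma_u$ from the third central moment of the residuals (the
  half-normal's skewness), the intercept shifted by
  $E[u] = \sigma_u\sqrt{2/\pi}$, with a $\gamma$ floor of 0.05 and extra
  starts at $\gamma \in \{0.3, 0.7\}$; the best likelihood wins.
* **Efficiency scores** use the conditional expectation
  $TE_i = E[e^{-u_i}\mid\varepsilon_i]$ (the Battese–Coelli form, the
  default of that software lineage), with $\mu^*_i = \gamma\varepsilon_i$
  and $\sigma^{*2} = \gamma(1-\gamma)\sigma^2$; the alternative
  $\exp(-E[u_i\mid\varepsilon_i])$ is available via
  `technical_efficiency(fit, estimator = "jlms")`. Both are validated
  against numerical integration of the conditional density.
* **Inefficiency test**: $z = \hat\gamma / SE(\hat\gamma)$ with a
  one-sided normal reference and significance bands at 0.1, 0.05, 0.01,
  0.001. One published row marks $z = 1.13$ as significant at 0.1 even
  though the one-sided $p$ is 0.129; the band mapping here is applied as
  defined, so that row would be reported as not significant.
* **Gap conversion**: a mean efficiency $\overline{TE}$ converts to a
  percentage gap $(1/\overline{TE} - 1)\times 100$. Because the
  reciprocal is convex, averaging farm-wise gaps gives a larger number
  than converting the mean score; published gap columns appear to mix
  both conventions, so both are exposed
  (`gap_from_efficiency(mean(te))` vs `mean(gap_from_efficiency(te))`).
* **Weak identification at the null.** When the true $\gamma$ is 0 the
  profile likelihood in $\gamma$ is nearly flat and $\hat\gamma$
  scatters considerably between samples even at $n = 400$; tests of the
  null-limit behaviour therefore assert medians over several seeds
  rather than single draws.

The synthetic generator (`gen_frontier_population()`) draws log-normal
inputs, exogenous log-normal output-mix ratios, $v$ normal and $u$
half-normal, and solves the distance function for $y_M$. Drawing the
*mix ratios* exogenously (rather than secondary output levels) keeps the
regressors independent of the composed error; drawing levels and solving
would make the normalized-ratio regressor endogenous and bias every
coefficient, which is a property of that simulation design, not of the
estimator. True efficiencies $e^{-u}$ are returned so recovery can be
scored; generator and estimator share no code.

## 3. The household herd simulator

A monthly cohort model of one household's herd over 20 years. Cohorts
are rows (class, count, age, liveweight, lactation month, gestation
month) with continuous head counts; dynamics are expected-value by
default, which makes every run deterministic and every conservation
identity exact. A seeded integer-stochastic mode draws conception,
mortality and calf sex as binomials instead.

**Monthly step order**: feed allocation → energy, milk and liveweight →
reproduction and mortality → herd management; economics accumulate
monthly and are summarised annually.

### Energy and protein

All constants are fixed, simplified feeding-standards forms:

| quantity | form | constants |
|---|---|---|
| maintenance | $0.26\,W^{0.75}/k_m$ MJ/d | $k_m = 0.7$ |
| pregnancy | ramp 0→12 MJ/d over last 3 gestation months | |
| lactation | $\max(0, ME - \text{maint} - \text{preg})\,k_l / E_{milk}$ | $k_l = 0.6$, $E_{milk} = 38.6\,F + 1.69$ MJ/kg |
| protein cap | $CP \times 0.6 / 0.033$ kg milk | milk protein 3.3%, efficiency 0.6 |
| gain | 35 MJ/kg at $k_g = 0.43$ | |
| mobilization | 28 MJ per kg tissue | floor $0.75\,W_{mature}$ |

Realized milk is the minimum of the breed potential (a flat-topped
lactation curve — linear rise through month 1, plateau, linear decline
over the final third to 0.25 of peak — scaled by $W/W_{mature}$), the
energy allowance and the protein allowance. When energy is the binding
constraint, body tissue buffers up to 20% of the deficit; a cow below
maintenance gives no milk and loses weight. Note the protein cap has no
maintenance-protein deduction, so it binds only on severely
protein-poor diets; protein-side interventions act mainly through the
associated digestibility (ME) improvements, which is how the
urea-treated-straw scenario is encoded.

### Reproduction, mortality, management

Open breeders past a 2-month post-partum anoestrus conceive with monthly
probability $p = 0.35 / (1 + e^{-12(c - 0.8)})$, $c = W/W_{mature}$;
gestation is 9 months, calf sex 50:50. With condition held at 1 the
implied calving interval is $9 + 2 + 1/p(1) \approx 14$ months; in the
simulations condition cycles below 1 during lactation, so equilibrium
intervals run 17–27 months depending on feeding — this energy-driven
partitioning is exactly why high-potential breeds on poor diets show
*longer* calving intervals, a pattern the published simulations also
display in the rainfed-India genetics scenarios. Monthly mortality is
$\text{base}/12 + 0.02\max(0, 0.75 - c)$, with growing stock's condition
measured against an age-specific target weight.

Management mirrors the household rules: male offspring sold at the
configured age (or at an age-and-weight rule, as in the pastoral
scenario's 12 months/180 kg), weaned female calves retained only while
the replacement pipeline needs them, heifers promoted at the breed's age
at first mating, breeders culled at an expected rate of one per breeding
lifetime, and the breeder count kept within the household's bounds
(excess sold oldest-first). Culling as a rate rather than a hard age cut
is the natural expected-value analogue for merged cohorts whose ages are
count-weighted means.

Calves below weaning (6 months) are reared outside the feed budget at
half potential growth: cows are milked fully and the residual
suckling/roughage intake of calves is not modelled. This overstates
saleable milk slightly and is listed as a limitation.

### Economics

Income is milk plus livestock sales (male offspring, surplus females,
culled breeders); costs are purchased feed (on-farm feed is costless),
and a flat health-plus-mating charge per head per year. Labour is not
costed. Currencies stay native (ETB, INR).

### Scenario library and calibration

The five baseline household types and their 22 interventions ship as
YAML files regenerated deterministically from code
(`gen_fixtures()`, `write_scenario_files()`); all quantities printed in
the published household descriptions (supplement amounts, breeder
bounds, sale rules, baseline mortalities, the +0.5% pasture N, the
+1 MJ straw upgrade and its 5→5.8 INR/kg price) are copied verbatim.
Everything else — feed dry matter, ME, CP, prices, on-farm supplies,
animal prices, and breed potentials — is a **calibration assumption**,
fixed once and documented here:

* Breed peaks: Zebu 4.5, Ethiopian crossbred 8, Indian local 4.2,
  Indian crossbred 8, buffalo 8 kg/day at mature weight (mature weights
  350/420/350/500/450 kg; buffalo milk 7% fat, cattle 4–4.5%). The
  published intervention yields themselves pin these down: 702
  kg/lactation from Zebu and 703 from Indian local cattle are
  unreachable with peaks below about 4.
* Feed table (ME MJ/kg DM, CP, fresh-weight DM): cereal straw 6.5–6.8 /
  0.04 / 0.90; legume hay 8.8 / 0.16 / 0.85; noug cake 11.5 / 0.32 /
  0.92; brans 11–11.5 / 0.13–0.15 / 0.90; natural pasture 8.0 /
  seasonal 0.05–0.11 / 0.30; native grass 8.5 / 0.08 / 0.25; good
  green grass 8.8 / 0.12 / 0.25; lablab 9.2 / 0.17 / 0.25 at
  11 t DM/ha/yr. Milk prices 10 ETB/kg, 30 INR/kg cow, 40 INR/kg
  buffalo.
* The legume-reseeding intervention also raises pasture supply (×1.35)
  because the published herd response (26→38 head) can only come from
  more feed, the growth response having been produced upstream by a
  pasture model that is out of scope here and replaced by fixture
  supply tables.

Scenario-level grazing offers were tuned once, at these fixed feed
qualities, until the simulated scenario set reproduced the published
qualitative pattern — every intervention raising annual farm milk, the
within-region ordering of scenarios by farm milk matching the published
ranking, nutrition interventions shortening the calving interval, and
the urban (all-purchased-fodder) baseline losing money. This is
calibration of undocumented inputs against published outputs, not
ground truth, and the numeric outputs of the simulator should be read
as illustrative of mechanism, never as predictions.

### What the simulator does not capture

Crop growth and weather (fixture feed supplies instead), labour, manure
and draught value, milk seasonality in prices, calf suckling, disease
other than a condition-linked mortality term, and any within-herd
genetic variation. Parameter sensitivity (conception slope, mobilization
buffer, cull rate) is deliberately exposed as plain constants.

## 4. Gap integration

`gap_report()` divides the best simulated lactation yield by the
benchmark attainable yield, flagging regions where combined
interventions push production past what top producers currently achieve.
The modelled households and the surveyed top producers are not sampled
from the same populations (different states within a zone), so the
report carries that caveat rather than resolving it.
`rank_interventions()` reports milk and profit rankings side by side —
the highest-yield intervention is not always the most profitable,
particularly where higher-fat buffalo milk earns a price premium over
larger cow-milk volumes.

## 5. Problem sizes and numerical choices

Tests and the acceptance script run: frontier recovery at $n = 500$
farms × 10 seeds; likelihood and efficiency oracles on ≤ 5 observations
against `integrate()` quadrature at relative tolerance $10^{-12}$;
benchmark closed-form checks at $n = 10^4$ log-normal draws; and the
full 27-scenario, 240-month simulation sweep. Cohort rows with matching
(class, reproductive state, integer age) are merged count-weighted each
month to bound the state size; head-count and feed-mass balances then
hold to floating-point accumulation (residuals below $10^{-8}$ head or
kg). Summaries average the final 15 years after a 5-year burn-in so the
arbitrary initial herd has equilibrated; the burn-in length only matters
if it is too short for the slowest scenario's demography, and doubling
it does not change the reported orderings.
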