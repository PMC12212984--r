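---
title: "Cetacean community assemblage analysis from daily acoustic detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cetacean community assemblage analysis from daily acoustic detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamdiv)
```

## The problem and the data model

Long-term passive acoustic monitoring (PAM) arrays record underwater sound
continuously for years; species-specific detectors and manual validation
reduce those recordings to *binary daily acoustic presence*: for each site,
calendar day and detection category, was the species' vocalization detected?
`pamdiv` starts exactly there. Everything upstream — recorders, click
detectors, classifiers — is out of scope; everything downstream of a
validated daily detection table is in scope.

The unit record for all statistics is the **monthly summary**: per site,
calendar month and category, the days detected and the days monitored.
Monthly bins are deliberate: daily presence of a vocalizing animal is
stochastic (an animal can be present and silent), and summing to months
absorbs that burstiness instead of letting it inflate turnover estimates.
Two structural rules follow:

* **Effort-aware denominators.** Monthly presence proportions divide by days
  *monitored*, not calendar days, so recording gaps never depress presence.
  This is the only convention that keeps proportions in [0, 1] under gaps
  while using all available data.
* **Months are never merged across years**, and a month bridging a recording
  gap keeps whatever effort it has; a month with zero effort simply does not
  exist in the summary.

## Relative acoustic presence

The composition of a site (`site_composition()`) is the per-category mean
over monitored months of `days_detected / days_monitored`, rescaled to sum
to 100%. A category detected every monitored day at a site where nothing
else is ever heard scores 100%; never-detected categories are omitted from
the mapping (a site with no detections at all yields an empty mapping
rather than a 0/0). Months are averaged uniformly over the whole monitored
period; we do not first average within deployment years, which would weight
months unevenly for no defensible reason.

## Turnover: ENS, SERr, SERa

Within a site-month the **relative presence** of category $i$ is
$p_i = d_i / \sum_j d_j$ where $d_i$ is its days detected — a composition
across categories, not the raw proportion of monitored days. The
diversity/turnover framework assumes relative abundances, and days detected
are the acoustic analogue. A month with no detections at all has no
composition; it is flagged and every statistic touching it is missing.
Treating such months as "complete turnover" would manufacture SER = 1 spikes
out of silence or missing effort, so gaps propagate as `NA` and
consecutive-month pairs separated by an unmonitored month are never bridged.

For one site and consecutive months $t-1, t$:

* **ENS** (effective number of species, inverse Simpson):
  $\mathrm{ENS} = 1 / \sum_i p_i^2$, bounded by 1 and the richness, equal to
  the richness for a perfectly even community. We emit both the monthly ENS
  and its month-over-month difference ΔENS — the difference is the simple
  subtraction of consecutive ENS values.
* **SERr** (richness-based species exchange ratio): immigrations plus
  extinctions over union richness,
  $(|G| + |L|) / |S_{t-1} \cup S_t|$ — identically the Jaccard
  dissimilarity. It is a ratio of small integers and is computed exactly;
  tests compare it to a brute-force set-counting oracle with
  `expect_identical`.
* **SERa** (abundance-based): the Wishart dissimilarity on relative
  presence,
  $\sum_i (p_{i,t-1} - p_{i,t})^2 \big/ \left(\sum_i p_{i,t-1}^2 +
  \sum_i p_{i,t}^2 - \sum_i p_{i,t-1}\,p_{i,t}\right)$,
  with each vector extended by zeros over the union of categories. Both
  ratios are 0 when identity and dominance are unchanged and 1 under
  complete replacement, and SERa reduces exactly to SERr whenever both
  months' detected categories are equi-proportional — a property test
  checks this over 500 random set pairs. The result is clamped to [0, 1]
  against one-ulp floating-point excursions; all other comparisons use a
  1e-12 tolerance.

The turnover panels overlay a LOESS curve (tricube weights, degree 2, span
0.25, evaluated at the observation months). The smoother is display-only —
it never feeds another statistic — and is omitted with a warning below 4
non-missing points.

## Conditional inference trees

`citree()` partitions site-month observations (response: site; covariates:
days detected per month per category) by permutation-test variable
selection. For covariate $x$ and response indicator $h(y_i)$ the linear
statistic is $T = \sum_i w_i x_i h(y_i)$; its exact conditional mean $\mu$
and covariance $\Sigma$ under permutations of $y$ follow Strasser & Weber
(1999), and the test statistic is the quadratic form
$c_{quad} = (T-\mu)^\top \Sigma^+ (T-\mu)$ with the Moore–Penrose
pseudoinverse (eigendecomposition, tolerance `sqrt(.Machine$double.eps)`)
and $\chi^2$ reference distribution on $\mathrm{rank}(\Sigma)$ degrees of
freedom. The quadratic form is the natural choice for a 10-level
categorical response, where max-type statistics are awkward. A seeded
Monte-Carlo mode permutes the response directly and serves as the
independent oracle: on seeded data with $n = 100$ the asymptotic p-values
agree with a 10,000-rep permutation estimate within ±0.02.

Fitting rules, with their defaults:

* **mincriterion = 0.95**: split only when $1 - p_{adj}$ of the best
  covariate exceeds 0.95 (i.e. adjusted p < 0.05).
* **Bonferroni multiplicity** over the $m$ non-constant covariates tested
  at the node ($p_{adj} = \min(1, m\,p_{raw})$) — the classical conditional
  inference tree default.
* **minsplit = 60 / minbucket = 15** (weight sums) for the full and stump
  configurations; **10 / 5** for the mysticete-only configuration, relaxed
  to compensate for the reduced covariate set. Case weights default to 1,
  so these read as observation counts. `minsplit` is the minimum node
  weight to *attempt* the tests at all.
* **Cutpoints** are midpoints between consecutive distinct covariate
  values, scored by the same quadratic statistic on the binary indicator
  $x \le c$, subject to `minbucket` on both sides; ties break toward the
  smaller cutpoint. On integer detection-day covariates a presence/absence
  split is cutpoint 0.5 and renders as "> 0".
* No surrogate splits and no covariate missingness handling: assembly
  zero-fills covariates, and a site-month exists only where effort exists.
* Selection precedes cutpoint search, so variable choice is unbiased with
  respect to the number of potential split points.

The three shipped configurations (`tree_config()`) are *full*, *stump*
(`maxdepth = 1`, isolating the single most discriminating covariate), and
*mysticete-only* (covariates restricted to the mysticete guild). The mixed
Gervais'/True's category is excluded from covariate sets by default
(`include_mixed = FALSE`), giving 13 species plus grouped delphinids = 14
covariates; it remains an ordinary category in compositions and niche
displays.

## The synthetic community generator

`shelfbreak_scenario()` encodes the study conditions the analysis assumes:
10 shelf-break sites from 41.1°N to 30.5°N monitored April 2016 – June
2019, with two short seeded redeployment gaps per site, and 15 categories
whose occupancy follows
$p(\text{day}) = \mathrm{clamp}\!\left(p_{base} \cdot \text{seasonal} \cdot
\text{range} \cdot \text{trend},\, 0, 1\right)$:
a cosine seasonal term (amplitude 0–1, peak day-of-year), a logistic
latitudinal step (the transition from ~12% to ~88% of $p_{base}$ spans the
stated `lat_width`; width 0 is a hard indicator), and a per-year
multiplicative trend. Days are drawn as independent Bernoulli variables; an
optional 2-state Markov `persistence` parameter produces bursty presence
(default off — monthly binning is the analysis' mitigation for burstiness,
and tests must be able to show it working on the harder, independent case).

The planted structure, and why:

* The Gervais'-like and Blainville's-like categories occupy only the five
  southern sites year-round ($p_{base}$ 0.65 and 0.40). Their range
  boundary sits at 37.6°N — between the Wilmington (38.37°N) and Norfolk
  (37.16°N) latitudes — so that leakage through the default 1° soft edge
  at the nearest northern site is negligible, matching a community in which
  the southern beaked whales are essentially absent north of the divide.
  With the default logistic edge the divide is recoverable but not
  degenerate; `boundary = "hard"` gives the strict by-construction variant.
* Sowerby's-like and True's-like categories mirror this to the north
  (lower $p_{base}$, mild seasonality), a goose-beaked-whale-like category
  spans all sites, and sperm-whale-like and delphinid-like categories are
  ubiquitous year-round — so site identity is carried by the beaked
  whales, not by the widespread callers.
* The five mysticete categories are strongly seasonal (amplitude 0.95)
  in two cohorts with peak days about half a year apart (15/45/45 vs
  198/228). Seasonal dominance therefore turns over twice a year, which is
  what produces the half-year SERa periodicity at sites where both cohorts
  are prominent; a rarely detected right-whale-like category
  ($p_{base} = 0.08$) stays in the catalogue to exercise near-absent
  species handling.

What the generator does *not* emulate — and hence what green tests do not
establish about field data: detection probability varying with range,
noise, or calling behaviour; day-to-day autocorrelation (unless
`persistence` is enabled); density (occupancy probability is the atomic
quantity); inter-annual distribution shifts beyond a multiplicative trend;
and correlated detection errors between acoustically similar species.

Half-year periodicity is measured as the peak of the detrended
autocorrelation of the northern-site mean SERa series over sub-annual lags
(2–9): a semi-annual cycle necessarily echoes at the annual lag 12, so the
annual harmonic is excluded from the search window.

## Problem sizes and reproducibility

The reference run is 10 sites × ~39 months × 15 categories (~178,000
Bernoulli draws), which generates in under a second; tree fits take tens of
milliseconds, so the recovery experiments (20 seeds for the stump, 100
label shuffles for the null calibration) and the 10,000-rep Monte-Carlo
oracle run comfortably inside a routine test session. Unit tests use a
3-site, 4-category, 8-month miniature with the same planted structure.
Every stochastic step flows from a single integer seed: scenario + seed
determines the detection table bit-for-bit, and `run_pipeline()` writes a
manifest (config hash, seed, versions) from which a run's tables can be
reproduced exactly.

## Known limitations

* Turnover is within-site over time only; no cross-site beta diversity and
  no richness estimators with detection-probability correction.
* The asymptotic $\chi^2$ p-values are approximations to the permutation
  null; for very small nodes the Monte-Carlo mode is the safer choice.
* The shipped calling-frequency band table is a *placeholder* (flagged per
  row); niche displays of real data require literature-derived bands.
* Monthly binning trades temporal resolution for robustness; phenomena
  faster than a month (storm responses, lunar cycles) are invisible by
  construction.
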