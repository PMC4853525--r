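---
title: "Estimating population exposure to substance content in music videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population exposure to substance content in music videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediareach)
```

## The problem

Music videos reach enormous, strongly age-skewed audiences, and many
popular videos contain alcohol or tobacco imagery or lyrics. Public-health
surveillance wants a single interpretable number per demographic group: how
many *impressions* — one person seeing one 10-second interval containing
content, for a video they have ever watched — the videos delivered, in
total and per head. mediareach implements that estimator, together with the
input validation, the survey-weighted reach estimation, and a synthetic
data generator that lets every stage be tested without access to the
(unpublished) survey microdata.

## Model and assumptions

For stratum $g$ (an age band crossed with gender) and content class $c$ (a
set of substances whose flags are unioned per interval):

$$G_{g,c} = \bar p_g \times N_g \times I_c, \qquad
  PC_{g,c} = \bar p_g \times I_c,$$

where $\bar p_g$ is the survey-weighted mean over in-stratum respondents of
the fraction of videos ever seen, $N_g$ the census mid-year population
(millions) and $I_c$ the total count of content-bearing intervals.

The estimator's assumptions, and what violations do:

* **Ever-seen, once.** Each respondent contributes at most one viewing per
  video. Repeat viewing — common for music videos — makes $G$ a lower
  bound; a `view_multiplier` hook scales all outputs if an average
  viewing frequency is available.
* **Aggregate reach, aggregate content.** The headline cell multiplies the
  stratum's *mean* reach by the *total* interval count, rather than
  summing per-video $p_{g,v} I_{v,c}$. The two differ when per-video reach
  correlates with per-video content density. We chose the aggregate form
  as the default because it makes the tobacco/alcohol gross ratio within a
  stratum exactly $I_{tob}/I_{alc}$ — a property the published stratified
  tables this package mirrors demonstrably satisfy (their ratios equal
  47/233 to four significant figures) — and kept the per-video form in
  `video_exposure_table()` for the video-level breakdown.
* **Weights as supplied.** Survey weights are taken as already calibrated;
  no re-raking.

## Reach standard errors and the confidence interval

The published tables this estimator reproduces report symmetric 95%
intervals without stating a method, so the CI construction was a genuinely
open design choice. The default is the standard survey-weighted one:

$$\widehat{se}(\bar p_g)^2 = \frac{s_w^2}{n_{eff}},\qquad
  n_{eff} = \frac{(\sum w)^2}{\sum w^2},$$

with $s_w^2$ the weighted variance of the per-respondent fractions
(corrected by $n_{eff}/(n_{eff}-1)$), and $\bar p \pm z\,se$ clipped to
$[0,1]$. With equal weights this collapses exactly to the unweighted mean
and its textbook standard error. Alternatives are selectable per call:
`method = "unweighted"` and `method = "bootstrap"` (percentile over
respondent resampling). The Kish CI's calibration is checked by
simulation: over 500 generator replicates the 95% interval covers the
model-implied truth ~95% of the time (the acceptance suite requires
93–97%).

Degenerate inputs are handled explicitly: a stratum with no respondents or
a single respondent is an error (variance undefined), identical fractions
give a zero-width interval, and a class with $I_c = 0$ yields a valid
all-zero impressions row.

## Content coding conventions

* A video of duration $d$ seconds has $\lceil d/10 \rceil$ intervals; the
  trailing short interval is a full coding unit, so no coded content is
  truncated. Interval $k$ (0-based) is the window $[10k, 10(k+1))$.
* Flags are strictly boolean after validation; the coding sheet is long
  format (one row per video-interval, one 0/1 column per
  `substance.category.channel`), which round-trips losslessly through CSV
  and nested JSON.
* Electronic cigarettes are a separate substance, **not** folded into
  tobacco: the source tables report tobacco (47 intervals) and e-cigarette
  (6 intervals) figures separately without stating whether they overlap,
  so the default classes stay disjoint and a combined class is a
  user-level choice (`content_class(c("tobacco", "electronic_cigarette"))`).

## Population handling

Counts are carried in millions end to end. Strata resolve against the
census table first by exact match, then by a greedy tiling of same-gender
bands, then (for `"all"`) by summing the gender resolutions; this makes
the whole-population count resolve via the published adolescent + adult
entries (5.91 + 49.20 = 55.11) rather than via the band sum, whose printed
2-decimal rows sum to 49.19 for adults — a 0.01 rounding artefact the
consistency checker `check_population_consistency()` tolerates up to 0.02
million. The shipped table has gender detail only at the
adolescent/adult level, as published; `split_population_by_gender()`
imputes band × gender counts from the enclosing gender shares when a
gender-split band scheme is requested, and is clearly an imputation, not
census data.

## The Total row

The aggregate row sums gross impressions and population over the scheme's
`role = "band"` rows (a disjoint partition), and sums the CI endpoints.
Endpoint summation matches the arithmetic of the published Total rows; it
is conservative when stratum estimates come from independent samples, and
`ci_method = "rss"` (root-sum-square of half-widths) provides the
narrower independence-based alternative. Aggregate per-capita is
`sum(G)/sum(N)`, a population-weighted mean that always lies between the
constituent per-capita values.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults encode the study conditions: 32 videos whose
per-video interval counts are uniform on 20–32 and nudged to total exactly
821; per-interval content rates 233/821 (alcohol), 47/821 (tobacco), 6/821
(e-cigarette), so expected totals equal the study margins; tobacco–alcohol
overlap within an interval exposed as `overlap_rate` (default:
independence, since the true overlap structure is unpublished); 2068
adolescent and 2232 adult respondents with ages drawn per single year in
proportion to the census bands (55+ truncated at 80); lognormal weights
with mean 1 and dispersion 0.3; and a logistic ever-seen model

$$\mathrm{logit}\, p_{rv} = \beta_0 + \beta_a(\mathrm{age}_r - 16)
  + \beta_f\,\mathrm{female}_r + u_v,\quad u_v \sim N(0, \sigma_v^2),$$

with $\beta_0 = -1.783$, $\beta_a = -0.06$, $\beta_f = 0.5$,
$\sigma_v = 0.8$ — solved numerically (once, before any testing) so the
model-implied mean reach is 0.22 for ages 11–18 and 0.06 for 19+, with
female reach exceeding male (≈0.26 vs ≈0.18 among adolescents). The root
seed is split into per-component substreams, so e.g. enlarging the survey
leaves the coded videos byte-identical.

Features of real data the generator deliberately omits — and which passing
tests therefore say nothing about:

* **No respondent-level viewer effect.** Indicators are independent across
  videos given age, gender and video popularity, so per-respondent
  fractions are far less dispersed than in a real panel where heavy music
  video consumers see most videos. Synthetic reach CIs are consequently
  much narrower than published ones; coverage checks are against the
  generator's own truth, not against real-world interval widths.
* Weights are drawn independently of demographics (real calibration
  weights correlate with them); there is no panel non-response, no repeat
  viewing, no region/social-grade structure beyond a label.
* Age reach is monotone on the log-odds scale, whereas the real pattern
  has a mild peak at 13–15.

`model_implied_reach()` computes the exact expected reach for any stratum
conditional on the realised video effects, which is what parameter-recovery
and coverage tests compare against.

## Numerical and rendering choices

All internal values are full precision; rounding (half away from zero, the
convention of published tables — base R rounds ties to even) is applied
only at render time by `render_exposure_table()`, at 2 decimals. Every
rendered cell is reproducible from the audit log written by
`write_exposure_table()`, which records the $(\bar p, N, I)$ triple behind
each cell.

## Problem sizes in the test suite

The suite exercises the full study design where the property demands it
(parameter recovery and CI coverage run the 32-video / 4300-respondent
scenario, coverage over 500 replicates; oracle-equivalence checks use 1000
random fixtures) and reduced scenarios (6–10 videos, 400–1400 respondents)
for structural properties, where size adds runtime but no information.

## Limitations

Beyond the generator simplifications above: the estimator inherits the
one-viewing convention (a lower bound on true exposure); it cannot
reproduce published gender-by-band per-capita values without band-level
gender microdata, which were not published; and the arithmetic-identity
checks against published cells validate the pipeline's algebra, not the
original survey fieldwork.
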