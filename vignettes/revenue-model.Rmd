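---
title: "Estimating youth-attributable social media advertising revenue by age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating youth-attributable social media advertising revenue by age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Social media platforms do not publish how many of their U.S. users are
children or adolescents, nor how much advertising revenue those users
generate. What is available is indirect: surveys report the *proportion* of
people using each platform by broad age group (with a stated margin of
error), usage trackers report *minutes per day* among users by coarse age
band, and market research reports each platform's *total* annual advertising
revenue and *total* users per age band. `youthadrev` combines these into
single-year-of-age estimates of users and revenue, with uncertainty, so that
the share attributable to ages 0–12 and 13–17 can be reported.

## The model

For one platform, let $a = 0, \dots, 84$ index single years of age (84 is
treated as an open "84+" band), $N_a$ the census population, $p_a$ the
probability of using the platform, and $m_a$ mean minutes/day among users.

1. **Sampling.** Each survey band's prevalence estimate $\hat\pi_g$ carries
   a 95% margin $\epsilon_g$. One *parameter set* draws a value per band
   from $\mathcal{N}(\hat\pi_g,\, (\epsilon_g/1.96)^2)$ truncated to
   $[0,1]$ (minutes draws are truncated to $[0,\infty)$). Truncation uses
   the inverse-CDF construction, so it is exact and a zero margin collapses
   to the point estimate.
2. **Interpolation.** The drawn band values, placed at band midpoints,
   are interpolated with a natural cubic spline (zero second derivative at
   the boundary knots, hence linear extrapolation beyond them) to give
   $p_a$ and $m_a$ at every age; $p_a$ is clamped to $[0,1]$ and $m_a$ to
   $[0,\infty)$. Ages below the youngest survey band (0–7) take the
   boundary-linear extrapolation clamped at zero rather than a forced zero
   anchor — whether young children contribute mass is decided by the
   calibration targets, not by an interpolation convention.
3. **Calibration.** Externally reported platform user totals $T_b$ per age
   band are the calibration targets. A parameter set's fit is scored by
   $$L = \sum_b \left(\frac{\sum_{a \in b} N_a p_a - T_b}{T_b}\right)^2 .$$
   The stochastic optimization is a seeded random search: draw
   `n_candidates` parameter sets from the sampling distributions, keep the
   `n_keep = 100` with the lowest loss. Because candidates are drawn from
   the survey sampling distributions themselves, the retained ensemble
   stays anchored to what the surveys can support, and its spread is the
   parameter uncertainty that the intervals report. The search module is a
   plain function of (inputs, population, config), so an annealing or
   CMA-style strategy could replace it without changing any contract.
4. **Allocation.** Revenue per minute of use is assumed constant in age, so
   each age receives
   $rev_a = R \cdot N_a p_a m_a / \sum_{a'} N_{a'} p_{a'} m_{a'}$, where
   $R$ is total annual ad revenue. The allocation conserves $R$ exactly;
   the 365×/year annualization cancels in the ratio and only appears in
   the implied revenue-per-minute diagnostic.
5. **Summaries.** For each reporting band (0–12, 13–17, 0–17), users and
   revenue are computed for every ensemble member; the report gives the
   ensemble mean and a 95% uncertainty interval defined as the 2.5th and
   97.5th percentiles of the member values. Means are linear, so the 0–12
   and 13–17 means add exactly to 0–17; percentile bounds are not additive
   and are reported per band only.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `age_max` | 84 | years | Top age, treated as "84+"; census counts above it are folded in. A convention — the sources do not state a top age. |
| `n_candidates` | 10,000 | sets | Candidates drawn per platform; 100 kept, i.e. the top 1%. Larger values can only improve the best loss (superset property). |
| `n_keep` | 100 | sets | The retained best-fitting ensemble over which means and intervals are computed. |
| `ui_lo`, `ui_hi` | 2.5, 97.5 | percentiles | Uncertainty-interval bounds, computed by linear interpolation between closest order statistics (quantile type 7) — pinned for bit-reproducibility. |
| `child_minutes_default` | 5 | min/day | Imputed as a 0–17 band (zero margin) for a platform whose minutes table reports nothing under 18, the convention used when trackers omit a platform's child minutes. |
| `seed` | — | — | Every candidate draws from its own counter-based substream of (seed, platform id, candidate index), so results are independent of platform order and evaluation order. |

## What the synthetic generator emulates — and what it does not

Real inputs are proprietary, so the package ships a generator with known
ground truth. Each synthetic platform is a `truth_spec`: prevalence is a
product of a logistic rise and a logistic decline,
$p(a) = p_{max}\,\sigma((a-a_{on})/w_{on})\,\sigma((a_{off}-a)/w_{off})$,
which captures the onset-plateau-decline shape of platform adoption while
staying in $[0, p_{max}]$; minutes/day is piecewise linear. Observation
mimics the sources: band estimates are population-weighted means of the
truth over the band plus truncated Gaussian noise with SD = margin/1.96;
calibration user totals are computed *exactly* from truth; total revenue is
revenue-per-minute × person-minutes × 365.

The default study conditions were fixed once, to be realistic rather than
convenient: six platform archetypes (an early-childhood video platform, two
adolescent-centred platforms, a broad photo-sharing platform, and two
adult-dominated platforms) with onset widths 1.5–4 years and decline widths
6–15 years; a U.S.-like population of ~4 million per single year of age with
a gentle decline after 60; survey bands 8–12 and 13–17 at a 3.2% margin and
18–29, 30–49, 50–64, 65+ at 7.3%, 5.2%, 5.8%, 5.8% — the margins the real
surveys state — with ages 0–7 deliberately unobserved; minutes margins of
15% of the band mean (the minutes sources state no margin; 15% is a typical
relative error for tracker panels); and market-research-style target bands
0–11, 12–17, 18–24, …, 65+.

What passing tests on this generator show: the sampling, interpolation,
calibration, allocation, and summarization machinery is correct, the
ensemble recovers generating curves to well within survey error, and the
intervals cover the true band totals at roughly their nominal rate. What
they do not show: that the real sources are unbiased, that real adoption
curves are logistic products, or that revenue per minute is truly constant
in age — those are assumptions of the method, not conclusions.

## Numerical choices

- **Spline.** `stats::splinefun(method = "natural")`, which is exact at the
  knots, has zero boundary curvature, and extrapolates linearly — verified
  in the tests against an independently assembled and solved tridiagonal
  natural-spline system (agreement to 1e-8).
- **Truncated normal.** Inverse-CDF: $x = \mu + \sigma\,\Phi^{-1}(u)$ with
  $u$ uniform on $[\Phi(\frac{lo-\mu}{\sigma}), \Phi(\frac{hi-\mu}{\sigma})]$.
  Exact truncation, no rejection loop, degenerate at $\sigma = 0$.
- **Selection ties.** Candidates are ranked by `order(loss)`, which breaks
  ties by candidate index, so selection is deterministic.
- **Zero calibration targets.** A band with a zero target contributes
  $(\text{modeled}/\bar T)^2$ with $\bar T$ the mean of the nonzero
  targets; all-zero targets are rejected.
- **Degenerate inputs.** Zero margins make every candidate identical: the
  ensemble collapses, interval widths are exactly zero, and (for truths the
  spline can represent exactly, e.g. constant prevalence) reported means
  equal the truth with no error.
- **Output stability.** Numbers are written with `formatC(..., digits =
  15)`, so re-running with the same seed and inputs yields byte-identical
  CSVs.

## Design choices where the design was open

- **Knot placement** at band midpoints (open top band: midpoint of its
  start and `age_max`) — the standard choice for interval-censored age
  data; nothing in the sources dictates knot positions.
- **Search realization.** "Stochastic optimization" is realized as
  draw-many/keep-best random search because it is the minimal mechanism
  that both optimizes fit and preserves the survey sampling distributions
  as the uncertainty source. A local optimizer would fit band totals more
  tightly but would detach the ensemble from the sampling error it is
  meant to propagate.
- **What the loss targets.** The loss matches external *user totals* only;
  revenue enters solely through allocation. Matching revenue in the loss
  would be redundant under the constant-rate assumption (allocation
  conserves total revenue identically).
- **Residual model bias.** A six-knot spline cannot reproduce eight band
  totals of a generic smooth adoption curve exactly; after calibration,
  band residuals of a few percent remain (concentrated where bands are
  small, e.g. 65+ on adolescent platforms, and below the youngest knot).
  This is a property of the model family, shared by any interval-censored
  interpolation approach, and is why recovery is judged against survey
  error (population-weighted MAE ≤ 1.5× the mean margin) and interval
  coverage rather than exact band agreement.
- **Attribution scope.** Revenue is attributed to modeled users only;
  logged-out or non-user exposure is out of scope.

## Problem sizes used in the tests

The test suite fits 5,000 candidates per platform for the six-platform
recovery check and 100–400 candidates for structural checks; Monte-Carlo
calibration of the sampling noise uses 10,000 draws per margin. The
acceptance script runs the full default configuration (10,000 candidates,
100 kept, six platforms). These sizes give stable statistics while keeping
a full run in well under a minute on one core.

## Limitations

- Estimates inherit whatever bias the proprietary sources carry; the
  generator tests internal validity only.
- Ages 0–7 are never directly observed; their estimates rest entirely on
  extrapolation disciplined by the calibration targets.
- Constant revenue-per-minute is a strong assumption: if advertisers pay
  less for child impressions, youth revenue is overstated, and vice versa.
- Percentile intervals reflect parameter (sampling) uncertainty only, not
  structural uncertainty in the spline family or the sources.
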