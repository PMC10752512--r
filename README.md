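# youthadrev

Social media platforms report neither their users' ages nor the advertising
revenue those users generate. `youthadrev` estimates both, by single year of
age, from what *is* reported: survey prevalence of platform use by age group
(with margins of error), minutes/day among users by age band, total platform
users per age band, and total annual advertising revenue. It is aimed at
health researchers and policy analysts who need defensible estimates of how
many children (0–12) and adolescents (13–17) use each platform and what
share of ad revenue they account for.

## Method in brief

For ages $a = 0..84$, population $N_a$, use probability $p_a$, and
minutes/day among users $m_a$:

- band estimates are sampled with their sampling error,
  $\mathcal{N}(\hat\pi_g, (\epsilon_g/1.96)^2)$ truncated to the legal
  range;
- sampled band values at band midpoints are interpolated to all ages with a
  natural cubic spline (clamped to $[0,1]$ / $[0,\infty)$);
- each sampled parameter set is scored against external band user totals
  $T_b$ by $L=\sum_b((\sum_{a\in b} N_a p_a - T_b)/T_b)^2$, and the 100
  best of 10,000 seeded random candidates are kept;
- annual revenue $R$ is allocated by person-minutes under a constant
  revenue-per-minute assumption,
  $rev_a = R\, N_a p_a m_a / \sum_{a'} N_{a'} p_{a'} m_{a'}$;
- reported numbers are ensemble means with 95% uncertainty intervals
  (2.5/97.5 percentiles across the kept sets).

The real market-research inputs are proprietary; a synthetic-data module
generates all five input tables from known ground-truth curves so the whole
pipeline is testable, and transcribed real tables can be supplied in the
same CSV schemas (see `?load_platform_inputs`).

## Worked example

```r
library(youthadrev)

population <- synthetic_population()          # ~4M per year of age, 0-84
truths     <- synthetic_platforms()           # six ground-truth archetypes
observed   <- observe_synthetic_study(truths, population, seed = 1)

cfg <- run_config(seed = 1, n_candidates = 2000, n_keep = 100)
res <- run_pipeline(observed, population, cfg)

subset(res$users, platform == "teen_chat")
#>    platform  band     mean    ui_lo    ui_hi
#> 4 teen_chat  0-12  3550426  3028819  4252849
#> 5 teen_chat 13-17  9586936  9096353 10076713
#> 6 teen_chat  0-17 13137363 12354762 14100684

subset(res$share, platform == "teen_chat" & band == "0-17")
#>    platform band      mean     ui_lo     ui_hi
#> 6 teen_chat 0-17 0.2901708 0.2623714 0.3123394
```

Reading: on this synthetic adolescent-centred platform, the model estimates
13.1 million users under 18 (95% UI 12.4–14.1M), of whom 3.6M are children
0–12, and attributes 29.0% (UI 26.2–31.2%) of the platform's total annual ad
revenue to them. Note the 0–12 and 13–17 means add exactly to the 0–17 mean;
the interval bounds do not, and are reported per band.

`run_pipeline(..., out_dir = "out")` additionally writes
`users_by_band.csv`, `revenue_by_band.csv`, `revenue_share_by_band.csv`, and
a `manifest.json` recording the configuration, seed, percentile convention,
and input digests.

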