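# small deterministic fixtures built in code

flat_population <- function(age_max = 84, count = 1000) {
  as_population_table(
    data.frame(age = 0:age_max, count = count), age_max = age_max)
}

# a compact platform with two prevalence bands and one minutes band
tiny_inputs <- function(platform_id = "tiny", margin = 0,
                        total_revenue = 1e6) {
  platform_inputs(platform_id,
    use_prevalence = age_band_table(
      group_lo = c(8, 13, 18, 30), group_hi = c(12, 17, 29, 49),
      estimate = c(0.2, 0.5, 0.4, 0.2), margin95 = margin),
    minutes = age_band_table(
      group_lo = c(0, 18), group_hi = c(17, 49),
      estimate = c(30, 20), margin95 = margin, proportion = FALSE),
    user_totals = data.frame(
      group_lo = c(0, 13, 18), group_hi = c(12, 17, 49),
      users = c(2000, 2500, 9000)),
    total_revenue = total_revenue, age_max = 84)
}

# constant-prevalence truth: the spline through equal band means is exact
# everywhere (including extrapolated ages), so noiseless runs recover band
# totals with zero error
constant_truth <- function(platform_id = "const", p = 0.3, minutes = 30,
                           rpm = 1e-4) {
  tr <- make_truth(platform_id, pmax = 1, a_on = 0, w_on = 1,
    a_off = 200, w_off = 1,
    minutes_knot_ages = 40, minutes_knot_values = minutes,
    revenue_per_minute = rpm)
  tr$prevalence <- function(a) rep(p, length(a))
  tr$params$constant_p <- p
  tr
}

# write the five input CSVs + config for load_platform_inputs tests
write_fixture_config <- function(dir, n_platforms = 6) {
  truths <- synthetic_platforms()[seq_len(n_platforms)]
  write_synthetic_inputs(dir, truths = truths,
    population = flat_population(), seed = 11)
}
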