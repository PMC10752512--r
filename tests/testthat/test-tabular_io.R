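test_that("population CSVs are validated and folded into the top age", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,count", "0,10", "1,20", "2,30"), tmp)
  pop <- load_population(tmp, age_max = 2)
  expect_s3_class(pop, "population_table")
  expect_equal(sum(pop$count), 60)

  writeLines(c("age,count", "0,10", "1,20", "1,5", "2,30"), tmp)
  expect_error(load_population(tmp, age_max = 2), "duplicate age")

  writeLines(c("age,count", "0,10", "1,-5", "2,30"), tmp)
  expect_error(load_population(tmp, age_max = 2), "negative count")

  writeLines(c("age,count", "0,10", "2,30"), tmp)
  expect_error(load_population(tmp, age_max = 2), "missing age")

  # ages above age_max accumulate into the open top band
  writeLines(c("age,count", "0,10", "1,20", "2,30", "3,5", "4,5"), tmp)
  pop <- load_population(tmp, age_max = 2)
  expect_equal(pop$count, c(10, 20, 40))
})

test_that("band tables reject overlap, bad proportions, bad margins", {
  expect_error(
    age_band_table(c(0, 10), c(12, 17), c(0.1, 0.2), 0),
    "overlapping bands")
  expect_error(
    age_band_table(0, 17, 1.2, 0),
    "outside \\[0,1\\]")
  expect_error(
    age_band_table(0, 17, 0.5, -0.1),
    "negative margin95")
  expect_error(
    age_band_table(10, 5, 0.5, 0),
    "group_lo > group_hi")
  # minutes tables allow values above 1
  expect_silent(age_band_table(0, 17, 30, 2, proportion = FALSE))
})

test_that("platform inputs load from a config of CSVs, one per platform", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_config(dir, n_platforms = 6)
  inputs <- load_platform_inputs(file.path(dir, "config.yaml"))
  expect_length(inputs, 6)
  expect_setequal(names(inputs), names(synthetic_platforms()))
  one <- inputs[[1]]
  expect_s3_class(one, "platform_inputs")
  expect_gt(one$total_revenue, 0)
  expect_gte(nrow(one$use_prevalence), 2)

  # a platform with an unreported child minutes band fitted at 5 min/day
  mins <- read.csv(file.path(dir, "minutes.csv"))
  mins <- mins[!(mins$platform == "adult_news" & mins$group_lo <= 17), ]
  child <- data.frame(platform = "adult_news", group_lo = 0,
    group_hi = 17, estimate = 5, margin95 = 0, source = "imputed",
    open_top = FALSE)
  write.csv(rbind(child, mins), file.path(dir, "minutes.csv"),
    row.names = FALSE, quote = FALSE)
  inputs <- load_platform_inputs(file.path(dir, "config.yaml"))
  m <- inputs$adult_news$minutes
  row <- m[m$group_lo == 0 & m$group_hi == 17, ]
  expect_equal(row$estimate, 5.0)
})

test_that("malformed platform inputs raise typed validation errors", {
  dir <- withr::local_tempdir()
  write_fixture_config(dir, n_platforms = 2)

  prev <- read.csv(file.path(dir, "prevalence.csv"))
  bad <- prev
  bad$estimate[1] <- 1.2
  write.csv(bad, file.path(dir, "prevalence.csv"), row.names = FALSE)
  expect_error(load_platform_inputs(file.path(dir, "config.yaml")),
    "outside \\[0,1\\]")

  bad <- prev
  bad$group_lo[2] <- bad$group_hi[1] - 1 # overlap first two bands
  write.csv(bad, file.path(dir, "prevalence.csv"), row.names = FALSE)
  expect_error(load_platform_inputs(file.path(dir, "config.yaml")),
    "overlapping bands")
  write.csv(prev, file.path(dir, "prevalence.csv"), row.names = FALSE)

  revs <- read.csv(file.path(dir, "revenue.csv"))
  write.csv(revs[-1, , drop = FALSE], file.path(dir, "revenue.csv"),
    row.names = FALSE)
  expect_error(load_platform_inputs(file.path(dir, "config.yaml")),
    "missing total_revenue")
})

test_that("written synthetic inputs round-trip to full precision", {
  dir <- withr::local_tempdir()
  write_fixture_config(dir, n_platforms = 3)
  obs <- observe_synthetic_study(synthetic_platforms()[1:3],
    flat_population(), seed = 11)
  inputs <- load_platform_inputs(file.path(dir, "config.yaml"))
  for (pid in names(obs)) {
    expect_equal(inputs[[pid]]$use_prevalence$estimate,
      obs[[pid]]$use_prevalence$estimate, tolerance = 1e-12)
    expect_equal(inputs[[pid]]$user_totals$users,
      obs[[pid]]$user_totals$users, tolerance = 1e-12)
    expect_equal(inputs[[pid]]$total_revenue, obs[[pid]]$total_revenue,
      tolerance = 1e-12)
  }
})

test_that("output writer emits three CSVs plus a manifest, even when empty", {
  dir <- withr::local_tempdir()
  empty <- list()
  paths <- write_outputs(empty, file.path(dir, "out"))
  expect_true(all(file.exists(paths)))
  expect_length(paths, 4)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$package, "youthadrev")
  expect_match(man$percentile_definition, "order statistics")
  # empty tables still have headers
  u <- read.csv(paths[["users"]])
  expect_equal(nrow(u), 0)
  expect_setequal(names(u), c("platform", "band", "mean", "ui_lo", "ui_hi"))
})

test_that("identical seed and inputs give byte-identical output files", {
  dir <- withr::local_tempdir()
  pop <- flat_population()
  obs <- observe_synthetic_study(synthetic_platforms()[1:2], pop, seed = 5)
  cfg <- run_config(seed = 5, n_candidates = 120, n_keep = 30)
  run_pipeline(obs, pop, cfg, out_dir = file.path(dir, "a"))
  run_pipeline(obs, pop, cfg, out_dir = file.path(dir, "b"))
  for (f in c("users_by_band.csv", "revenue_by_band.csv",
    "revenue_share_by_band.csv")) {
    expect_identical(readLines(file.path(dir, "a", f)),
      readLines(file.path(dir, "b", f)))
  }
})
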