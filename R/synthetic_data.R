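#' Define a ground-truth platform (synthetic data)
#'
#' A truth specification holds the generating curves the synthetic survey
#' tables are observed from. Prevalence by age is a product of a logistic
#' rise and a logistic decline,
#' \deqn{p(a) = p_{max}\,\sigma((a - a_{on})/w_{on})\,
#'   \sigma((a_{off} - a)/w_{off}),}
#' which is bounded in [0, pmax] for all ages. Minutes/day among users is
#' piecewise linear over stated knots (constant beyond them).
#'
#' @param platform_id identifier.
#' @param pmax peak use probability, in [0, 1].
#' @param a_on,w_on onset age (years) and onset width (> 0).
#' @param a_off,w_off decline age (years) and decline width (> 0).
#' @param minutes_knot_ages,minutes_knot_values piecewise-linear minutes
#'   curve (values >= 0); a single knot gives a constant curve.
#' @param revenue_per_minute USD per person-minute-day (> 0).
#' @return a \code{truth_spec} with callable \code{prevalence(a)} and
#'   \code{minutes(a)}.
#' @export
make_truth <- function(platform_id, pmax, a_on, w_on, a_off, w_off,
                       minutes_knot_ages, minutes_knot_values,
                       revenue_per_minute) {
  if (pmax < 0 || pmax > 1) stop("pmax must be in [0, 1]", call. = FALSE)
  if (w_on <= 0 || w_off <= 0) stop("widths must be > 0", call. = FALSE)
  if (any(minutes_knot_values < 0)) {
    stop("minutes curve must be >= 0", call. = FALSE)
  }
  if (revenue_per_minute <= 0) {
    stop("revenue_per_minute must be > 0", call. = FALSE)
  }
  force(pmax); force(a_on); force(w_on); force(a_off); force(w_off)
  ka <- minutes_knot_ages; kv <- minutes_knot_values
  prevalence <- function(a) {
    pmax * stats::plogis((a - a_on) / w_on) *
      stats::plogis((a_off - a) / w_off)
  }
  minutes <- if (length(ka) == 1) {
    function(a) rep(kv, length(a))
  } else {
    function(a) stats::approx(ka, kv, xout = a, rule = 2)$y
  }
  structure(list(platform_id = platform_id,
    params = list(pmax = pmax, a_on = a_on, w_on = w_on, a_off = a_off,
      w_off = w_off, minutes_knot_ages = ka, minutes_knot_values = kv,
      revenue_per_minute = revenue_per_minute),
    prevalence = prevalence, minutes = minutes,
    revenue_per_minute = revenue_per_minute),
    class = "truth_spec")
}

#' Observe a truth specification as noisy survey tables
#'
#' Emulates the observation process behind the real inputs: each survey
#' band's estimate is the population-weighted mean of the truth curve over
#' the band's ages, plus Gaussian sampling noise with SD = margin95 / 1.96,
#' truncated to the legal range ([0, 1] for proportions, [0, Inf) for
#' minutes). Calibration user totals are computed exactly from truth
#' (\eqn{\sum_a pop_a p(a)} over each target band), and total annual revenue
#' is revenue_per_minute x total person-minutes/day x 365.
#'
#' @param truth a \code{truth_spec}.
#' @param population a \code{population_table}.
#' @param prevalence_bands,minutes_bands band layouts: data frames
#'   \code{group_lo,group_hi,margin95} (optional \code{open_top}).
#' @param target_bands calibration band layout, \code{group_lo,group_hi}.
#' @param seed integer seed for the observation noise.
#' @return a \code{platform_inputs} carrying attribute \code{"truth"}.
#' @export
observe_truth <- function(truth, population,
                          prevalence_bands = default_survey_bands(),
                          minutes_bands = default_minutes_bands(),
                          target_bands = default_target_bands(),
                          seed = 1L) {
  age_max <- max(population$age)
  p_true <- truth$prevalence(population$age)
  m_true <- truth$minutes(population$age)

  band_mean <- function(lo, hi, values) {
    sel <- population$age >= lo & population$age <= hi
    if (!any(sel)) stop("empty band ", lo, "-", hi, call. = FALSE)
    w <- population$count[sel]
    if (sum(w) == 0) return(mean(values[sel]))
    sum(w * values[sel]) / sum(w)
  }

  prev_mean <- mapply(band_mean, prevalence_bands$group_lo,
    pmin(prevalence_bands$group_hi, age_max),
    MoreArgs = list(values = p_true))
  min_mean <- mapply(band_mean, minutes_bands$group_lo,
    pmin(minutes_bands$group_hi, age_max),
    MoreArgs = list(values = m_true))

  set.seed(as.integer(seed %% .Machine$integer.max))
  prev_obs <- rtrunc_norm(length(prev_mean), prev_mean,
    prevalence_bands$margin95 / 1.96, 0, 1)
  min_obs <- rtrunc_norm(length(min_mean), min_mean,
    minutes_bands$margin95 / 1.96, 0, Inf)

  users_exact <- mapply(function(lo, hi) {
    sel <- population$age >= lo & population$age <= hi
    if (!any(sel)) stop("empty target band ", lo, "-", hi, call. = FALSE)
    sum(population$count[sel] * p_true[sel])
  }, target_bands$group_lo, pmin(target_bands$group_hi, age_max))

  total_revenue <- truth$revenue_per_minute *
    sum(population$count * p_true * m_true) * 365

  out <- platform_inputs(truth$platform_id,
    use_prevalence = age_band_table(prevalence_bands$group_lo,
      prevalence_bands$group_hi, prev_obs, prevalence_bands$margin95,
      source = band_col(prevalence_bands, "source"),
      open_top = as_flag(band_col(prevalence_bands, "open_top")),
      proportion = TRUE),
    minutes = age_band_table(minutes_bands$group_lo,
      minutes_bands$group_hi, min_obs, minutes_bands$margin95,
      source = band_col(minutes_bands, "source"),
      open_top = as_flag(band_col(minutes_bands, "open_top")),
      proportion = FALSE),
    user_totals = data.frame(group_lo = target_bands$group_lo,
      group_hi = pmin(target_bands$group_hi, age_max),
      users = users_exact),
    total_revenue = total_revenue, age_max = age_max)
  attr(out, "truth") <- truth
  out
}

# exact truncated normal via inverse CDF; sd = 0 collapses to the mean
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lo, mean[pos], sd[pos])
    phi <- stats::pnorm(hi, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), plo, phi)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmin(pmax(out, lo), hi)
}

#' Survey band layout used for synthetic prevalence observations
#'
#' Children 8-12 and 13-17 with a 3.2\% full-sample margin; adults 18-29,
#' 30-49, 50-64, 65+ with margins 7.3\%, 5.2\%, 5.8\%, 5.8\%. Ages 0-7 are
#' deliberately uncovered, as in youth media surveys.
#' @return data frame \code{group_lo,group_hi,margin95,open_top}.
#' @export
default_survey_bands <- function() {
  data.frame(
    group_lo = c(8L, 13L, 18L, 30L, 50L, 65L),
    group_hi = c(12L, 17L, 29L, 49L, 64L, 84L),
    margin95 = c(0.032, 0.032, 0.073, 0.052, 0.058, 0.058),
    open_top = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
}

#' Minutes band layout for synthetic observations
#'
#' One child band 0-17 and adult bands 18-29, 30-49, 50-64, 65+. Margins are
#' 15\% of the band estimate (filled in by \code{\link{observe_truth}}
#' relative to the noiseless band mean).
#' @param rel_margin relative 95\% margin applied to each band mean.
#' @return data frame \code{group_lo,group_hi,rel_margin,open_top}; the
#'   \code{margin95} column is resolved against a truth by
#'   \code{\link{resolve_minutes_margins}}.
#' @export
default_minutes_bands <- function(rel_margin = 0.15) {
  data.frame(
    group_lo = c(0L, 18L, 30L, 50L, 65L),
    group_hi = c(17L, 29L, 49L, 64L, 84L),
    margin95 = NA_real_, rel_margin = rel_margin,
    open_top = c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

#' Resolve relative minutes margins against a truth curve
#' @param bands a minutes band layout with \code{rel_margin}.
#' @param truth a \code{truth_spec}.
#' @param population a \code{population_table}.
#' @return the layout with absolute \code{margin95} filled in.
#' @export
resolve_minutes_margins <- function(bands, truth, population) {
  m_true <- truth$minutes(population$age)
  mm <- mapply(function(lo, hi) {
    sel <- population$age >= lo & population$age <= hi
    w <- population$count[sel]
    sum(w * m_true[sel]) / sum(w)
  }, bands$group_lo, pmin(bands$group_hi, max(population$age)))
  if (is.null(bands$rel_margin)) bands$rel_margin <- 0.15
  bands$margin95 <- ifelse(is.na(bands$margin95),
    bands$rel_margin * mm, bands$margin95)
  bands
}

#' Calibration target band layout (market-research style)
#'
#' Bands 0-11, 12-17, 18-24, 25-34, 35-44, 45-54, 55-64, 65+, the shape of
#' externally reported platform user totals. The 0-11 band covers ages the
#' surveys do not, so calibration carries information about use below age 8.
#' @return data frame \code{group_lo,group_hi}.
#' @export
default_target_bands <- function() {
  data.frame(
    group_lo = c(0L, 12L, 18L, 25L, 35L, 45L, 55L, 65L),
    group_hi = c(11L, 17L, 24L, 34L, 44L, 54L, 64L, 84L))
}

#' Synthetic U.S.-like population by single year of age
#'
#' Roughly 4 million persons per single year of age from 0 to 84, with a
#' gentle decline after age 60 emulating mortality; the top age is treated
#' as an open band. Deterministic.
#' @param age_max top age (default 84).
#' @return a \code{population_table}.
#' @export
synthetic_population <- function(age_max = 84L) {
  age <- 0:age_max
  count <- ifelse(age <= 60, 4e6,
    4e6 * exp(-0.04 * (age - 60)))
  as_population_table(data.frame(age = age, count = round(count)),
    age_max = age_max)
}

#' Six synthetic platform archetypes
#'
#' Ground-truth specifications spanning the usage shapes the analysis must
#' handle: a video platform used from early childhood, two adolescent-heavy
#' platforms, a broad photo-sharing platform, and two adult-dominated
#' platforms with little youth use. Parameters are fixed test fixtures, not
#' estimates of any real platform.
#' @return named list of \code{truth_spec}.
#' @export
synthetic_platforms <- function() {
  specs <- list(
    # used by young children through adults, long watch times
    youth_video = make_truth("youth_video", pmax = 0.85, a_on = 4,
      w_on = 2, a_off = 62, w_off = 12,
      minutes_knot_ages = c(5, 13, 30, 70),
      minutes_knot_values = c(55, 90, 45, 30),
      revenue_per_minute = 8e-5),
    # adolescent-centred messaging platform
    teen_chat = make_truth("teen_chat", pmax = 0.72, a_on = 12,
      w_on = 1.5, a_off = 28, w_off = 7,
      minutes_knot_ages = c(10, 16, 30),
      minutes_knot_values = c(40, 75, 25),
      revenue_per_minute = 3e-5),
    # short-video platform, teen onset, slower adult decline
    teen_video = make_truth("teen_video", pmax = 0.68, a_on = 11,
      w_on = 2, a_off = 38, w_off = 10,
      minutes_knot_ages = c(8, 15, 40),
      minutes_knot_values = c(60, 85, 40),
      revenue_per_minute = 5e-5),
    # photo sharing, teen onset, broad adult plateau
    photo_share = make_truth("photo_share", pmax = 0.70, a_on = 12,
      w_on = 2.5, a_off = 48, w_off = 11,
      minutes_knot_ages = c(10, 18, 45),
      minutes_knot_values = c(35, 55, 25),
      revenue_per_minute = 1.2e-4),
    # adult-dominated network, late onset
    adult_network = make_truth("adult_network", pmax = 0.75, a_on = 17,
      w_on = 2.5, a_off = 75, w_off = 15,
      minutes_knot_ages = c(15, 30, 70),
      minutes_knot_values = c(20, 35, 30),
      revenue_per_minute = 1.5e-4),
    # adult news/discussion platform, little youth use, short sessions
    adult_news = make_truth("adult_news", pmax = 0.35, a_on = 17,
      w_on = 2, a_off = 55, w_off = 12,
      minutes_knot_ages = c(15, 30, 60),
      minutes_knot_values = c(5, 25, 15),
      revenue_per_minute = 1e-4))
  specs
}

#' Observe the full synthetic study (all platforms)
#'
#' @param truths list of \code{truth_spec} (default the six archetypes).
#' @param population a \code{population_table}.
#' @param seed integer seed; each platform gets an independent substream.
#' @param prevalence_bands,minutes_bands,target_bands band layouts.
#' @param noiseless if TRUE all margins are set to zero (degenerate,
#'   deterministic observations).
#' @return named list of \code{platform_inputs} with \code{"truth"}
#'   attributes.
#' @export
observe_synthetic_study <- function(truths = synthetic_platforms(),
                                    population = synthetic_population(),
                                    seed = 1L,
                                    prevalence_bands = default_survey_bands(),
                                    minutes_bands = default_minutes_bands(),
                                    target_bands = default_target_bands(),
                                    noiseless = FALSE) {
  out <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    mb <- resolve_minutes_margins(minutes_bands, tr, population)
    pb <- prevalence_bands
    if (noiseless) {
      pb$margin95 <- 0
      mb$margin95 <- 0
    }
    observe_truth(tr, population, prevalence_bands = pb,
      minutes_bands = mb, target_bands = target_bands,
      seed = substream_seed(seed, tr$platform_id, i))
  })
  names(out) <- vapply(truths, `[[`, "", "platform_id")
  out
}

#' Write the synthetic input tables to disk
#'
#' Emits the five input CSVs (population, prevalence, minutes, user totals,
#' revenue), a YAML config referencing them, and \code{truth.json} recording
#' the generating curve parameters for later recovery scoring.
#'
#' @param dir output directory.
#' @param truths,population,seed as in
#'   \code{\link{observe_synthetic_study}}.
#' @return invisibly, the written file paths (config first).
#' @export
write_synthetic_inputs <- function(dir, truths = synthetic_platforms(),
                                   population = synthetic_population(),
                                   seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obs <- observe_synthetic_study(truths, population, seed = seed)
  bind <- function(field, cols) {
    do.call(rbind, lapply(obs, function(o) {
      df <- o[[field]][, cols, drop = FALSE]
      cbind(platform = o$platform_id, df)
    }))
  }
  prev <- bind("use_prevalence",
    c("group_lo", "group_hi", "estimate", "margin95", "source", "open_top"))
  mins <- bind("minutes",
    c("group_lo", "group_hi", "estimate", "margin95", "source", "open_top"))
  tots <- bind("user_totals", c("group_lo", "group_hi", "users"))
  revs <- data.frame(platform = names(obs),
    total_revenue_usd = vapply(obs, `[[`, 0, "total_revenue"))
  paths <- file.path(dir, c("config.yaml", "population.csv",
    "prevalence.csv", "minutes.csv", "user_totals.csv", "revenue.csv",
    "truth.json"))
  utils::write.csv(population, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(format_num_df(prev), paths[3], row.names = FALSE,
    quote = FALSE)
  utils::write.csv(format_num_df(mins), paths[4], row.names = FALSE,
    quote = FALSE)
  utils::write.csv(format_num_df(tots), paths[5], row.names = FALSE,
    quote = FALSE)
  utils::write.csv(format_num_df(revs), paths[6], row.names = FALSE,
    quote = FALSE)
  yaml::write_yaml(list(population = "population.csv",
    prevalence = "prevalence.csv", minutes = "minutes.csv",
    user_totals = "user_totals.csv", revenue = "revenue.csv"), paths[1])
  jsonlite::write_json(lapply(truths, `[[`, "params"), paths[7],
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
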