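#' Sample group-level estimates with their sampling error
#'
#' Draws one value per survey band from a Normal centred on the band's point
#' estimate with SD = margin95 / 1.96 — the sampling SD implied by reading
#' the margin as a 95\% CI half-width — truncated to the estimate's legal
#' range. A zero margin returns the point estimate exactly.
#'
#' @param bands an \code{age_band_table} (or data frame with
#'   \code{estimate,margin95}).
#' @param range legal range of the quantity: \code{c(0, 1)} for
#'   proportions, \code{c(0, Inf)} for minutes.
#' @param seed optional integer; if given, sampling is done in a local,
#'   seeded RNG stream and the caller's RNG state is untouched.
#' @return numeric vector, one draw per band.
#' @export
sample_group_estimates <- function(bands, range = c(0, 1), seed = NULL) {
  stopifnot(all(bands$margin95 >= 0))
  draw <- function() {
    rtrunc_norm(nrow(bands), bands$estimate, bands$margin95 / 1.96,
      range[1], range[2])
  }
  if (is.null(seed)) return(draw())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  draw()
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Natural cubic spline interpolation
#'
#' Interpolates knot points with the natural cubic spline (continuous second
#' derivatives, zero second derivative at the boundary knots) and evaluates
#' it at the requested ages. Beyond the boundary knots the natural boundary
#' condition makes the extrapolation linear. With exactly two knots the
#' spline is the straight line through them.
#'
#' @param knot_ages strictly increasing knot locations (>= 2 knots).
#' @param knot_values values at the knots.
#' @param ages evaluation points.
#' @return values at \code{ages}.
#' @export
spline_interpolate <- function(knot_ages, knot_values, ages) {
  if (length(knot_ages) < 2) {
    stop("spline needs at least 2 knots", call. = FALSE)
  }
  if (length(knot_ages) != length(knot_values)) {
    stop("knot_ages and knot_values differ in length", call. = FALSE)
  }
  if (any(diff(knot_ages) <= 0)) {
    stop("knot_ages must be strictly increasing", call. = FALSE)
  }
  stats::splinefun(knot_ages, knot_values, method = "natural")(ages)
}

#' Band midpoint knot locations
#'
#' Each survey band contributes one spline knot at its midpoint
#' \code{(group_lo + group_hi) / 2}; an open-ended top band ("65+") uses the
#' midpoint of \code{group_lo..age_max} instead.
#'
#' @param bands an \code{age_band_table}.
#' @param age_max top age of the analysis.
#' @return numeric vector of knot ages.
#' @export
band_midpoints <- function(bands, age_max = 84L) {
  hi <- ifelse(as_flag(band_col(bands, "open_top")), age_max,
    bands$group_hi)
  (bands$group_lo + hi) / 2
}

#' Build a single-year-of-age profile from one parameter set
#'
#' Places knots at the band midpoints of the prevalence and minutes layouts,
#' fits a separate natural cubic spline through each set of sampled values,
#' evaluates both at every age 0..age_max, and clamps: use probability to
#' [0, 1], minutes to [0, Inf). Ages below the youngest knot (e.g. 0-7 when
#' the youngest survey band starts at 8) take the boundary-linear
#' extrapolation, clamped at zero. A single minutes band yields a constant
#' minutes curve.
#'
#' @param ps a \code{parameter_set} from \code{\link{draw_parameter_set}}.
#' @param inputs the \code{platform_inputs} providing the band layouts.
#' @param age_max top age.
#' @return an \code{age_profile}: list with \code{ages}, \code{p}
#'   (probability of use), \code{m} (minutes/day among users).
#' @export
build_age_profile <- function(ps, inputs, age_max = 84L) {
  ages <- 0:age_max
  pk <- band_midpoints(inputs$use_prevalence, age_max)
  p_raw <- spline_interpolate(pk, ps$prevalence_draws, ages)
  p <- pmin(pmax(p_raw, 0), 1)
  if (nrow(inputs$minutes) == 1) {
    m <- rep(max(ps$minutes_draws, 0), length(ages))
  } else {
    mk <- band_midpoints(inputs$minutes, age_max)
    m <- pmax(spline_interpolate(mk, ps$minutes_draws, ages), 0)
  }
  structure(list(platform_id = inputs$platform_id, ages = ages,
    p = p, m = m), class = "age_profile")
}

#' Draw one parameter set for a platform
#'
#' A parameter set is one joint draw of all group-level prevalence and
#' minutes values, the unit over which fit quality is scored and
#' uncertainty propagated.
#'
#' @param inputs a \code{platform_inputs}.
#' @param seed integer substream seed.
#' @return a \code{parameter_set}.
#' @export
draw_parameter_set <- function(inputs, seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  structure(list(platform_id = inputs$platform_id,
    prevalence_draws = rtrunc_norm(nrow(inputs$use_prevalence),
      inputs$use_prevalence$estimate,
      inputs$use_prevalence$margin95 / 1.96, 0, 1),
    minutes_draws = rtrunc_norm(nrow(inputs$minutes),
      inputs$minutes$estimate, inputs$minutes$margin95 / 1.96, 0, Inf),
    seed = seed), class = "parameter_set")
}

#' Users by single year of age
#'
#' @param profile an \code{age_profile}.
#' @param population a \code{population_table} over the same ages.
#' @return numeric vector, \code{users_a = count_a * p_a}.
#' @export
users_by_age <- function(profile, population) {
  if (length(profile$p) != nrow(population)) {
    stop("profile and population cover different age ranges",
      call. = FALSE)
  }
  population$count * profile$p
}
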