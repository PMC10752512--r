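#' Loss of an age profile against external user totals
#'
#' Sum over calibration bands of the squared relative error between modeled
#' band users (\eqn{\sum_a count_a p_a} over the band) and the externally
#' reported band total. Zero exactly when every band matches. A band with a
#' zero target contributes \code{(modeled / ref_scale)^2} where
#' \code{ref_scale} is the mean of the nonzero targets, so a zero target
#' never divides by zero; all-zero targets are an error.
#'
#' @param profile an \code{age_profile}.
#' @param population a \code{population_table}.
#' @param targets data frame \code{group_lo,group_hi,users}.
#' @return nonnegative scalar loss.
#' @export
profile_loss <- function(profile, population, targets) {
  if (nrow(targets) == 0 || any(targets$users < 0)) {
    stop("targets must be non-empty with nonnegative user counts",
      call. = FALSE)
  }
  if (all(targets$users == 0)) {
    stop("all calibration targets are zero", call. = FALSE)
  }
  users <- users_by_age(profile, population)
  modeled <- vapply(seq_len(nrow(targets)), function(i) {
    sel <- population$age >= targets$group_lo[i] &
      population$age <= targets$group_hi[i]
    sum(users[sel])
  }, numeric(1))
  ref <- mean(targets$users[targets$users > 0])
  denom <- ifelse(targets$users > 0, targets$users, ref)
  sum(((modeled - targets$users) / denom)^2)
}

# counter-based substream: deterministic, order-independent hash of
# (base seed, label bytes, counter) into [1, 2^31 - 2]
substream_seed <- function(seed, label, i) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  h <- (h + (as.numeric(i) * 2654435761)) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Fit one platform by seeded stochastic search
#'
#' Realizes the stochastic optimization as seeded random search over the
#' sampling distributions of the group estimates: draws
#' \code{config$n_candidates} parameter sets (each from its own
#' counter-based substream of \code{config$seed}, so results do not depend
#' on evaluation order or on other platforms), builds each candidate's age
#' profile, scores it against the platform's external user totals, and
#' retains the \code{config$n_keep} lowest-loss candidates as the
#' uncertainty ensemble. Deterministic under a fixed seed.
#'
#' @param inputs a \code{platform_inputs}.
#' @param population a \code{population_table}.
#' @param config a \code{run_config} (\code{n_candidates >= n_keep}).
#' @return a \code{fitted_ensemble}: members sorted by loss ascending, each
#'   a list \code{(params, profile, loss)}; also carries every candidate's
#'   loss for selection audits.
#' @export
fit_platform <- function(inputs, population, config = run_config()) {
  if (config$n_candidates < config$n_keep) {
    stop("n_candidates must be >= n_keep", call. = FALSE)
  }
  n <- config$n_candidates
  losses <- numeric(n)
  keep_n <- config$n_keep
  candidates <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- draw_parameter_set(inputs,
      substream_seed(config$seed, inputs$platform_id, i))
    profile <- build_age_profile(ps, inputs, config$age_max)
    losses[i] <- profile_loss(profile, population, inputs$user_totals)
    candidates[[i]] <- list(params = ps, profile = profile)
  }
  keep <- order(losses)[seq_len(keep_n)]
  members <- lapply(keep, function(i) {
    c(candidates[[i]], list(loss = losses[i]))
  })
  structure(list(platform_id = inputs$platform_id, members = members,
    losses = losses[keep], candidate_losses = losses,
    n_candidates_evaluated = n, n_keep = keep_n, seed = config$seed),
    class = "fitted_ensemble")
}

#' @export
print.fitted_ensemble <- function(x, ...) {
  cat("<fitted_ensemble> ", x$platform_id, ": kept ", x$n_keep, " of ",
    x$n_candidates_evaluated, " candidates; loss range [",
    format(min(x$losses), digits = 4), ", ",
    format(max(x$losses), digits = 4), "]\n", sep = "")
  invisible(x)
}
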