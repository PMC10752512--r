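#' Allocate annual revenue across ages by person-minutes
#'
#' Under the constant revenue-per-minute assumption, each age receives a
#' share of the platform's total annual advertising revenue proportional to
#' its daily person-minutes (\code{users_a * m_a}):
#' \deqn{rev_a = R \cdot \frac{u_a m_a}{\sum_b u_b m_b}.}
#' The allocation conserves the total exactly; the 365x annualization
#' cancels in the ratio and appears only in the implied revenue-per-minute
#' diagnostic attribute.
#'
#' @param profile an \code{age_profile}.
#' @param population a \code{population_table}.
#' @param total_revenue total annual revenue (USD/year, > 0).
#' @return a \code{revenue_table} data frame with columns \code{age, users,
#'   person_minutes, revenue}; attributes \code{platform_id},
#'   \code{total_revenue}, \code{revenue_per_minute_year} (USD per annual
#'   person-minute).
#' @export
allocate_revenue <- function(profile, population, total_revenue) {
  users <- users_by_age(profile, population)
  pm <- users * profile$m
  total_pm <- sum(pm)
  if (total_pm <= 0) {
    stop("platform '", profile$platform_id,
      "' has zero modeled person-minutes; cannot allocate revenue",
      call. = FALSE)
  }
  revenue <- total_revenue * pm / total_pm
  structure(data.frame(age = profile$ages, users = users,
    person_minutes = pm, revenue = revenue),
    platform_id = profile$platform_id,
    total_revenue = total_revenue,
    revenue_per_minute_year = total_revenue / (total_pm * 365),
    class = c("revenue_table", "data.frame"))
}

#' Aggregate a per-age revenue table into reporting bands
#'
#' @param table a \code{revenue_table} from \code{\link{allocate_revenue}}.
#' @param bands data frame \code{band,group_lo,group_hi} (default youth
#'   bands 0-12, 13-17, 0-17).
#' @return data frame \code{band, users, revenue, share} where \code{share}
#'   is the band's fraction of total platform revenue.
#' @export
band_aggregate <- function(table, bands = default_youth_bands()) {
  if (any(bands$group_lo < min(table$age) |
      bands$group_hi > max(table$age))) {
    stop("reporting band outside the modeled age range", call. = FALSE)
  }
  total <- attr(table, "total_revenue")
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- table$age >= bands$group_lo[i] & table$age <= bands$group_hi[i]
    data.frame(band = bands$band[i],
      users = sum(table$users[sel]),
      revenue = sum(table$revenue[sel]),
      share = sum(table$revenue[sel]) / total)
  })
  do.call(rbind, rows)
}

#' Impute a child minutes band when none covers ages under 18
#'
#' Platforms whose minutes table has no band touching ages 0-17 get a
#' synthetic 0-17 band at a configured default (5 minutes/day) with zero
#' margin — the convention used when a platform's child minutes go
#' unreported by usage trackers.
#'
#' @param inputs a \code{platform_inputs}.
#' @param default_minutes minutes/day to impute.
#' @return the inputs, possibly with one extra minutes band.
#' @export
impute_child_minutes <- function(inputs, default_minutes = 5) {
  covers_child <- any(inputs$minutes$group_lo <= 17)
  if (covers_child) return(inputs)
  child <- data.frame(group_lo = 0L, group_hi = 17L,
    estimate = default_minutes, margin95 = 0,
    source = "imputed default", open_top = FALSE)
  m <- rbind(child, as.data.frame(inputs$minutes))
  m <- m[order(m$group_lo), , drop = FALSE]
  inputs$minutes <- structure(m,
    class = c("age_band_table", "data.frame"))
  inputs
}
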