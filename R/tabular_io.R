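#' Read a single-year-of-age population table
#'
#' Reads a CSV with columns \code{age} (integer years) and \code{count}
#' (persons) and validates it: ages must be unique and contiguous from 0 to
#' the maximum age, counts nonnegative. Population recorded above
#' \code{age_max} is accumulated into the top age, which is treated as an
#' open-ended band (e.g. "84+").
#'
#' @param path path to a CSV file with header \code{age,count}.
#' @param age_max top single year of age retained (default 84).
#' @return a \code{population_table}: a data frame with columns \code{age}
#'   and \code{count}, ages \code{0:age_max}.
#' @export
load_population <- function(path, age_max = 84L) {
  df <- read_csv_checked(path, c("age", "count"))
  as_population_table(df, age_max = age_max)
}

#' Construct and validate a population table
#'
#' @param df data frame with integer column \code{age} and numeric
#'   \code{count}.
#' @param age_max top age; rows with \code{age > age_max} are folded into
#'   \code{age_max}.
#' @return a validated \code{population_table}.
#' @export
as_population_table <- function(df, age_max = 84L) {
  stopifnot(is.data.frame(df), all(c("age", "count") %in% names(df)))
  if (anyNA(df$age) || anyNA(df$count)) {
    stop("population table: missing values in 'age' or 'count'",
      call. = FALSE)
  }
  if (any(df$age != as.integer(df$age))) {
    stop("population table: non-integer age at row ",
      which(df$age != as.integer(df$age))[1], call. = FALSE)
  }
  bad <- which(df$count < 0)
  if (length(bad)) {
    stop("population table: negative count at row ", bad[1],
      " (column 'count')", call. = FALSE)
  }
  # fold ages above the open-ended top band into age_max
  df$age <- pmin(as.integer(df$age), as.integer(age_max))
  if (anyDuplicated(df$age[df$age < age_max])) {
    dup <- df$age[df$age < age_max][duplicated(df$age[df$age < age_max])][1]
    stop("population table: duplicate age ", dup, call. = FALSE)
  }
  count <- vapply(0:age_max, function(a) sum(df$count[df$age == a]),
    numeric(1))
  missing_ages <- (0:age_max)[!(0:age_max) %in% df$age]
  if (length(missing_ages)) {
    stop("population table: missing age ", missing_ages[1],
      " (ages must be contiguous 0..", age_max, ")", call. = FALSE)
  }
  structure(data.frame(age = 0:age_max, count = count),
    class = c("population_table", "data.frame"))
}

#' Survey age-band estimates
#'
#' An age-band table holds one row per survey band: inclusive bounds
#' \code{group_lo}/\code{group_hi}, a point \code{estimate} (a proportion in
#' [0, 1] or minutes/day), a \code{margin95} (the +/- half-width of the 95\%
#' confidence interval, same units as the estimate), a \code{source} label,
#' and \code{open_top} flagging an open-ended top band such as "65+".
#'
#' @param group_lo,group_hi inclusive integer age bounds.
#' @param estimate point estimates.
#' @param margin95 95\% CI half-widths (>= 0).
#' @param source free-text source labels.
#' @param open_top logical; is the band open-ended at the top ("65+")?
#' @param proportion if TRUE, estimates must lie in [0, 1].
#' @return an \code{age_band_table} data frame.
#' @export
age_band_table <- function(group_lo, group_hi, estimate, margin95,
                           source = "", open_top = FALSE,
                           proportion = TRUE) {
  df <- data.frame(group_lo = as.integer(group_lo),
    group_hi = as.integer(group_hi),
    estimate = as.numeric(estimate), margin95 = as.numeric(margin95),
    source = source, open_top = open_top)
  validate_bands(df, proportion = proportion)
  structure(df, class = c("age_band_table", "data.frame"))
}

validate_bands <- function(df, proportion = TRUE, what = "band table") {
  if (nrow(df) == 0) stop(what, ": no bands", call. = FALSE)
  bad <- which(df$group_lo > df$group_hi)
  if (length(bad)) {
    stop(what, ": group_lo > group_hi at row ", bad[1], call. = FALSE)
  }
  bad <- which(df$margin95 < 0)
  if (length(bad)) {
    stop(what, ": negative margin95 at row ", bad[1], call. = FALSE)
  }
  if (proportion) {
    bad <- which(df$estimate < 0 | df$estimate > 1)
    if (length(bad)) {
      stop(what, ": proportion estimate outside [0,1] at row ", bad[1],
        " (column 'estimate', value ", df$estimate[bad[1]], ")",
        call. = FALSE)
    }
  } else if (any(df$estimate < 0)) {
    stop(what, ": negative estimate at row ", which(df$estimate < 0)[1],
      call. = FALSE)
  }
  o <- order(df$group_lo)
  lo <- df$group_lo[o]; hi <- df$group_hi[o]
  if (nrow(df) > 1 && any(lo[-1] <= hi[-nrow(df)])) {
    i <- which(lo[-1] <= hi[-nrow(df)])[1]
    stop(what, ": overlapping bands ", lo[i], "-", hi[i], " and ",
      lo[i + 1], "-", hi[i + 1], call. = FALSE)
  }
  invisible(df)
}

#' Bundle the inputs for one platform
#'
#' @param platform_id platform identifier.
#' @param use_prevalence \code{age_band_table} of use proportions.
#' @param minutes \code{age_band_table} of minutes/day among users.
#' @param user_totals data frame \code{group_lo,group_hi,users}: external
#'   calibration targets (total platform users per age band).
#' @param total_revenue total annual advertising revenue (USD/year, > 0).
#' @param age_max top age of the analysis.
#' @return a \code{platform_inputs} object.
#' @export
platform_inputs <- function(platform_id, use_prevalence, minutes,
                            user_totals, total_revenue, age_max = 84L) {
  if (is.null(total_revenue) || is.na(total_revenue) || total_revenue <= 0) {
    stop("platform '", platform_id, "': total_revenue must be > 0",
      call. = FALSE)
  }
  if (nrow(use_prevalence) < 2) {
    stop("platform '", platform_id, "': need at least 2 prevalence bands",
      call. = FALSE)
  }
  if (nrow(minutes) < 1) {
    stop("platform '", platform_id, "': need at least 1 minutes band",
      call. = FALSE)
  }
  validate_bands(use_prevalence, proportion = TRUE,
    what = paste0("platform '", platform_id, "' prevalence"))
  validate_bands(minutes, proportion = FALSE,
    what = paste0("platform '", platform_id, "' minutes"))
  stopifnot(all(c("group_lo", "group_hi", "users") %in% names(user_totals)))
  if (any(user_totals$group_lo < 0 | user_totals$group_hi > age_max)) {
    stop("platform '", platform_id,
      "': calibration band outside [0, ", age_max, "]", call. = FALSE)
  }
  if (any(user_totals$users < 0)) {
    stop("platform '", platform_id, "': negative user total", call. = FALSE)
  }
  structure(list(platform_id = platform_id,
    use_prevalence = use_prevalence, minutes = minutes,
    user_totals = user_totals, total_revenue = as.numeric(total_revenue),
    age_max = as.integer(age_max)),
    class = "platform_inputs")
}

#' @export
print.platform_inputs <- function(x, ...) {
  cat("<platform_inputs> ", x$platform_id, "\n",
    "  prevalence bands: ", nrow(x$use_prevalence),
    ", minutes bands: ", nrow(x$minutes),
    ", calibration bands: ", nrow(x$user_totals), "\n",
    "  total revenue: ", format(x$total_revenue, big.mark = ","),
    " USD/year\n", sep = "")
  invisible(x)
}

#' Load per-platform inputs from a run configuration file
#'
#' The configuration is a YAML file naming four CSVs (paths relative to the
#' configuration file): \code{prevalence} and \code{minutes} with columns
#' \code{platform,group_lo,group_hi,estimate,margin95,source,open_top};
#' \code{user_totals} with \code{platform,group_lo,group_hi,users}; and
#' \code{revenue} with \code{platform,total_revenue_usd}. One
#' \code{platform_inputs} is returned per platform listed in the prevalence
#' table; a platform missing a revenue row is an error.
#'
#' @param path path to the YAML configuration.
#' @param age_max top age of the analysis.
#' @return named list of \code{platform_inputs}.
#' @export
load_platform_inputs <- function(path, age_max = 84L) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("prevalence", "minutes", "user_totals", "revenue")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("config missing entries: ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base, p)
  prev <- read_csv_checked(resolve(cfg$prevalence),
    c("platform", "group_lo", "group_hi", "estimate", "margin95"))
  mins <- read_csv_checked(resolve(cfg$minutes),
    c("platform", "group_lo", "group_hi", "estimate", "margin95"))
  tots <- read_csv_checked(resolve(cfg$user_totals),
    c("platform", "group_lo", "group_hi", "users"))
  revs <- read_csv_checked(resolve(cfg$revenue),
    c("platform", "total_revenue_usd"))
  platforms <- unique(prev$platform)
  out <- lapply(platforms, function(pid) {
    p <- prev[prev$platform == pid, , drop = FALSE]
    m <- mins[mins$platform == pid, , drop = FALSE]
    t <- tots[tots$platform == pid, , drop = FALSE]
    r <- revs$total_revenue_usd[revs$platform == pid]
    if (length(r) == 0) {
      stop("platform '", pid, "': missing total_revenue", call. = FALSE)
    }
    platform_inputs(pid,
      use_prevalence = age_band_table(p$group_lo, p$group_hi, p$estimate,
        p$margin95, source = band_col(p, "source"),
        open_top = as_flag(band_col(p, "open_top")), proportion = TRUE),
      minutes = age_band_table(m$group_lo, m$group_hi, m$estimate,
        m$margin95, source = band_col(m, "source"),
        open_top = as_flag(band_col(m, "open_top")), proportion = FALSE),
      user_totals = t[, c("group_lo", "group_hi", "users")],
      total_revenue = r[1], age_max = age_max)
  })
  names(out) <- platforms
  out
}

band_col <- function(df, name) {
  if (name %in% names(df)) df[[name]] else
    if (name == "open_top") FALSE else ""
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s) ",
      paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write summarized pipeline outputs
#'
#' Emits three tidy CSVs — users by reporting band, revenue by band, and
#' revenue share by band, each with ensemble mean and uncertainty-interval
#' bounds — plus a JSON manifest recording the run configuration, seed,
#' percentile convention, and MD5 digests of any input files.
#'
#' @param summaries list with data frames \code{users}, \code{revenue},
#'   \code{share} (columns \code{platform, band, mean, ui_lo, ui_hi}).
#' @param dir output directory (created if needed).
#' @param config the \code{run_config} used.
#' @param input_files character vector of input file paths to digest.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(summaries, dir, config = run_config(),
                          input_files = character()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- c(users = file.path(dir, "users_by_band.csv"),
    revenue = file.path(dir, "revenue_by_band.csv"),
    share = file.path(dir, "revenue_share_by_band.csv"),
    manifest = file.path(dir, "manifest.json"))
  empty <- data.frame(platform = character(), band = character(),
    mean = numeric(), ui_lo = numeric(), ui_hi = numeric())
  for (nm in c("users", "revenue", "share")) {
    tab <- summaries[[nm]]
    if (is.null(tab) || nrow(tab) == 0) tab <- empty
    utils::write.csv(format_num_df(tab), paths[[nm]], row.names = FALSE,
      quote = FALSE)
  }
  digests <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  } else list()
  manifest <- list(
    package = "youthadrev",
    config = unclass(config),
    percentile_definition = "linear interpolation between closest order statistics (quantile type 7)",
    input_digests = digests,
    files = as.list(basename(paths[c("users", "revenue", "share")])))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(paths)
}

# fixed-notation formatting so outputs are byte-stable across locales
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 15)
    }
  }
  df
}

#' Analysis run configuration
#'
#' @param seed base integer seed; every stochastic stage derives its
#'   substreams from it.
#' @param age_max top single year of age (treated as an open "84+" band).
#' @param n_candidates candidate parameter sets drawn per platform.
#' @param n_keep retained best-fitting sets forming the uncertainty
#'   ensemble.
#' @param ui_lo,ui_hi uncertainty-interval percentiles (default 2.5, 97.5).
#' @param youth_bands reporting bands as a data frame
#'   \code{band,group_lo,group_hi} (default 0-12, 13-17, 0-17).
#' @param child_minutes_default minutes/day imputed, with zero margin, as a
#'   0-17 band for a platform whose minutes table has no band covering ages
#'   under 18 (default 5, the convention used when a platform's child
#'   minutes go unreported).
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed = 1L, age_max = 84L, n_candidates = 10000L,
                       n_keep = 100L, ui_lo = 2.5, ui_hi = 97.5,
                       youth_bands = default_youth_bands(),
                       child_minutes_default = 5) {
  stopifnot(n_keep >= 1, n_candidates >= n_keep,
    ui_lo >= 0, ui_hi <= 100, ui_lo < ui_hi, age_max >= 1)
  structure(list(seed = as.integer(seed), age_max = as.integer(age_max),
    n_candidates = as.integer(n_candidates), n_keep = as.integer(n_keep),
    ui_lo = ui_lo, ui_hi = ui_hi, youth_bands = youth_bands,
    child_minutes_default = child_minutes_default),
    class = "run_config")
}

#' Default reporting bands: children 0-12, adolescents 13-17, all youth 0-17
#' @return data frame \code{band,group_lo,group_hi}.
#' @export
default_youth_bands <- function() {
  data.frame(band = c("0-12", "13-17", "0-17"),
    group_lo = c(0L, 13L, 0L), group_hi = c(12L, 17L, 17L))
}
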