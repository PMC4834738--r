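#' Band specification for the adherence zone
#'
#' How far above/below the predicted trajectory the zone bounds sit.
#' The default is a symmetric band of +/- 2 % of baseline weight;
#' absolute widths in lb or kg and asymmetric bands are supported.
#'
#' @param type `"percent_baseline"`, `"absolute_lb"` or `"absolute_kg"`.
#' @param value Band half-width (percent of baseline weight, lb, or kg
#'   according to `type`); used for both sides unless `upper`/`lower`
#'   are given.
#' @param upper,lower Optional asymmetric half-widths, same unit as
#'   `type`.
#' @return A `band_spec` list.
#' @export
band_spec <- function(type = c("percent_baseline", "absolute_lb", "absolute_kg"),
                      value = 2, upper = NULL, lower = NULL) {
  type <- match.arg(type)
  upper <- upper %||% value
  lower <- lower %||% value
  if (upper < 0 || lower < 0)
    abort_wrx("band widths must be >= 0", "weightrx_invalid_config")
  structure(list(type = type, upper = upper, lower = lower),
            class = "band_spec")
}

band_width_kg <- function(band, baseline_kg) {
  f <- switch(band$type,
              percent_baseline = baseline_kg / 100,
              absolute_lb = lb_to_kg(1),
              absolute_kg = 1)
  c(upper = band$upper * f, lower = band$lower * f)
}

#' Build the zone of adherence
#'
#' Upper and lower bound series around a predicted trajectory.  A
#' client is considered adherent to the energy prescription while their
#' observed weight stays between the bounds.
#'
#' @param trajectory A [predict_trajectory()] result.
#' @param band A [band_spec()].
#' @param baseline_date Optional `Date` of day 0 (adds a `date` column).
#' @return An `adherence_zone`: tibble with `day`, optional `date`,
#'   `predicted_kg`, `lower_kg`, `upper_kg`.
#' @export
build_zone <- function(trajectory, band = band_spec(),
                       baseline_date = NULL) {
  stopifnot(inherits(trajectory, "weight_trajectory"))
  baseline_kg <- trajectory$weight_kg[trajectory$day == 0]
  w <- band_width_kg(band, baseline_kg)
  out <- tibble::tibble(
    day = trajectory$day,
    predicted_kg = trajectory$weight_kg,
    lower_kg = trajectory$weight_kg - w[["lower"]],
    upper_kg = trajectory$weight_kg + w[["upper"]]
  )
  if (!is.null(baseline_date)) {
    out$date <- as.Date(baseline_date) + out$day
    out <- out[, c("day", "date", "predicted_kg", "lower_kg", "upper_kg")]
  }
  structure(out, band = band, class = c("adherence_zone", class(out)))
}

# least-squares line through (x, y); returns slope, its standard error
# and n.  se is 0 for an exact fit.
ls_fit <- function(x, y) {
  n <- length(x)
  if (n < 2) return(list(slope = NA_real_, se = NA_real_, n = n))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  if (n > 2) {
    res <- y - mean(y) - slope * xc
    se <- sqrt(max(sum(res^2), 0) / (n - 2) / sxx)
  } else se <- 0
  list(slope = slope, se = se, n = n)
}

#' Flag classification configuration
#'
#' Tunable cutoffs for the daily color-coded flag:
#' * `trail_window` — days in the trailing slope window.
#' * `min_points` — retained weights needed before slope conditions are
#'   evaluated (below it only in/out of zone is used).
#' * `edge_frac` — "approaching the upper edge" means within this top
#'   fraction of the band.
#' * `plateau_conf` — one-sided confidence level for declaring a
#'   plateau: the trailing slope must be non-negative with this
#'   statistical confidence (t-test against zero using the fit's own
#'   residual error), which guards against noise-driven false alarms
#'   in daily scale weights.  Set `NULL` for the raw rule
#'   (slope >= 0).
#'
#' @param trail_window,min_points,edge_frac,plateau_conf See above.
#' @return A `flag_config` list.
#' @export
flag_config <- function(trail_window = 7L, min_points = 3L,
                        edge_frac = 0.2, plateau_conf = 0.95) {
  structure(list(trail_window = as.integer(trail_window),
                 min_points = as.integer(min_points),
                 edge_frac = edge_frac, plateau_conf = plateau_conf),
            class = "flag_config")
}

plateau_hit <- function(slope, se, n, conf) {
  if (is.null(conf) || !is.finite(se) || se == 0) return(slope >= 0)
  slope / se >= qt(conf, df = n - 2)
}

#' Classify the daily adherence flag
#'
#' One of five states for a client-date:
#' * `GREEN` — weight inside the zone, losing as expected;
#' * `GREEN_YELLOW` — inside the zone but plateauing while the
#'   prediction slopes down, or within the top `edge_frac` of the band;
#' * `RED` — outside the zone (above it without an adherent downward
#'   trend, or below it);
#' * `RED_GREEN` — above the zone but decreasing at least as fast as
#'   the predicted slope, i.e. on course to re-enter;
#' * `NO_DATA` — no retained weight that date.
#'
#' Trailing slopes are least-squares fits over the retained weights of
#' the last `trail_window` days; with fewer than `min_points` points
#' only the in/out-of-zone test is applied.
#'
#' @param series A `weight_series`.
#' @param zone An [build_zone()] result with a `date` column, or with
#'   `day` matched against the series' day offsets.
#' @param date The `Date` to classify.
#' @param config A [flag_config()].
#' @return One-row tibble: `date`, `flag`, `weight_kg`, `lower_kg`,
#'   `upper_kg`, `obs_slope`, `pred_slope`.
#' @export
classify_flag <- function(series, zone, date, config = flag_config()) {
  date <- as.Date(date)
  zdate <- zone_dates(zone, series)
  zi <- match(date, zdate)
  if (is.na(zi))
    abort_wrx("date outside the zone horizon", "weightrx_invalid_input")
  lower <- zone$lower_kg[zi]
  upper <- zone$upper_kg[zi]
  obs <- retained_observations(series)
  w <- obs$weight_kg[match(date, obs$date)]
  row <- tibble::tibble(date = date, flag = NA_character_,
                        weight_kg = NA_real_, lower_kg = lower,
                        upper_kg = upper, obs_slope = NA_real_,
                        pred_slope = NA_real_)
  if (is.na(w)) {
    row$flag <- "NO_DATA"
    return(row)
  }
  row$weight_kg <- w
  win <- obs[obs$date >= date - (config$trail_window - 1) & obs$date <= date, ]
  fit <- NULL
  pred_slope <- NA_real_
  if (nrow(win) >= config$min_points) {
    fit <- ls_fit(as.numeric(win$date), win$weight_kg)
    pz <- zone[zdate >= date - (config$trail_window - 1) & zdate <= date, ]
    pred_slope <- ls_fit(as.numeric(zone_dates(pz, series)), pz$predicted_kg)$slope
    row$obs_slope <- fit$slope
    row$pred_slope <- pred_slope
  }
  in_zone <- w >= lower && w <= upper
  if (in_zone) {
    plateau <- !is.null(fit) && !is.na(pred_slope) && pred_slope < 0 &&
      plateau_hit(fit$slope, fit$se, fit$n, config$plateau_conf)
    near_edge <- upper > lower &&
      w > upper - config$edge_frac * (upper - lower)
    row$flag <- if (plateau || near_edge) "GREEN_YELLOW" else "GREEN"
  } else if (w > upper) {
    adherent_rate <- !is.null(fit) && !is.na(pred_slope) &&
      fit$slope <= pred_slope
    row$flag <- if (adherent_rate) "RED_GREEN" else "RED"
  } else {
    row$flag <- "RED"
  }
  row
}

# dates of the zone grid; falls back to the series baseline date when
# the zone was built without one
zone_dates <- function(zone, series) {
  if ("date" %in% names(zone)) return(zone$date)
  as.Date(attr(series, "baseline_date")) + zone$day
}

#' Classify flags for a range of dates
#'
#' @inheritParams classify_flag
#' @param dates Dates to classify; defaults to the full zone grid.
#' @return Tibble with one row per date (see [classify_flag()]).
#' @export
flag_series <- function(series, zone, dates = NULL, config = flag_config()) {
  dates <- as.Date(dates %||% zone_dates(zone, series))
  dplyr::bind_rows(lapply(dates, function(d)
    classify_flag(series, zone, d, config)))
}

#' k-of-n out-of-zone trigger
#'
#' Fires when at least `k` of the most recent `n` dated flags are in
#' `count_states` (default: `RED` only — a client above the zone but
#' decreasing at an adherent rate, `RED_GREEN`, signals recovering
#' adherence and is not counted).  `NO_DATA` days occupy window slots
#' but are never counted toward `k`; set `no_data_in_window = FALSE`
#' to drop them from the window first.  With fewer than `n` dated
#' flags since enrollment the trigger never fires.
#'
#' @param flags Character vector of flag states ordered oldest to
#'   newest, one per calendar date since enrollment.
#' @param k,n Trigger parameters (`n >= k >= 1`), default 3 of 5.
#' @param count_states Flag states counted toward `k`.
#' @param no_data_in_window Whether `NO_DATA` days occupy window slots.
#' @return `TRUE` or `FALSE`.
#' @examples
#' trigger_check(c("RED", "GREEN", "RED", "GREEN", "RED")) # TRUE
#' @export
trigger_check <- function(flags, k = 3L, n = 5L, count_states = "RED",
                          no_data_in_window = TRUE) {
  if (k < 1 || n < k)
    abort_wrx("need n >= k >= 1", "weightrx_invalid_config")
  if (!no_data_in_window) flags <- flags[flags != "NO_DATA"]
  if (length(flags) < n) return(FALSE)
  sum(tail(flags, n) %in% count_states) >= k
}

#' Plot the weight graph: prediction, zone and observed weights
#'
#' @param zone An [build_zone()] result (with dates).
#' @param series Optional `weight_series` to overlay.
#' @param unit `"lb"` or `"kg"`.
#' @return A ggplot object.
#' @export
plot_zone <- function(zone, series = NULL, unit = c("lb", "kg")) {
  unit <- match.arg(unit)
  cv <- if (unit == "lb") kg_to_lb else identity
  zd <- tibble::as_tibble(zone)
  zd$x <- if ("date" %in% names(zd)) zd$date else zd$day
  p <- ggplot2::ggplot(zd, ggplot2::aes(x = x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = cv(lower_kg),
                                      ymax = cv(upper_kg)),
                         fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = cv(predicted_kg)),
                       color = "goldenrod", linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = cv(lower_kg)),
                       linetype = "dashed", color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = cv(upper_kg)),
                       linetype = "dashed", color = "steelblue") +
    ggplot2::labs(x = NULL, y = sprintf("Weight (%s)", unit))
  if (!is.null(series)) {
    obs <- retained_observations(series)
    obs$x <- if ("date" %in% names(zd)) obs$date else obs$day
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(x = x,
                                              y = cv(weight_kg)),
                                 color = "purple", size = 1)
  }
  p
}

#' Export a zone and its per-day flags to CSV
#'
#' @param zone An `adherence_zone`.
#' @param flags Optional [flag_series()] result to join on date.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_zone_csv <- function(zone, path, flags = NULL) {
  df <- as.data.frame(tibble::as_tibble(zone))
  df$predicted_lb <- kg_to_lb(df$predicted_kg)
  df$lower_lb <- kg_to_lb(df$lower_kg)
  df$upper_lb <- kg_to_lb(df$upper_kg)
  if (!is.null(flags) && "date" %in% names(df))
    df$flag <- flags$flag[match(df$date, flags$date)]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
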