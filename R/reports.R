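# percentages are displayed to one decimal, half-up
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Assemble a client log
#'
#' The container the reporting functions consume: cleaned telemetry
#' plus the event streams a client generates.
#'
#' @param client_id Identifier.
#' @param enrollment_start,enrollment_end Enrollment `Date`s
#'   (inclusive; the enrollment day itself counts).
#' @param series A `weight_series`.
#' @param steps Step-record tibble (`date`, `steps`).
#' @param view_events Tibble of UI view events (`date`, `target` in
#'   `weight_graph`/`step_graph`/`tip`, `tip_id`).
#' @param feedback_events Tibble of feedback events.
#' @param episodes Episode history tibble.
#' @return A `client_log` list.
#' @export
client_log <- function(client_id, enrollment_start, enrollment_end,
                       series, steps = NULL, view_events = NULL,
                       feedback_events = NULL, episodes = NULL) {
  structure(list(
    client_id = client_id,
    enrollment_start = as.Date(enrollment_start),
    enrollment_end = as.Date(enrollment_end),
    series = series,
    steps = steps %||% tibble::tibble(date = as.Date(character()),
                                      steps = numeric()),
    view_events = view_events %||% tibble::tibble(date = as.Date(character()),
                                                  target = character(),
                                                  tip_id = character()),
    feedback_events = feedback_events %||% empty_events(),
    episodes = episodes %||% empty_episodes()
  ), class = "client_log")
}

clip_period <- function(log, period = NULL) {
  period <- as.Date(period %||% c(log$enrollment_start, log$enrollment_end))
  c(max(period[1], log$enrollment_start), min(period[2], log$enrollment_end))
}

#' Usage report
#'
#' Engagement summary over a period: days enrolled, days with weight
#' and step data (retained observations only) and their percentages,
#' graph views, and per-tip view counts.
#'
#' @param log A [client_log()].
#' @param period Optional `c(start, end)` `Date` pair (clipped to the
#'   enrollment window, inclusive day counting).
#' @return A `usage_report` list.
#' @export
usage_report <- function(log, period = NULL) {
  pd <- clip_period(log, period)
  days <- max(0L, as.integer(pd[2] - pd[1]) + 1L)
  in_pd <- function(d) d >= pd[1] & d <= pd[2]
  obs <- retained_observations(log$series)
  days_weight <- length(unique(obs$date[in_pd(obs$date)]))
  st <- collapse_steps(log$steps)
  days_steps <- length(unique(st$date[in_pd(st$date)]))
  ve <- log$view_events[in_pd(log$view_events$date), ]
  tips <- ve[ve$target == "tip", ]
  tip_counts <- if (nrow(tips)) {
    tc <- table(tips$tip_id)
    tibble::tibble(tip_id = names(tc), views = as.integer(tc))
  } else tibble::tibble(tip_id = character(), views = integer())
  pct <- function(k) if (days > 0) round_half_up(100 * k / days) else 0
  structure(list(
    client_id = log$client_id, period_start = pd[1], period_end = pd[2],
    days_enrolled = days, days_with_weight = days_weight,
    days_with_steps = days_steps,
    pct_days_with_weight = pct(days_weight),
    pct_days_with_steps = pct(days_steps),
    weight_graph_views = sum(ve$target == "weight_graph"),
    step_graph_views = sum(ve$target == "step_graph"),
    tips_viewed = tip_counts
  ), class = "usage_report")
}

#' Outcome report
#'
#' Weight change over a period (pounds and percent, last minus first
#' retained weight), the target weight and zone bounds at period end,
#' and the partition of enrolled days into in / below / above zone /
#' no data.
#'
#' @param log A [client_log()].
#' @param zone An [build_zone()] zone with dates.
#' @param period Optional `c(start, end)` `Date` pair.
#' @return An `outcome_report` list.
#' @export
outcome_report <- function(log, zone, period = NULL) {
  pd <- clip_period(log, period)
  days <- max(0L, as.integer(pd[2] - pd[1]) + 1L)
  obs <- retained_observations(log$series)
  obs <- obs[obs$date >= pd[1] & obs$date <= pd[2], ]
  if (nrow(obs) == 0)
    abort_wrx("no retained weights in the period", "weightrx_invalid_input")
  first_w <- obs$weight_kg[which.min(obs$date)]
  last_w <- obs$weight_kg[which.max(obs$date)]
  change_lb <- kg_to_lb(last_w - first_w)
  change_pct <- round_half_up(100 * (last_w - first_w) / first_w)
  zdate <- zone_dates(zone, log$series)
  all_days <- seq(pd[1], pd[2], by = "day")
  zi <- match(all_days, zdate)
  wi <- obs$weight_kg[match(all_days, obs$date)]
  pos <- ifelse(is.na(wi) | is.na(zi), "no_data",
         ifelse(wi > zone$upper_kg[zi], "above",
         ifelse(wi < zone$lower_kg[zi], "below", "in")))
  cnt <- function(s) sum(pos == s)
  zend <- zi[length(zi)]
  pct <- function(k) if (days > 0) round_half_up(100 * k / days) else 0
  structure(list(
    client_id = log$client_id, period_start = pd[1], period_end = pd[2],
    days_enrolled = days,
    first_weight_lb = kg_to_lb(first_w), last_weight_lb = kg_to_lb(last_w),
    change_lb = change_lb, change_pct = change_pct,
    target_weight_lb = if (!is.na(zend)) kg_to_lb(zone$predicted_kg[zend]) else NA_real_,
    target_lower_lb = if (!is.na(zend)) kg_to_lb(zone$lower_kg[zend]) else NA_real_,
    target_upper_lb = if (!is.na(zend)) kg_to_lb(zone$upper_kg[zend]) else NA_real_,
    days_in_zone = cnt("in"), days_below_zone = cnt("below"),
    days_above_zone = cnt("above"), days_no_data = cnt("no_data"),
    pct_in_zone = pct(cnt("in")), pct_below_zone = pct(cnt("below")),
    pct_above_zone = pct(cnt("above"))
  ), class = "outcome_report")
}

#' Toolbox report
#'
#' Per-strategy usage counts plus, for each episode, the weight change
#' and mean daily steps during the episode.
#'
#' @param log A [client_log()] whose `episodes` field is populated.
#' @return A `toolbox_report` list with `strategy_usage` and
#'   `episode_detail` tibbles.
#' @export
toolbox_report <- function(log) {
  eps <- log$episodes
  usage <- if (nrow(eps)) {
    tc <- table(eps$strategy_id)
    tibble::tibble(strategy_id = names(tc), episodes = as.integer(tc))
  } else tibble::tibble(strategy_id = character(), episodes = integer())
  obs <- retained_observations(log$series)
  st <- collapse_steps(log$steps)
  detail <- lapply(seq_len(nrow(eps)), function(i) {
    s <- as.Date(eps$start_date[i])
    e <- s + eps$window[i]
    o <- obs[obs$date >= s & obs$date <= e, ]
    k <- st$steps[st$date >= s & st$date <= e]
    tibble::tibble(
      strategy_id = eps$strategy_id[i], start_date = s, end_date = e,
      status = eps$status[i],
      weight_change_lb = if (nrow(o) >= 2)
        kg_to_lb(o$weight_kg[which.max(o$date)] - o$weight_kg[which.min(o$date)])
        else NA_real_,
      mean_daily_steps = if (length(k)) mean(k) else NA_real_)
  })
  structure(list(client_id = log$client_id, strategy_usage = usage,
                 episode_detail = dplyr::bind_rows(detail)),
            class = "toolbox_report")
}

#' Group (clinic-level) report
#'
#' Per-client outcome/usage rows plus mean and median aggregates of
#' the headline numbers.
#'
#' @param logs List of [client_log()]s.
#' @param zones List of matching zones (same order).
#' @param period Optional `c(start, end)` `Date` pair.
#' @return A `group_report` list with `clients` (one row per client)
#'   and `aggregates` (rows `mean` and `median`).
#' @export
group_report <- function(logs, zones, period = NULL) {
  if (length(logs) == 0)
    abort_wrx("need at least one client", "weightrx_invalid_input")
  rows <- lapply(seq_along(logs), function(i) {
    o <- outcome_report(logs[[i]], zones[[i]], period)
    u <- usage_report(logs[[i]], period)
    tibble::tibble(
      client_id = o$client_id, days_enrolled = o$days_enrolled,
      pct_days_with_weight = u$pct_days_with_weight,
      change_lb = o$change_lb, change_pct = o$change_pct,
      pct_in_zone = o$pct_in_zone)
  })
  clients <- dplyr::bind_rows(rows)
  num <- c("days_enrolled", "pct_days_with_weight", "change_lb",
           "change_pct", "pct_in_zone")
  agg <- tibble::tibble(
    statistic = c("mean", "median"))
  for (v in num) {
    agg[[v]] <- c(mean(clients[[v]]), median(clients[[v]]))
  }
  structure(list(clients = clients, aggregates = agg),
            class = "group_report")
}

#' Export a report as CSV or JSON
#'
#' Scalar fields become one row (CSV) or one object (JSON); nested
#' tibbles are written alongside (CSV) or inline (JSON).
#'
#' @param report A usage/outcome/toolbox/group report.
#' @param path Output file; extension picks the format (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(prep_report(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    flat <- prep_report(report)
    scal <- flat[!vapply(flat, is.data.frame, TRUE)]
    write.csv(as.data.frame(scal, stringsAsFactors = FALSE), path,
              row.names = FALSE, na = "")
    nested <- flat[vapply(flat, is.data.frame, TRUE)]
    for (nm in names(nested)) {
      write.csv(nested[[nm]], sub("\\.csv$", sprintf("_%s.csv", nm), path),
                row.names = FALSE, na = "")
    }
  }
  invisible(path)
}

prep_report <- function(report) {
  x <- unclass(report)
  lapply(x, function(v) {
    if (inherits(v, "Date")) format(v)
    else if (tibble::is_tibble(v)) as.data.frame(v)
    else v
  })
}

#' Dump raw client data to flat files
#'
#' Honors "raw data can be downloaded": writes the cleaned weight
#' series, step records, view events, feedback events and episodes of
#' a client log as plain CSV/JSONL files in a directory.
#'
#' @param log A [client_log()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
dump_raw_data <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_weight_series(log$series, file.path(dir, "weights.csv"))
  write.csv(as.data.frame(log$steps), file.path(dir, "steps.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(log$view_events), file.path(dir, "view_events.csv"),
            row.names = FALSE)
  write_events_jsonl(log$feedback_events, file.path(dir, "feedback_events.jsonl"))
  write.csv(as.data.frame(log$episodes), file.path(dir, "episodes.csv"),
            row.names = FALSE)
  invisible(dir)
}
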