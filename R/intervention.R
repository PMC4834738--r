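#' Toolbox strategy catalogue
#'
#' Ordered catalogue of behavioral intervention strategies, deployed
#' least-intense-first when adherence fails.  The default seeds the
#' classic options: a food-intake self-monitoring plan, increased
#' activity, portion-controlled foods, and increased contact frequency
#' with the clinician.  A clinic supplies its own catalogue as YAML
#' (a list of `id`, `label`, `intensity_rank`, `cost_tier` entries).
#'
#' @param path Optional YAML file to load instead of the default.
#' @return Tibble with columns `id`, `label`, `intensity_rank`
#'   (1 = least intense, unique), `cost_tier`.
#' @export
toolbox_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    cat <- tibble::tibble(
      id = c("self_monitoring", "increase_activity",
             "portion_controlled_foods", "increase_contact"),
      label = c("Adopt a food-intake self-monitoring plan",
                "Increase daily activity or exercise",
                "Use portion-controlled foods",
                "Increase contact frequency with clinician"),
      intensity_rank = 1:4,
      cost_tier = c("low", "low", "medium", "high")
    )
  } else {
    lst <- yaml::read_yaml(path)
    cat <- dplyr::bind_rows(lapply(lst, tibble::as_tibble))
  }
  if (anyDuplicated(cat$intensity_rank))
    abort_wrx("`intensity_rank` must be unique within a catalogue",
              "weightrx_invalid_config")
  cat[order(cat$intensity_rank), ]
}

empty_episodes <- function() {
  tibble::tibble(strategy_id = character(), start_date = as.Date(character()),
                 window = integer(), status = character(),
                 slope = numeric())
}

#' Select the next toolbox strategy
#'
#' Escalation is least-to-most intense within an "escalation run": the
#' episodes since the most recent success.  The chosen strategy is the
#' lowest `intensity_rank` not yet attempted-and-failed in the current
#' run; a success resets the run, so a later trigger starts again from
#' the cheapest remedy.  When every strategy in the run has failed the
#' function returns `NULL` and signals a warning of class
#' `weightrx_escalation_exhausted` (clinician referral).
#'
#' @param catalogue A [toolbox_catalogue()].
#' @param episodes Episode history tibble (`strategy_id`, `start_date`,
#'   `window`, `status`, `slope`), ordered by start date.
#' @return One-row tibble from the catalogue, or `NULL` if exhausted.
#' @export
next_strategy <- function(catalogue, episodes = empty_episodes()) {
  failed <- character()
  if (nrow(episodes)) {
    closed <- episodes[episodes$status %in% c("success", "failure"), ]
    last_success <- max(c(0L, which(closed$status == "success")))
    run <- closed[seq_len(nrow(closed)) > last_success, ]
    failed <- run$strategy_id[run$status == "failure"]
  }
  open <- catalogue[!(catalogue$id %in% failed), ]
  if (nrow(open) == 0) {
    warning(warningCondition(
      "toolbox exhausted: all strategies failed in this escalation run",
      class = "weightrx_escalation_exhausted"))
    return(NULL)
  }
  open[which.min(open$intensity_rank), ]
}

#' Evaluate a toolbox episode
#'
#' After the evaluation window (default 14 days) has elapsed, the
#' episode is a success if improvement occurred: the weight on the last
#' observed episode day is back inside the zone, or the least-squares
#' weight slope over the episode is at least as steep (down) as the
#' predicted slope over the same days.  Otherwise it is a failure.
#' With fewer than `min_points` retained weights in the window the
#' evaluation is deferred (`"deferred"`) and the episode extends.
#'
#' @param episode One-row episode tibble (`strategy_id`, `start_date`,
#'   `window`).
#' @param series A `weight_series`.
#' @param zone An [build_zone()] zone (with dates).
#' @param min_points Minimum retained weights required.
#' @return List with `status` (`"success"`, `"failure"` or
#'   `"deferred"`) and `slope` (observed episode slope, kg/day).
#' @export
evaluate_episode <- function(episode, series, zone, min_points = 3L) {
  start <- as.Date(episode$start_date)
  end <- start + episode$window
  obs <- retained_observations(series)
  obs <- obs[obs$date >= start & obs$date <= end, ]
  if (nrow(obs) < min_points)
    return(list(status = "deferred", slope = NA_real_))
  slope <- ls_fit(as.numeric(obs$date), obs$weight_kg)$slope
  zdate <- zone_dates(zone, series)
  zsel <- zdate >= start & zdate <= end
  pred_slope <- ls_fit(as.numeric(zdate[zsel]), zone$predicted_kg[zsel])$slope
  last_date <- max(obs$date)
  zi <- match(last_date, zdate)
  back_in_zone <- !is.na(zi) &&
    obs$weight_kg[obs$date == last_date] >= zone$lower_kg[zi] &&
    obs$weight_kg[obs$date == last_date] <= zone$upper_kg[zi]
  status <- if (back_in_zone || (is.finite(pred_slope) && slope <= pred_slope))
    "success" else "failure"
  list(status = status, slope = slope)
}

#' Schedule tip deliveries
#'
#' Health-education tips are delivered on a cadence that starts weekly
#' and tapers off (biweekly, then monthly) as the program progresses.
#' Phases are configured as week ranges with a cadence each; deliveries
#' fall at the cadence interval from the start of each phase.
#'
#' @param start_date Program start `Date`.
#' @param phases Tibble/data frame with columns `start_week`,
#'   `end_week` (1-based, inclusive) and `cadence` (`"weekly"`,
#'   `"biweekly"` or `"monthly"`).
#' @param tip_ids Optional character vector of tip identifiers cycled
#'   over the deliveries.
#' @return A `tip_schedule` tibble: `tip_id`, `delivery_date`, `phase`,
#'   `viewed_at`, `acknowledged_at` (both `NA` until tracked).
#' @examples
#' ph <- tibble::tibble(start_week = c(1, 9, 17), end_week = c(8, 16, 24),
#'                      cadence = c("weekly", "biweekly", "monthly"))
#' nrow(schedule_tips(as.Date("2026-01-05"), ph)) # 14
#' @export
schedule_tips <- function(start_date,
                          phases = tibble::tibble(
                            start_week = c(1, 9, 17), end_week = c(8, 16, 24),
                            cadence = c("weekly", "biweekly", "monthly")),
                          tip_ids = NULL) {
  start_date <- as.Date(start_date)
  step <- c(weekly = 7, biweekly = 14, monthly = 28)
  days <- integer()
  phase <- integer()
  for (i in seq_len(nrow(phases))) {
    if (!phases$cadence[i] %in% names(step))
      abort_wrx("cadence must be weekly, biweekly or monthly",
                "weightrx_invalid_config")
    d0 <- (phases$start_week[i] - 1) * 7
    d1 <- phases$end_week[i] * 7 - 1
    if (d1 < d0) next
    dd <- seq(d0, d1, by = step[[phases$cadence[i]]])
    days <- c(days, dd)
    phase <- c(phase, rep(i, length(dd)))
  }
  n <- length(days)
  ids <- tip_ids %||% sprintf("tip_%02d", seq_len(max(n, 1)))
  out <- tibble::tibble(
    tip_id = rep_len(ids, n)[seq_len(n)],
    delivery_date = start_date + days,
    phase = phase,
    viewed_at = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01"),
    acknowledged_at = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01")
  )
  structure(out, class = c("tip_schedule", class(out)))
}

#' Record a tip view / acknowledgment
#'
#' @param schedule A [schedule_tips()] result.
#' @param tip_id Tip to mark.
#' @param at Timestamp.
#' @param acknowledged Whether the client also acknowledged the content.
#' @return The updated schedule.
#' @export
mark_tip_viewed <- function(schedule, tip_id, at = Sys.time(),
                            acknowledged = FALSE) {
  i <- which(schedule$tip_id == tip_id)[1]
  if (is.na(i))
    abort_wrx("unknown tip_id", "weightrx_invalid_input")
  schedule$viewed_at[i] <- at
  if (acknowledged) schedule$acknowledged_at[i] <- at
  schedule
}

feedback_templates <- function() {
  list(
    congratulatory = "Great work - your weight is right on track inside your zone.",
    tip = "Tip: keep your routine going; consistency drives long-term success.",
    toolbox_recommendation = "Your weight has been outside the zone for several days. Recommended next step: %s.",
    reminder = "We have not received a weight in %d days - step on the scale tomorrow morning.",
    clinician_custom = "Please contact your clinician: all toolbox strategies have been attempted."
  )
}

empty_events <- function() {
  tibble::tibble(date = as.Date(character()), kind = character(),
                 payload = character(), trigger = character())
}

#' Generate automated feedback events
#'
#' Deterministic template-based feedback:
#' * a `GREEN` flag yields a congratulatory message plus a tip;
#' * a fired out-of-zone trigger yields a toolbox recommendation;
#' * a missing-weight streak at the reminder threshold yields a
#'   reminder.
#'
#' Every event records its trigger provenance.  Payloads come from the
#' template catalogue only.
#'
#' @param date Event `Date`.
#' @param flag Optional flag state for the date.
#' @param trigger_fired Whether the k-of-n trigger fired.
#' @param strategy_label Label of the recommended strategy (for the
#'   toolbox recommendation payload).
#' @param no_data_streak Current consecutive missing-weight days.
#' @param reminder_after Streak length at which a reminder is sent.
#' @param templates Template catalogue (named list of strings).
#' @return Tibble of events (`date`, `kind`, `payload`, `trigger`);
#'   possibly zero rows.
#' @export
generate_feedback <- function(date, flag = NULL, trigger_fired = FALSE,
                              strategy_label = NULL, no_data_streak = 0,
                              reminder_after = 3,
                              templates = feedback_templates()) {
  date <- as.Date(date)
  ev <- list()
  if (!is.null(flag) && identical(flag, "GREEN")) {
    ev <- c(ev, list(
      tibble::tibble(date = date, kind = "congratulatory",
                     payload = templates$congratulatory,
                     trigger = "flag:GREEN"),
      tibble::tibble(date = date, kind = "tip", payload = templates$tip,
                     trigger = "flag:GREEN")))
  }
  if (trigger_fired) {
    payload <- if (is.null(strategy_label))
      templates$clinician_custom
    else sprintf(templates$toolbox_recommendation, strategy_label)
    kind <- if (is.null(strategy_label)) "clinician_custom"
            else "toolbox_recommendation"
    ev <- c(ev, list(tibble::tibble(date = date, kind = kind,
                                    payload = payload,
                                    trigger = "trigger:out_of_zone")))
  }
  if (no_data_streak >= reminder_after &&
      no_data_streak %% reminder_after == 0) {
    ev <- c(ev, list(tibble::tibble(
      date = date, kind = "reminder",
      payload = sprintf(templates$reminder, no_data_streak),
      trigger = sprintf("no_data_streak:%d", no_data_streak))))
  }
  if (length(ev) == 0) return(empty_events())
  dplyr::bind_rows(ev)
}

#' Write / read an event log as JSON lines
#'
#' One JSON object per line; round-trips exactly.
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `write_events_jsonl()` returns `path` invisibly;
#'   `read_events_jsonl()` returns the event tibble.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    row <- as.list(events[i, ])
    row$date <- format(row$date)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_events())
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x$date <- as.Date(x$date)
    tibble::as_tibble(x)
  })
  dplyr::bind_rows(rows)
}
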