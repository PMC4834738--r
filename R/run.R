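#' Program configuration
#'
#' Central place for every tunable the program exposes: model
#' parameters, band spec, flag cutoffs, trigger (k of n), episode
#' window, reminder threshold and tip phases.  Loadable from YAML so a
#' clinic's choices live in one audited file.
#'
#' @param params A [model_params()].
#' @param band A [band_spec()].
#' @param flags A [flag_config()].
#' @param trigger_k,trigger_n k-of-n out-of-zone trigger.
#' @param trigger_states Flag states counted toward the trigger.
#' @param episode_window Toolbox evaluation window, days.
#' @param reminder_after Missing-weight days before a reminder.
#' @param step_increment Steps/day added to baseline for the goal.
#' @param tip_phases Tip cadence phases (see [schedule_tips()]).
#' @param catalogue A [toolbox_catalogue()].
#' @return A `program_config` list.
#' @export
program_config <- function(params = model_params(), band = band_spec(),
                           flags = flag_config(), trigger_k = 3L,
                           trigger_n = 5L, trigger_states = "RED",
                           episode_window = 14L, reminder_after = 3L,
                           step_increment = 3000,
                           tip_phases = tibble::tibble(
                             start_week = c(1, 9, 17),
                             end_week = c(8, 16, 24),
                             cadence = c("weekly", "biweekly", "monthly")),
                           catalogue = toolbox_catalogue()) {
  if (trigger_k < 1 || trigger_n < trigger_k)
    abort_wrx("need trigger_n >= trigger_k >= 1", "weightrx_invalid_config")
  if (episode_window < 1)
    abort_wrx("`episode_window` must be >= 1 day", "weightrx_invalid_config")
  structure(list(params = params, band = band, flags = flags,
                 trigger_k = as.integer(trigger_k),
                 trigger_n = as.integer(trigger_n),
                 trigger_states = trigger_states,
                 episode_window = as.integer(episode_window),
                 reminder_after = as.integer(reminder_after),
                 step_increment = step_increment,
                 tip_phases = tip_phases, catalogue = catalogue),
            class = "program_config")
}

#' Read a program configuration from YAML
#'
#' Unknown keys raise an error naming the offending key, so a typo in a
#' clinic config cannot silently fall back to a default.
#'
#' @param path YAML file.
#' @return A [program_config()].
#' @export
read_program_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("params", "band", "flags", "trigger_k", "trigger_n",
             "trigger_states", "episode_window", "reminder_after",
             "step_increment", "tip_phases", "catalogue_path")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort_wrx(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
              "weightrx_invalid_config")
  args <- list()
  if (!is.null(cfg$params)) {
    cfg$params$forbes_intercept <- unlist(cfg$params$forbes_intercept)
    if (!is.null(cfg$params$rmr_coef$intercept))
      cfg$params$rmr_coef$intercept <- unlist(cfg$params$rmr_coef$intercept)
    args$params <- do.call(model_params, cfg$params)
  }
  if (!is.null(cfg$band)) args$band <- do.call(band_spec, cfg$band)
  if (!is.null(cfg$flags)) args$flags <- do.call(flag_config, cfg$flags)
  if (!is.null(cfg$tip_phases))
    args$tip_phases <- dplyr::bind_rows(lapply(cfg$tip_phases,
                                               tibble::as_tibble))
  if (!is.null(cfg$catalogue_path))
    args$catalogue <- toolbox_catalogue(cfg$catalogue_path)
  for (k in c("trigger_k", "trigger_n", "trigger_states",
              "episode_window", "reminder_after", "step_increment"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(program_config, args)
}

#' Run the daily update loop for one client
#'
#' The end-to-end engine: for each date from baseline to the end of
#' the observed telemetry it classifies the daily flag, evaluates the
#' k-of-n out-of-zone trigger, opens/evaluates toolbox episodes
#' (least-intense-first, one active episode at a time, escalation run
#' resets after a success), and emits feedback events (congratulation +
#' tip on green days, toolbox recommendations, missing-weight
#' reminders, clinician referral when the toolbox is exhausted).
#' Deterministic: identical inputs give an identical event stream.
#'
#' @param profile A [client_profile()].
#' @param rx An [energy_prescription()].
#' @param series A cleaned `weight_series` ([ingest()] +
#'   [filter_outliers()]).
#' @param config A [program_config()].
#' @param steps Optional step records.
#' @param view_events Optional view-event tibble.
#' @param client_id Identifier.
#' @return A `program_run` list: `trajectory`, `zone`, `flags`,
#'   `events`, `episodes`, `tip_schedule`, `log` (a [client_log()]).
#' @export
run_program <- function(profile, rx, series, config = program_config(),
                        steps = NULL, view_events = NULL,
                        client_id = attr(series, "client_id") %||% "client") {
  baseline_date <- as.Date(attr(series, "baseline_date"))
  traj <- predict_trajectory(profile, rx, config$params)
  zone <- build_zone(traj, config$band, baseline_date)
  obs <- retained_observations(series)
  last_date <- if (nrow(obs)) max(obs$date) else baseline_date
  dates <- seq(baseline_date, min(last_date, max(zone$date)), by = "day")

  flags <- character(0)
  flag_rows <- vector("list", length(dates))
  events <- list()
  episodes <- empty_episodes()
  active <- NULL
  exhausted <- FALSE
  streak <- 0L

  for (i in seq_along(dates)) {
    d <- dates[i]
    fr <- classify_flag(series, zone, d, config$flags)
    flag_rows[[i]] <- fr
    flags <- c(flags, fr$flag)
    streak <- if (fr$flag == "NO_DATA") streak + 1L else 0L

    # evaluate an elapsed episode
    if (!is.null(active) && d >= active$start_date + active$window) {
      ev <- evaluate_episode(active, series, zone)
      if (ev$status != "deferred") {
        episodes <- dplyr::bind_rows(episodes, tibble::tibble(
          strategy_id = active$strategy_id,
          start_date = active$start_date, window = active$window,
          status = ev$status, slope = ev$slope))
        if (ev$status == "success") exhausted <- FALSE
        active <- NULL
      } else {
        active$window <- active$window + 1L  # extend until enough data
      }
    }

    fired <- trigger_check(flags, config$trigger_k, config$trigger_n,
                           config$trigger_states)
    strategy_label <- NULL
    announce <- FALSE
    if (fired && is.null(active) && !exhausted) {
      strat <- withCallingHandlers(
        next_strategy(config$catalogue, episodes),
        weightrx_escalation_exhausted = function(w)
          invokeRestart("muffleWarning"))
      if (is.null(strat)) {
        exhausted <- TRUE
        announce <- TRUE  # clinician referral event
      } else {
        active <- list(strategy_id = strat$id, start_date = d,
                       window = config$episode_window)
        strategy_label <- strat$label
        announce <- TRUE
      }
    }
    ev <- generate_feedback(d, flag = fr$flag,
                            trigger_fired = announce,
                            strategy_label = strategy_label,
                            no_data_streak = streak,
                            reminder_after = config$reminder_after)
    if (nrow(ev)) events <- c(events, list(ev))
  }
  if (!is.null(active)) {
    episodes <- dplyr::bind_rows(episodes, tibble::tibble(
      strategy_id = active$strategy_id, start_date = active$start_date,
      window = active$window, status = "active", slope = NA_real_))
  }

  events <- if (length(events)) dplyr::bind_rows(events) else empty_events()
  tips <- schedule_tips(baseline_date, config$tip_phases)
  log <- client_log(client_id, baseline_date, max(dates), series,
                    steps = steps, view_events = view_events,
                    feedback_events = events, episodes = episodes)
  structure(list(trajectory = traj, zone = zone,
                 flags = dplyr::bind_rows(flag_rows), events = events,
                 episodes = episodes, tip_schedule = tips, log = log),
            class = "program_run")
}
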