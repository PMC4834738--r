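#' Behavior profile for a synthetic client
#'
#' Controls how a simulated client's telemetry deviates from the model
#' prediction:
#' * `adherence` — fraction of the prescribed intake change actually
#'   achieved (1 = fully adherent, 0 = stays at maintenance);
#' * `noise_sd` — Gaussian day-to-day weight noise, kg (hydration,
#'   clothing); default 0.3 kg;
#' * `missing_prob` — probability a day has no weight record;
#' * `foreign_prob` — probability the day's record is a foreign weight
#'   (someone else on the scale), offset by at least `foreign_min`
#'   (relative) so ground truth for the +/-5 % filter is unambiguous;
#' * `duplicate_prob` — probability of an extra evening record (to
#'   exercise the first-of-day rule);
#' * `step_mean`, `step_sd` — daily step distribution;
#' * `lapses` — data frame of lapse episodes (`start` day, `length`
#'   days, `excess` kcal/day added to intake).
#'
#' @param adherence Fraction in `[0, 1]` (values above 1 allowed for
#'   over-compliance).
#' @param noise_sd Weight noise sd, kg (>= 0).
#' @param missing_prob,foreign_prob,duplicate_prob Probabilities.
#' @param foreign_min,foreign_max Relative offset range of foreign
#'   weights (default 6-15 %, always beyond the 5 % filter).
#' @param step_mean,step_sd Steps/day distribution.
#' @param lapses Data frame (`start`, `length`, `excess`) or `NULL`.
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(adherence = 1, noise_sd = 0.3,
                             missing_prob = 0, foreign_prob = 0,
                             duplicate_prob = 0, foreign_min = 0.06,
                             foreign_max = 0.15, step_mean = 6500,
                             step_sd = 1500, lapses = NULL) {
  for (p in c(missing_prob, foreign_prob, duplicate_prob))
    if (p < 0 || p > 1)
      abort_wrx("probabilities must be in [0, 1]", "weightrx_invalid_config")
  if (noise_sd < 0)
    abort_wrx("`noise_sd` must be >= 0", "weightrx_invalid_config")
  if (foreign_min < 0.06)
    abort_wrx("`foreign_min` must be >= 0.06 so foreign weights are unambiguous",
              "weightrx_invalid_config")
  structure(list(adherence = adherence, noise_sd = noise_sd,
                 missing_prob = missing_prob, foreign_prob = foreign_prob,
                 duplicate_prob = duplicate_prob, foreign_min = foreign_min,
                 foreign_max = foreign_max, step_mean = step_mean,
                 step_sd = step_sd, lapses = lapses),
            class = "behavior_profile")
}

#' Simulate a client's telemetry
#'
#' Generates raw weight records, step records and UI view events for a
#' synthetic client.  The true weight follows the forward model under
#' an effective intake of `maintenance + adherence * delta` (plus any
#' lapse excess); observations add Gaussian noise, days are dropped
#' according to the missingness probability, and foreign weights are
#' injected with a >= 6 % offset.  Fully reproducible given `seed`.
#'
#' @param profile A [client_profile()].
#' @param rx An [energy_prescription()].
#' @param behavior A [behavior_profile()].
#' @param days Days of telemetry to generate (defaults to the
#'   prescription horizon).
#' @param seed Integer seed.
#' @param start_date `Date` of day 0.
#' @param params A [model_params()].
#' @return A `synthetic_client` list: `weights` (raw records:
#'   `timestamp`, `weight_kg`, `source`), `steps` (`date`, `steps`,
#'   `source`; two cumulative syncs per day), `view_events` (`date`,
#'   `target`, `tip_id`), and `truth` (the simulated true daily weights
#'   and effective intake).
#' @export
simulate_client <- function(profile, rx, behavior = behavior_profile(),
                            days = NULL, seed = 1L,
                            start_date = as.Date("2026-01-05"),
                            params = model_params()) {
  stopifnot(inherits(profile, "client_profile"),
            inherits(rx, "energy_prescription"),
            inherits(behavior, "behavior_profile"))
  days <- as.integer(days %||% rx$horizon)
  set.seed(as.integer(seed))
  start_date <- as.Date(start_date)

  intake <- rep(rx$maintenance_intake + behavior$adherence * rx$delta_intake,
                max(days, 1))
  if (!is.null(behavior$lapses) && nrow(behavior$lapses) > 0 && days > 0) {
    for (i in seq_len(nrow(behavior$lapses))) {
      l <- behavior$lapses[i, ]
      sel <- seq_len(days) - 1 >= l$start &
             seq_len(days) - 1 < l$start + l$length
      intake[sel] <- intake[sel] + l$excess
    }
  }
  state <- initial_composition(profile$weight_kg, profile$sex, params)
  truth <- simulate_compartments(state, intake, days, profile, params)

  dates <- start_date + truth$day
  n <- length(dates)
  missing <- rbinom(n, 1, behavior$missing_prob) == 1
  foreign <- rbinom(n, 1, behavior$foreign_prob) == 1
  dup <- rbinom(n, 1, behavior$duplicate_prob) == 1
  noise <- rnorm(n, 0, behavior$noise_sd)
  f_off <- runif(n, behavior$foreign_min, behavior$foreign_max) *
    sign(runif(n) - 0.5)
  obs_w <- truth$weight_kg + noise
  obs_w[foreign] <- truth$weight_kg[foreign] * (1 + f_off[foreign])

  keep <- !missing
  wts <- tibble::tibble(
    timestamp = as.POSIXct(paste(dates[keep], "07:10:00"), tz = "UTC"),
    weight_kg = obs_w[keep],
    source = "device")
  if (any(dup & keep)) {
    extra_dates <- dates[dup & keep]
    extra <- tibble::tibble(
      timestamp = as.POSIXct(paste(extra_dates, "20:30:00"), tz = "UTC"),
      weight_kg = truth$weight_kg[dup & keep] +
        rnorm(sum(dup & keep), 0, behavior$noise_sd) + 0.4,
      source = "device")
    wts <- dplyr::bind_rows(wts, extra)
    wts <- wts[order(wts$timestamp), ]
  }

  total <- pmax(0, round(rnorm(n, behavior$step_mean, behavior$step_sd)))
  st_missing <- rbinom(n, 1, behavior$missing_prob) == 1
  steps <- tibble::tibble(
    date = rep(dates, 2),
    steps = c(round(total * runif(n, 0.4, 0.7)), total),
    source = "device")[rep(!st_missing, 2), ]
  steps <- steps[order(steps$date), ]

  viewed <- rbinom(n, 1, 0.3) == 1
  view_events <- tibble::tibble(
    date = dates[viewed],
    target = sample(c("weight_graph", "step_graph", "tip"), sum(viewed),
                    replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  view_events$tip_id <- ifelse(view_events$target == "tip",
                               sprintf("tip_%02d", sample(1:14,
                                       nrow(view_events), replace = TRUE)),
                               NA_character_)

  structure(list(
    client_id = sprintf("synth_%04d", as.integer(seed)),
    start_date = start_date,
    weights = wts, steps = steps, view_events = view_events,
    truth = list(day = truth$day, weight_kg = truth$weight_kg,
                 intake_kcal = intake,
                 foreign_days = dates[foreign & keep],
                 missing_days = dates[missing])
  ), class = "synthetic_client")
}

#' Write a synthetic client's telemetry to disk
#'
#' Emits the exact dialects the readers accept: `weights.csv`
#' (timestamp/weight/unit/source, in lb), `weights.json` (device
#' payload), `steps.csv` and `view_events.csv`.
#'
#' @param client A [simulate_client()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_client_telemetry <- function(client, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- client$weights
  write.csv(data.frame(
    timestamp = format(w$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    weight = round(kg_to_lb(w$weight_kg), 2),
    unit = "lb", source = w$source), file.path(dir, "weights.csv"),
    row.names = FALSE)
  jsonlite::write_json(data.frame(
    device_id = "scale-0001",
    timestamp_ms = as.numeric(w$timestamp) * 1000,
    weight_g = round(w$weight_kg * 1000)), file.path(dir, "weights.json"),
    digits = NA)
  write.csv(as.data.frame(client$steps), file.path(dir, "steps.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(client$view_events),
            file.path(dir, "view_events.csv"), row.names = FALSE)
  invisible(dir)
}
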