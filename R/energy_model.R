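#' Maintenance energy requirement
#'
#' Total daily energy expenditure at which body weight is stable, for a
#' person at light-to-moderate activity: `pal * RMR / (1 - tef)`.
#' Solving intake = expenditure with expenditure =
#' `pal * RMR + tef * intake` gives this closed form.
#'
#' @param profile A [client_profile()].
#' @param params A [model_params()].
#' @return Maintenance intake, kcal/day.
#' @examples
#' p <- client_profile("female", 50, height_in = 65, weight_lb = 200)
#' maintenance_energy(p)
#' @export
maintenance_energy <- function(profile, params = model_params()) {
  stopifnot(inherits(profile, "client_profile"))
  rmr <- resting_metabolic_rate(profile$weight_kg, profile$height_cm,
                                profile$age, profile$sex, params)
  params$pal * rmr / (1 - params$tef)
}

# Instantaneous energy expenditure (kcal/day) at weight `w`, intake `I`,
# relative to the client's enrollment weight `w0` (the compensation term
# tracks cumulative weight change from baseline).
energy_expenditure <- function(w, intake, profile, params, w0 = profile$weight_kg) {
  rmr <- resting_metabolic_rate(w, profile$height_cm, profile$age,
                                profile$sex, params)
  params$pal * rmr + params$tef * intake + params$comp_per_kg * (w - w0)
}

# Core forward simulation of the two-compartment system
#   rho_ffm * dL/dt = p(F) * (I - E),  rho_fat * dF/dt = (1 - p(F)) * (I - E)
# from an explicit (fat, ffm) state.  `intake` is a scalar or a
# per-day vector (piecewise constant on integer days).  A third state
# accumulates the energy imbalance so mass/energy bookkeeping can be
# checked exactly.  Returns one row per integer day 0..days.
simulate_compartments <- function(state, intake, days, profile, params,
                                  w0 = profile$weight_kg) {
  days <- as.integer(days)
  if (days == 0) {
    return(tibble::tibble(day = 0L, fat_kg = state[[1]], ffm_kg = state[[2]],
                          weight_kg = state[[1]] + state[[2]],
                          cum_balance_kcal = 0))
  }
  iv <- if (length(intake) == 1) rep(intake, days) else intake
  if (length(iv) != days)
    abort_wrx("per-day intake must have one value per simulated day",
              "weightrx_invalid_prescription")

  rhs <- function(t, y, parms) {
    fat <- max(y[1], 1e-6)
    w <- fat + y[2]
    eb <- parms$intake - energy_expenditure(w, parms$intake, profile, params, w0)
    p <- partition_fraction(fat, params)
    list(c((1 - p) * eb / params$rho_fat, p * eb / params$rho_ffm, eb))
  }

  # integrate block-wise over runs of constant intake so the solver
  # never steps across an intake discontinuity
  blocks <- rle(iv)
  y <- c(state[[1]], state[[2]])
  t0 <- 0L
  cum0 <- 0
  rows <- vector("list", length(blocks$values))
  for (b in seq_along(blocks$values)) {
    len <- blocks$lengths[b]
    sol <- deSolve::ode(y = c(y, 0), times = seq(0, len), func = rhs,
                        parms = list(intake = blocks$values[b]),
                        method = "lsoda", rtol = 1e-9, atol = 1e-7)
    keep <- if (b == 1) seq_len(len + 1) else seq_len(len) + 1
    rows[[b]] <- tibble::tibble(
      day = t0 + sol[keep, 1],
      fat_kg = sol[keep, 2], ffm_kg = sol[keep, 3],
      cum_balance_kcal = cum0 + sol[keep, 4])
    last <- sol[nrow(sol), ]
    y <- c(last[[2]], last[[3]])
    cum0 <- cum0 + last[[4]]
    t0 <- t0 + len
  }
  out <- dplyr::bind_rows(rows)
  out$day <- as.integer(round(out$day))
  out$weight_kg <- out$fat_kg + out$ffm_kg
  out[, c("day", "fat_kg", "ffm_kg", "weight_kg", "cum_balance_kcal")]
}

#' Predict a weight-change trajectory
#'
#' Forward-simulates the two-compartment energy-balance model under a
#' constant prescribed intake, producing the predicted weight for every
#' day of the prescription horizon.  Day 0 is the baseline; with a
#' restriction the trajectory decelerates toward a new equilibrium
#' (plateau) as expenditure falls with weight.
#'
#' @param profile A [client_profile()].
#' @param rx An [energy_prescription()].
#' @param params A [model_params()].
#' @return A `weight_trajectory`: a tibble with columns `day`,
#'   `fat_kg`, `ffm_kg`, `weight_kg`, `weight_lb`, `cum_balance_kcal`,
#'   of length `horizon + 1`, with the inputs attached as attributes.
#' @examples
#' p <- client_profile("female", 50, height_in = 65, weight_lb = 200)
#' rx <- energy_prescription(maintenance_energy(p), -500, 365)
#' tr <- predict_trajectory(p, rx)
#' kg_to_lb(tr$weight_kg[1] - tr$weight_kg[366]) # ~17.4 lb
#' @export
predict_trajectory <- function(profile, rx, params = model_params()) {
  stopifnot(inherits(profile, "client_profile"),
            inherits(rx, "energy_prescription"))
  if (rx$prescribed_intake < 0)
    abort_wrx("prescribed intake must be >= 0", "weightrx_invalid_prescription")
  state <- initial_composition(profile$weight_kg, profile$sex, params)
  out <- simulate_compartments(state, rx$prescribed_intake, rx$horizon,
                               profile, params)
  out$weight_lb <- kg_to_lb(out$weight_kg)
  out <- out[, c("day", "fat_kg", "ffm_kg", "weight_kg", "weight_lb",
                 "cum_balance_kcal")]
  attr(out, "profile") <- profile
  attr(out, "rx") <- rx
  attr(out, "params") <- params
  class(out) <- c("weight_trajectory", class(out))
  out
}

#' Export a trajectory as CSV
#'
#' Columns: `day`, `date` (if a baseline date is given),
#' `predicted_weight_lb`, `predicted_weight_kg`.
#'
#' @param trajectory A [predict_trajectory()] result.
#' @param path Output file.
#' @param baseline_date Optional `Date` of day 0.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, baseline_date = NULL) {
  df <- data.frame(day = trajectory$day)
  if (!is.null(baseline_date))
    df$date <- as.Date(baseline_date) + trajectory$day
  df$predicted_weight_lb <- trajectory$weight_lb
  df$predicted_weight_kg <- trajectory$weight_kg
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Estimate energy intake from observed weights
#'
#' Inverts the forward model: over consecutive non-overlapping windows
#' of the day grid (default 14 days), finds the constant daily intake
#' whose simulated weight curve best fits the retained observations in
#' the window (least squares in weight space, one-dimensional bounded
#' minimization).  The model state is carried across windows: window 1
#' starts from the enrollment baseline composition, and each later
#' window starts from the previous window's fitted end state, so the
#' estimator behaves as a piecewise-constant-intake filter.
#'
#' Windows with fewer than 2 observations are skipped and flagged
#' (`skipped = TRUE`, intake `NA`); the state is advanced through them
#' at the last fitted intake (maintenance before any fit).
#'
#' @param profile A [client_profile()].
#' @param series A `weight_series` (see [ingest()]) or a data frame
#'   with columns `day` (integer offset from baseline) and `weight_kg`.
#' @param params A [model_params()].
#' @param window Window length, days.
#' @param bounds Search bounds relative to maintenance, kcal/day.
#' @param tol Optimizer tolerance on intake, kcal/day.
#' @return Tibble with one row per window: `window`, `start_day`,
#'   `end_day`, `n_obs`, `intake_kcal`, `delta_kcal` (intake minus
#'   maintenance), `skipped`.
#' @export
estimate_intake <- function(profile, series, params = model_params(),
                            window = 14L, bounds = c(-2500, 2500),
                            tol = 0.05) {
  stopifnot(inherits(profile, "client_profile"))
  obs <- if (inherits(series, "weight_series")) {
    retained_observations(series)[, c("day", "weight_kg")]
  } else {
    tibble::tibble(day = as.integer(series$day), weight_kg = series$weight_kg)
  }
  if (nrow(obs) == 0)
    abort_wrx("no retained observations to estimate from",
              "weightrx_invalid_series")
  window <- as.integer(window)
  im <- maintenance_energy(profile, params)
  lo <- max(0, im + bounds[1])
  hi <- im + bounds[2]
  state <- initial_composition(profile$weight_kg, profile$sex, params)
  starts <- seq(0L, max(obs$day), by = window)
  rows <- vector("list", length(starts))
  last_fit <- im
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + window, max(obs$day) + 1L)  # window covers days [s, e)
    span <- e - s
    wobs <- obs[obs$day >= s & obs$day < e, ]
    if (nrow(wobs) < 2) {
      fitted <- NA_real_
      # carry the last estimate through data gaps (maintenance if none)
      advance_intake <- last_fit
    } else {
      rel <- wobs$day - s
      sse <- function(intake) {
        sim <- simulate_compartments(state, intake, span, profile, params)
        sum((sim$weight_kg[rel + 1] - wobs$weight_kg)^2)
      }
      fitted <- optimize(sse, c(lo, hi), tol = tol)$minimum
      advance_intake <- fitted
      last_fit <- fitted
    }
    sim <- simulate_compartments(state, advance_intake, span, profile, params)
    state <- c(sim$fat_kg[span + 1], sim$ffm_kg[span + 1])
    rows[[i]] <- tibble::tibble(
      window = i, start_day = s, end_day = e - 1L, n_obs = nrow(wobs),
      intake_kcal = fitted, delta_kcal = fitted - im,
      skipped = is.na(fitted))
  }
  dplyr::bind_rows(rows)
}
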