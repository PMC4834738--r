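# Independent oracles: each re-derives the quantity it checks from the
# stated rules, sharing no code with the implementation under test.

# fixed-step Euler integration of the two-compartment system, written
# out from the model equations
euler_trajectory <- function(profile, intake, days, params = model_params(),
                             dt = 0.01) {
  co <- params$rmr_coef
  cc <- params$forbes_slope * params$rho_ffm / params$rho_fat
  w0 <- profile$weight_kg
  # invert ffm = slope*log(f) + intercept by bisection
  b <- params$forbes_intercept[[profile$sex]]
  f <- function(fat) fat + params$forbes_slope * log(fat) + b - w0
  lo <- 1e-6; hi <- w0
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  fat <- (lo + hi) / 2
  ffm <- w0 - fat
  nst <- round(days / dt)
  out <- numeric(days + 1)
  out[1] <- fat + ffm
  for (s in seq_len(nst)) {
    w <- fat + ffm
    rmr <- max(0, co$weight * w + co$height * profile$height_cm +
                 co$age * profile$age + co$intercept[[profile$sex]])
    e <- params$pal * rmr + params$tef * intake +
      params$comp_per_kg * (w - w0)
    eb <- intake - e
    p <- cc / (cc + fat)
    fat <- fat + dt * (1 - p) * eb / params$rho_fat
    ffm <- ffm + dt * p * eb / params$rho_ffm
    if (s %% round(1 / dt) == 0) out[round(s * dt) + 1] <- fat + ffm
  }
  out
}

# brute-force first-of-day + strict-5% cleaning over raw records
oracle_clean <- function(timestamps, weights_kg, threshold = 0.05) {
  ord <- order(timestamps)
  ts <- timestamps[ord]
  w <- weights_kg[ord]
  d <- as.Date(ts, tz = "UTC")
  status <- rep("retained", length(w))
  status[duplicated(d)] <- "duplicate_same_day"
  ref <- NA_real_
  for (i in seq_along(w)) {
    if (status[i] != "retained") next
    if (is.na(ref)) { ref <- w[i]; next }
    if (abs(w[i] - ref) / ref > threshold) status[i] <- "outlier_gt_5pct"
    else ref <- w[i]
  }
  tibble::tibble(date = d, weight_kg = w, status = status)
}

# independent flag re-derivation using lm() for the slopes
oracle_flag <- function(obs, zone, date, trail = 7, minp = 3,
                        edge = 0.2, conf = 0.95) {
  zi <- which(zone$date == date)
  lo <- zone$lower_kg[zi]; up <- zone$upper_kg[zi]
  w <- obs$weight_kg[obs$date == date]
  if (length(w) == 0) return("NO_DATA")
  win <- obs[obs$date >= date - (trail - 1) & obs$date <= date, ]
  slope <- NA_real_; se <- NA_real_; psl <- NA_real_
  if (nrow(win) >= minp) {
    fit <- stats::lm(weight_kg ~ as.numeric(date), data = win)
    slope <- unname(stats::coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    zwin <- zone[zone$date >= date - (trail - 1) & zone$date <= date, ]
    psl <- unname(stats::coef(
      stats::lm(predicted_kg ~ as.numeric(date), data = zwin))[2])
  }
  if (w >= lo && w <= up) {
    plateau <- !is.na(slope) && psl < 0 &&
      (if (is.na(se) || se < 1e-12) slope >= 0
       else slope / se >= stats::qt(conf, nrow(win) - 2))
    near <- up > lo && w > up - edge * (up - lo)
    if (plateau || near) "GREEN_YELLOW" else "GREEN"
  } else if (w > up) {
    if (!is.na(slope) && !is.na(psl) && slope <= psl) "RED_GREEN" else "RED"
  } else "RED"
}
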