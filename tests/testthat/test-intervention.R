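ep_row <- function(id, status, start = as.Date("2026-01-05")) {
  tibble::tibble(strategy_id = id, start_date = start, window = 14L,
                 status = status, slope = NA_real_)
}

test_that("escalation picks the least intense strategy not yet failed, resetting on success", {
  cat <- toolbox_catalogue()
  expect_equal(next_strategy(cat)$intensity_rank, 1)
  h1 <- ep_row(cat$id[1], "failure")
  expect_equal(next_strategy(cat, h1)$intensity_rank, 2)
  # success resets the run: a later trigger starts from rank 1 again
  h2 <- dplyr::bind_rows(h1, ep_row(cat$id[2], "success"))
  expect_equal(next_strategy(cat, h2)$intensity_rank, 1)
  # within one run, ranks strictly escalate
  h3 <- dplyr::bind_rows(lapply(cat$id[1:3], ep_row, status = "failure"))
  expect_equal(next_strategy(cat, h3)$intensity_rank, 4)
  # exhausted catalogue signals a clinician referral
  h4 <- dplyr::bind_rows(lapply(cat$id, ep_row, status = "failure"))
  expect_warning(res <- next_strategy(cat, h4),
                 class = "weightrx_escalation_exhausted")
  expect_null(res)
})

test_that("catalogues load from YAML and reject duplicate ranks", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(id = "a", label = "A", intensity_rank = 2L, cost_tier = "low"),
    list(id = "b", label = "B", intensity_rank = 1L, cost_tier = "high")), f)
  cat <- toolbox_catalogue(f)
  expect_equal(cat$id, c("b", "a"))  # ordered by intensity
  yaml::write_yaml(list(
    list(id = "a", label = "A", intensity_rank = 1L, cost_tier = "low"),
    list(id = "b", label = "B", intensity_rank = 1L, cost_tier = "high")), f)
  expect_error(toolbox_catalogue(f), class = "weightrx_invalid_config")
})

test_that("episode evaluation: back in zone or adherent slope means success", {
  z <- build_zone(make_traj(90 - 0.05 * (0:29)), band_spec("absolute_kg", 1),
                  baseline_date = as.Date("2026-01-05"))
  ep <- tibble::tibble(strategy_id = "self_monitoring",
                       start_date = z$date[1], window = 14L)
  # re-enters the zone by the last episode day -> success
  w_in <- seq(z$upper_kg[1] + 1.2, z$predicted_kg[15], length.out = 15)
  s_in <- make_series(z$date[1:15], w_in)
  expect_equal(evaluate_episode(ep, s_in, z)$status, "success")
  # flat above the zone while prediction declines -> failure
  s_flat <- make_series(z$date[1:15], rep(z$upper_kg[1] + 1.2, 15))
  expect_equal(evaluate_episode(ep, s_flat, z)$status, "failure")
  # fewer than 3 weights -> deferred
  s_few <- make_series(z$date[c(1, 15)], rep(z$upper_kg[1] + 1.2, 2))
  expect_equal(evaluate_episode(ep, s_few, z)$status, "deferred")
})

test_that("episode slope criterion matches an independent least-squares fit", {
  set.seed(23)
  bdate <- as.Date("2026-01-05")
  for (i in 1:200) {
    pslope <- runif(1, -0.08, -0.01)
    z <- build_zone(make_traj(runif(1, 80, 100) + pslope * (0:20)),
                    band_spec("absolute_kg", runif(1, 0.5, 1.5)),
                    baseline_date = bdate)
    keep <- runif(15) > 0.2
    keep[c(1, 15)] <- TRUE
    w <- z$upper_kg[1:15] + runif(1, 0.3, 2) + runif(1, -0.15, 0.05) * (0:14) +
      rnorm(15, 0, 0.25)
    s <- make_series(z$date[1:15][keep], w[keep], baseline_date = bdate)
    ep <- tibble::tibble(strategy_id = "x", start_date = bdate, window = 14L)
    got <- evaluate_episode(ep, s, z)
    obs <- retained_observations(s)
    fit <- stats::lm(weight_kg ~ as.numeric(date), data = obs)
    zi <- match(max(obs$date), z$date)
    back_in <- obs$weight_kg[which.max(obs$date)] <= z$upper_kg[zi] &&
      obs$weight_kg[which.max(obs$date)] >= z$lower_kg[zi]
    zwin <- z[z$date >= bdate & z$date <= bdate + 14, ]
    pfit <- stats::lm(predicted_kg ~ as.numeric(date), data = zwin)
    want <- back_in || unname(coef(fit)[2]) <= unname(coef(pfit)[2])
    expect_identical(got$status == "success", want)
    expect_equal(got$slope, unname(coef(fit)[2]), tolerance = 1e-8)
  }
})

test_that("tip schedules follow the configured cadence phases", {
  ph <- tibble::tibble(start_week = c(1, 9, 17), end_week = c(8, 16, 24),
                       cadence = c("weekly", "biweekly", "monthly"))
  ts <- schedule_tips(as.Date("2026-01-05"), ph)
  expect_equal(nrow(ts), 14)  # 8 weekly + 4 biweekly + 2 monthly
  expect_equal(sum(ts$phase == 1), 8)
  expect_equal(sum(ts$phase == 2), 4)
  expect_equal(sum(ts$phase == 3), 2)
  expect_true(all(diff(ts$delivery_date) > 0))
  # single-phase weekly 4-week program
  ts2 <- schedule_tips(as.Date("2026-01-05"),
                       tibble::tibble(start_week = 1, end_week = 4,
                                      cadence = "weekly"))
  expect_equal(nrow(ts2), 4)
  # zero-length program
  ts0 <- schedule_tips(as.Date("2026-01-05"),
                       tibble::tibble(start_week = 1, end_week = 0,
                                      cadence = "weekly"))
  expect_equal(nrow(ts0), 0)
  # view tracking
  ts3 <- mark_tip_viewed(ts2, ts2$tip_id[1],
                         at = as.POSIXct("2026-01-06 10:00:00", tz = "UTC"),
                         acknowledged = TRUE)
  expect_false(is.na(ts3$viewed_at[1]))
  expect_false(is.na(ts3$acknowledged_at[1]))
})

test_that("feedback events follow the stated rules with provenance", {
  d <- as.Date("2026-01-10")
  ev <- generate_feedback(d, flag = "GREEN")
  expect_setequal(ev$kind, c("congratulatory", "tip"))
  expect_true(all(ev$trigger == "flag:GREEN"))
  ev2 <- generate_feedback(d, flag = "RED", trigger_fired = TRUE,
                           strategy_label = "Use portion-controlled foods")
  expect_equal(ev2$kind, "toolbox_recommendation")
  expect_match(ev2$payload, "portion-controlled")
  ev3 <- generate_feedback(d, flag = "NO_DATA", no_data_streak = 3)
  expect_equal(ev3$kind, "reminder")
  expect_equal(nrow(generate_feedback(d, flag = "NO_DATA", no_data_streak = 2)), 0)
  # exhausted toolbox -> clinician referral
  ev4 <- generate_feedback(d, trigger_fired = TRUE, strategy_label = NULL)
  expect_equal(ev4$kind, "clinician_custom")
})

test_that("event logs round-trip through JSON lines", {
  ev <- dplyr::bind_rows(
    generate_feedback(as.Date("2026-01-10"), flag = "GREEN"),
    generate_feedback(as.Date("2026-01-11"), flag = "NO_DATA",
                      no_data_streak = 3))
  f <- tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, f)
  ev2 <- read_events_jsonl(f)
  expect_equal(as.data.frame(ev2), as.data.frame(ev))
})

test_that("the daily update loop is deterministic and audit-consistent", {
  prof <- ref_profile()
  rx <- ref_rx(-500, 90, prof)
  beh <- behavior_profile(adherence = 0.2, noise_sd = 0.3,
                          missing_prob = 0.08)
  sc <- simulate_client(prof, rx, beh, seed = 5)
  ser <- filter_outliers(ingest(sc$weights))
  r1 <- run_program(prof, rx, ser, steps = sc$steps)
  r2 <- run_program(prof, rx, ser, steps = sc$steps)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$flags, r2$flags)
  # a poorly adherent client opens at least one episode
  expect_gt(nrow(r1$episodes), 0)
  # escalation monotone within each run (strictly increasing ranks)
  cat <- toolbox_catalogue()
  eps <- r1$episodes[r1$episodes$status != "active", ]
  runs <- split(eps, cumsum(dplyr::lag(eps$status, default = "start") == "success"))
  for (rn in runs) {
    ranks <- cat$intensity_rank[match(rn$strategy_id, cat$id)]
    expect_true(all(diff(ranks) > 0))
  }
  # every toolbox recommendation event matches an episode start
  recs <- r1$events[r1$events$kind == "toolbox_recommendation", ]
  expect_true(all(recs$date %in% r1$episodes$start_date))
})
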