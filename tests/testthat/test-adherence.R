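bdate <- as.Date("2026-01-05")

# a gently declining fake prediction with dates
demo_zone <- function(n = 30, start_kg = 90, slope = -0.03, band = band_spec()) {
  tr <- make_traj(start_kg + slope * (0:(n - 1)))
  build_zone(tr, band, baseline_date = bdate)
}

test_that("zone bounds follow the band spec and contain the prediction", {
  tr <- make_traj(lb_to_kg(c(200, 197, 195)))
  z <- build_zone(tr, band_spec("absolute_lb", 2))
  expect_equal(kg_to_lb(z$lower_kg[3]), 193, tolerance = 1e-9)
  expect_equal(kg_to_lb(z$upper_kg[3]), 197, tolerance = 1e-9)
  # degenerate zero band collapses onto the prediction
  z0 <- build_zone(tr, band_spec("absolute_kg", 0))
  expect_equal(z0$lower_kg, z0$upper_kg)
  expect_equal(z0$lower_kg, z0$predicted_kg)
  # percent band scales with baseline weight
  zp <- build_zone(tr, band_spec("percent_baseline", 2))
  expect_equal(zp$upper_kg - zp$predicted_kg,
               rep(0.02 * lb_to_kg(200), 3), tolerance = 1e-12)
  # containment invariant for an asymmetric band
  za <- build_zone(tr, band_spec("absolute_kg", upper = 1.5, lower = 0.5))
  expect_true(all(za$lower_kg <= za$predicted_kg &
                    za$predicted_kg <= za$upper_kg))
  expect_error(band_spec(value = -1), class = "weightrx_invalid_config")
})

test_that("defining flag cases classify as documented", {
  z <- demo_zone()
  mid <- z$predicted_kg  # dead-center weights, clearly declining
  s <- make_series(z$date[1:10], mid[1:10])
  expect_equal(classify_flag(s, z, z$date[10])$flag, "GREEN")

  # above the upper bound and rising -> RED
  s_red <- make_series(z$date[1:10], z$upper_kg[1:10] + seq(0.5, 1.4, by = 0.1))
  expect_equal(classify_flag(s_red, z, z$date[10])$flag, "RED")

  # 1 lb above the zone but falling faster than predicted -> RED_GREEN
  s_rg <- make_series(z$date[1:10], z$upper_kg[1:10] + lb_to_kg(1) - 0.1 * (0:9))
  fr <- classify_flag(s_rg, z, z$date[3])
  expect_gt(fr$weight_kg, fr$upper_kg)
  expect_equal(fr$flag, "RED_GREEN")
  expect_lt(fr$obs_slope, fr$pred_slope)

  # below the zone -> RED
  s_lo <- make_series(z$date[1:10], z$lower_kg[1:10] - 0.5)
  expect_equal(classify_flag(s_lo, z, z$date[10])$flag, "RED")

  # in the top 20% of the band -> GREEN_YELLOW
  s_edge <- make_series(z$date[1:10], z$upper_kg[1:10] - 0.05)
  expect_equal(classify_flag(s_edge, z, z$date[10])$flag, "GREEN_YELLOW")

  # flat weights in zone while prediction declines -> plateau GREEN_YELLOW
  s_flat <- make_series(z$date[1:10], rep(z$predicted_kg[1], 10))
  expect_equal(classify_flag(s_flat, z, z$date[5])$flag, "GREEN_YELLOW")

  # no retained weight on the date -> NO_DATA
  expect_equal(classify_flag(s, z, z$date[25])$flag, "NO_DATA")
})

test_that("slope conditions are skipped with fewer than 3 trailing points", {
  z <- demo_zone()
  # two flat in-zone points would be a plateau if slopes were evaluated
  s <- make_series(z$date[c(1, 2)], rep(z$predicted_kg[1], 2))
  expect_equal(classify_flag(s, z, z$date[2])$flag, "GREEN")
  # a single above-zone point cannot be RED_GREEN
  s2 <- make_series(z$date[1], z$upper_kg[1] + 1)
  expect_equal(classify_flag(s2, z, z$date[1])$flag, "RED")
})

test_that("every dated weight maps to exactly one flag state", {
  z <- demo_zone()
  set.seed(3)
  s <- make_series(z$date[1:20], z$predicted_kg[1:20] + rnorm(20, 0, 1.2))
  fl <- flag_series(s, z, z$date[1:20])
  expect_equal(nrow(fl), 20)
  expect_true(all(fl$flag %in% c("GREEN", "GREEN_YELLOW", "RED",
                                 "RED_GREEN", "NO_DATA")))
  expect_false(any(is.na(fl$flag)))
})

test_that("widening the band never converts GREEN to RED", {
  set.seed(11)
  for (i in 1:25) {
    tr <- make_traj(90 - 0.04 * (0:14) + rnorm(1, 0, 0.5))
    zn <- build_zone(tr, band_spec("absolute_kg", 0.8), baseline_date = bdate)
    zw <- build_zone(tr, band_spec("absolute_kg", 1.6), baseline_date = bdate)
    s <- make_series(zn$date, tr$weight_kg + rnorm(15, 0, 0.8))
    fn <- flag_series(s, zn)$flag
    fw <- flag_series(s, zw)$flag
    was_green <- fn %in% c("GREEN", "GREEN_YELLOW")
    expect_false(any(fw[was_green] %in% c("RED", "RED_GREEN")))
  }
})

test_that("classify_flag agrees with the independent interval/slope oracle", {
  set.seed(19)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    slope <- runif(1, -0.08, 0.02)
    tr <- make_traj(runif(1, 70, 110) + slope * (0:(n - 1)))
    z <- build_zone(tr, band_spec("absolute_kg", runif(1, 0.4, 2)),
                    baseline_date = bdate)
    keep <- runif(n) > 0.15
    keep[n] <- TRUE
    obs_w <- tr$weight_kg + rnorm(n, 0, 0.6)
    s <- make_series(z$date[keep], obs_w[keep], baseline_date = bdate)
    d <- z$date[n]
    got <- classify_flag(s, z, d)$flag
    want <- oracle_flag(retained_observations(s), z, d)
    expect_identical(got, want)
  }
})

test_that("the 3-of-5 trigger matches exhaustive enumeration of flag patterns", {
  pats <- expand.grid(rep(list(c("GREEN", "RED")), 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    fl <- unlist(pats[i, ])
    expect_identical(trigger_check(fl, 3, 5), sum(fl == "RED") >= 3)
  }
  # the documented example pattern
  expect_true(trigger_check(c("RED", "GREEN", "RED", "GREEN", "RED")))
  expect_false(trigger_check(rep("GREEN", 5)))
  expect_false(trigger_check(c("RED", "RED", "GREEN", "GREEN", "GREEN")))
})

test_that("trigger window semantics: NO_DATA, RED_GREEN, short histories", {
  # NO_DATA occupies a window slot but never counts toward k
  expect_false(trigger_check(c("RED", "NO_DATA", "RED", "NO_DATA", "NO_DATA")))
  expect_true(trigger_check(c("NO_DATA", "RED", "RED", "NO_DATA", "RED")))
  # dropping NO_DATA from the window is configurable: the same history
  # fires only when missing days stop occupying window slots
  hist <- c("RED", "NO_DATA", "RED", "GREEN", "GREEN", "NO_DATA", "RED")
  expect_false(trigger_check(hist))
  expect_true(trigger_check(hist, no_data_in_window = FALSE))
  # RED_GREEN signals recovering adherence and is excluded by default
  expect_false(trigger_check(c("RED", "RED_GREEN", "RED", "RED_GREEN", "RED_GREEN")))
  expect_true(trigger_check(c("RED", "RED_GREEN", "RED", "RED_GREEN", "RED_GREEN"),
                            count_states = c("RED", "RED_GREEN")))
  # fewer than n dated flags since enrollment: never fires
  expect_false(trigger_check(c("RED", "RED", "RED")))
  expect_error(trigger_check("RED", k = 3, n = 2),
               class = "weightrx_invalid_config")
})

test_that("zone exports and plots work", {
  z <- demo_zone(10)
  s <- make_series(z$date[1:5], z$predicted_kg[1:5])
  f <- tempfile(fileext = ".csv")
  write_zone_csv(z, f, flags = flag_series(s, z, z$date[1:5]))
  df <- read.csv(f)
  expect_true(all(c("predicted_lb", "lower_lb", "upper_lb", "flag") %in%
                    names(df)))
  p <- plot_zone(z, s)
  expect_s3_class(p, "ggplot")
})
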