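# reference client used throughout: 50-year-old female, 65 in, 200 lb
ref_profile <- function() {
  client_profile("female", age = 50, height_in = 65, weight_lb = 200,
                 baseline_steps = 4000)
}

ref_rx <- function(delta = -500, horizon = 365,
                   profile = ref_profile(), params = model_params()) {
  energy_prescription(maintenance_energy(profile, params), delta, horizon)
}

# one-record-per-day weight series from dates and kg weights
make_series <- function(dates, weights_kg, baseline_date = min(as.Date(dates)),
                        hour = "08:00:00") {
  rec <- tibble::tibble(
    timestamp = as.POSIXct(paste(as.Date(dates), hour), tz = "UTC"),
    weight_kg = weights_kg, source = "device")
  ingest(rec, baseline_date = baseline_date)
}

# minimal weight_trajectory for zone/flag tests that do not need the ODE
make_traj <- function(weights_kg, days = seq_along(weights_kg) - 1L) {
  structure(tibble::tibble(day = as.integer(days), weight_kg = weights_kg,
                           weight_lb = kg_to_lb(weights_kg)),
            class = c("weight_trajectory", class(tibble::tibble())))
}
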