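# lenient timestamp parsing: NA (not an error) for records that match no
# known format, so one bad record cannot abort an import
parse_timestamp <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (f in fmts) {
    idx <- which(is.na(out))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], format = f, tz = tz))
  }
  out
}

#' Read raw weight records
#'
#' Readers for the two telemetry dialects the package accepts:
#'
#' * CSV with columns `timestamp` (ISO 8601), `weight`, `unit`
#'   (`"lb"` or `"kg"`) and `source` (`device`, `client_manual`,
#'   `clinician_manual`);
#' * a JSON array emulating a network-scale push, each element
#'   `{device_id, timestamp_ms, weight_g}` (epoch milliseconds, grams).
#'
#' @param path File path.
#' @param tz Fixed per-client timezone used to assign calendar dates.
#' @return A tibble of raw records: `timestamp` (POSIXct), `weight_kg`,
#'   `source`.
#' @export
read_weight_csv <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "weight", "unit", "source")
  if (!all(need %in% names(df)))
    abort_wrx(sprintf("weight CSV needs columns: %s", paste(need, collapse = ", ")),
              "weightrx_invalid_input")
  tibble::tibble(
    timestamp = parse_timestamp(df$timestamp, tz),
    weight_kg = ifelse(tolower(df$unit) == "lb", lb_to_kg(df$weight), df$weight),
    source = df$source
  )
}

#' @rdname read_weight_csv
#' @export
read_weight_json <- function(path, tz = "UTC") {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("timestamp_ms", "weight_g") %in% names(js)))
    abort_wrx("weight JSON payload needs `timestamp_ms` and `weight_g`",
              "weightrx_invalid_input")
  tibble::tibble(
    timestamp = as.POSIXct(js$timestamp_ms / 1000,
                           origin = "1970-01-01", tz = tz),
    weight_kg = js$weight_g / 1000,
    source = "device"
  )
}

#' Ingest raw weight records into a one-per-day series
#'
#' Applies the first-of-day rule: for each calendar date the
#' earliest-timestamp record is retained; later records on the same
#' date are kept but marked `excluded = "duplicate_same_day"`.
#' Records that cannot be parsed (missing/non-positive weight, invalid
#' timestamp) are rejected with a reason and processing continues; the
#' rejects are attached as the `"rejected"` attribute.
#'
#' @param records Tibble of raw records (`timestamp`, `weight_kg`,
#'   `source`), e.g. from [read_weight_csv()].
#' @param client_id Client identifier.
#' @param baseline_date `Date` of day 0; defaults to the earliest
#'   record date.
#' @param collapse_first_of_day Set `FALSE` to keep all same-day
#'   records retained (for examining within-day fluctuation).
#' @param tz Timezone for date assignment.
#' @return A `weight_series`: tibble with columns `date`, `day`
#'   (integer offset from baseline), `weight_kg`, `source`, `excluded`
#'   (`NA` for retained rows, else the exclusion reason), ordered by
#'   date then timestamp.
#' @export
ingest <- function(records, client_id = "client", baseline_date = NULL,
                   collapse_first_of_day = TRUE, tz = "UTC") {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble::tibble(date = as.Date(character()), day = integer(),
                          weight_kg = numeric(), source = character(),
                          excluded = character())
    return(new_weight_series(out, client_id, baseline_date %||% as.Date(NA)))
  }
  ts <- parse_timestamp(records$timestamp, tz)
  bad_ts <- is.na(ts)
  bad_w <- !is.finite(records$weight_kg) | records$weight_kg <= 0
  rejected <- records[bad_ts | bad_w, ]
  rejected$reason <- ifelse(bad_ts[bad_ts | bad_w],
                            "unparseable_timestamp", "invalid_weight")
  ok <- records[!(bad_ts | bad_w), ]
  ts <- ts[!(bad_ts | bad_w)]
  ord <- order(ts)
  ok <- ok[ord, ]
  ts <- ts[ord]
  date <- as.Date(ts, tz = tz)
  excluded <- rep(NA_character_, nrow(ok))
  if (collapse_first_of_day) excluded[duplicated(date)] <- "duplicate_same_day"
  baseline_date <- as.Date(baseline_date %||% min(date))
  out <- tibble::tibble(
    date = date,
    day = as.integer(date - baseline_date),
    weight_kg = ok$weight_kg,
    source = ok$source %||% "device",
    excluded = excluded
  )
  s <- new_weight_series(out, client_id, baseline_date)
  attr(s, "rejected") <- rejected
  s
}

new_weight_series <- function(df, client_id, baseline_date) {
  structure(df, client_id = client_id, baseline_date = baseline_date,
            class = c("weight_series", class(df)))
}

#' Retained observations of a weight series
#'
#' @param series A `weight_series`.
#' @return Tibble of the non-excluded rows.
#' @export
retained_observations <- function(series) {
  tibble::as_tibble(series)[is.na(series$excluded), ]
}

#' Flag foreign weights (+/- threshold filter)
#'
#' Scans retained observations in date order and marks as excluded
#' (`"outlier_gt_5pct"`) any observation whose relative deviation from
#' the *last retained* weight strictly exceeds `threshold`.  Excluded
#' observations never update the reference, so a run of foreign weights
#' (someone else on the scale) cannot poison later comparisons.  The
#' first retained observation is always kept.  A deviation of exactly
#' `threshold` is retained.
#'
#' @param series A `weight_series` from [ingest()].
#' @param threshold Relative deviation, default 0.05 (5 %).
#' @return The series with outliers marked.  Idempotent.
#' @export
filter_outliers <- function(series, threshold = 0.05) {
  stopifnot(inherits(series, "weight_series"))
  if (threshold < 0)
    abort_wrx("`threshold` must be >= 0", "weightrx_invalid_config")
  idx <- which(is.na(series$excluded))
  if (length(idx) <= 1) return(series)
  ref <- series$weight_kg[idx[1]]
  for (i in idx[-1]) {
    w <- series$weight_kg[i]
    if (abs(w - ref) / ref > threshold) {
      series$excluded[i] <- "outlier_gt_5pct"
    } else {
      ref <- w
    }
  }
  series
}

#' Convert a series back to raw records
#'
#' Retained and excluded rows become raw records again (timestamps at
#' 08:00, excluded duplicates one hour later), so that
#' `ingest(as_raw_records(s))` reproduces the retained structure.
#'
#' @param series A `weight_series`.
#' @return Tibble of raw records.
#' @export
as_raw_records <- function(series) {
  hour <- ifelse(is.na(series$excluded), 8, 9)
  tibble::tibble(
    timestamp = as.POSIXct(paste0(series$date, sprintf(" %02d:00:00", hour)),
                           tz = "UTC"),
    weight_kg = series$weight_kg,
    source = series$source
  )
}

#' Write a cleaned weight series to CSV
#'
#' Includes exclusion reasons so the cleaning decisions are auditable.
#'
#' @param series A `weight_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weight_series <- function(series, path) {
  df <- as.data.frame(tibble::as_tibble(series))
  df$weight_lb <- kg_to_lb(df$weight_kg)
  df$client_id <- attr(series, "client_id")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a cleaned weight series written by [write_weight_series()]
#'
#' @param path File path.
#' @return A `weight_series`.
#' @export
read_weight_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  out <- tibble::tibble(
    date = as.Date(df$date), day = as.integer(df$day),
    weight_kg = df$weight_kg, source = df$source,
    excluded = if ("excluded" %in% names(df)) as.character(df$excluded)
               else NA_character_
  )
  new_weight_series(out, df$client_id[1] %||% "client",
                    min(out$date) - out$day[which.min(out$date)])
}

#' @export
print.weight_series <- function(x, ...) {
  n_ret <- sum(is.na(x$excluded))
  cat(sprintf("<weight_series> client %s, %d records (%d retained), %s to %s\n",
              attr(x, "client_id"), nrow(x), n_ret,
              if (nrow(x)) format(min(x$date)) else "-",
              if (nrow(x)) format(max(x$date)) else "-"))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
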