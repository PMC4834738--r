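#' Daily step goal
#'
#' The program's activity goal is expressed in steps/day, never kcal
#' (consumer activity monitors do not estimate caloric expenditure
#' reliably).  The goal is baseline plus an increment, by default in
#' the 3000-4000 steps/day range, so a typical 4000-step baseline
#' yields a 7000-8000 steps/day goal.
#'
#' @param baseline_steps Habitual steps/day (>= 0).
#' @param increment Steps/day added to baseline (>= 0), default 3000.
#' @return An `activity_goal` list with `baseline_steps`, `increment`,
#'   `goal`.
#' @examples
#' compute_goal(4000, 3000)$goal # 7000
#' compute_goal(4000, 4000)$goal # 8000
#' @export
compute_goal <- function(baseline_steps, increment = 3000) {
  if (!is.numeric(baseline_steps) || baseline_steps < 0)
    abort_wrx("`baseline_steps` must be >= 0", "weightrx_invalid_config")
  if (!is.numeric(increment) || increment < 0)
    abort_wrx("`increment` must be >= 0", "weightrx_invalid_config")
  structure(list(baseline_steps = baseline_steps, increment = increment,
                 goal = baseline_steps + increment),
            class = "activity_goal")
}

#' Read daily step records
#'
#' CSV with columns `date`, `steps`, `source` (`device` or `manual`).
#'
#' @param path File path.
#' @return Tibble of step records.
#' @export
read_steps_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "steps") %in% names(df)))
    abort_wrx("steps CSV needs columns `date` and `steps`",
              "weightrx_invalid_input")
  tibble::tibble(date = as.Date(df$date),
                 steps = as.numeric(df$steps),
                 source = df$source %||% "device")
}

# step devices sync cumulative daily totals several times a day, so the
# retained count for a date is the maximum over same-day records
collapse_steps <- function(records) {
  records <- records[!is.na(records$steps) & records$steps >= 0, ]
  if (nrow(records) == 0)
    return(tibble::tibble(date = as.Date(character()), steps = numeric()))
  agg <- stats::aggregate(steps ~ date, data = records, FUN = max)
  tibble::as_tibble(agg[order(agg$date), ])
}

#' Daily step adherence
#'
#' Per calendar date, the retained step count (max over same-day sync
#' records) is compared with the goal: `met` if at or above the goal,
#' `not_met` below it, `missing` for dates without any record.
#'
#' @param records Tibble of step records (`date`, `steps`), e.g. from
#'   [read_steps_csv()].
#' @param goal An [compute_goal()] result (or a single number).
#' @param dates Optional `Date` vector defining the evaluation range;
#'   defaults to the full span of the records.
#' @return Tibble: `date`, `steps` (NA when missing), `goal`, `status`.
#' @export
step_adherence <- function(records, goal, dates = NULL) {
  g <- if (inherits(goal, "activity_goal")) goal$goal else goal
  daily <- collapse_steps(records)
  if (is.null(dates)) {
    if (nrow(daily) == 0)
      return(tibble::tibble(date = as.Date(character()), steps = numeric(),
                            goal = numeric(), status = character()))
    dates <- seq(min(daily$date), max(daily$date), by = "day")
  }
  steps <- daily$steps[match(dates, daily$date)]
  tibble::tibble(
    date = as.Date(dates), steps = steps, goal = g,
    status = ifelse(is.na(steps), "missing",
                    ifelse(steps >= g, "met", "not_met"))
  )
}

#' Plot daily steps against the goal
#'
#' Bar chart of retained daily counts with a horizontal goal line.
#'
#' @param adherence A [step_adherence()] result.
#' @return A ggplot object.
#' @export
plot_steps <- function(adherence) {
  ggplot2::ggplot(adherence, ggplot2::aes(x = date, y = steps)) +
    ggplot2::geom_col(fill = "seagreen", na.rm = TRUE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = goal),
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = NULL, y = "Steps/day")
}
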