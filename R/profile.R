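#' Client profile
#'
#' Demographics and baseline anthropometrics used by the energy-balance
#' model.  Height and weight may be given in either unit system; they
#' are stored in cm and kg.
#'
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (> 0).
#' @param height_cm,height_in Height; supply exactly one.
#' @param weight_kg,weight_lb Baseline weight; supply exactly one.
#' @param baseline_steps Optional habitual steps/day (>= 0), used for
#'   step-goal computation.
#' @return An object of class `client_profile`.
#' @examples
#' client_profile("female", age = 50, height_in = 65, weight_lb = 200)
#' @export
client_profile <- function(sex = c("female", "male"), age,
                           height_cm = NULL, height_in = NULL,
                           weight_kg = NULL, weight_lb = NULL,
                           baseline_steps = NULL) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1 || !is.finite(age) || age <= 0)
    abort_wrx("`age` must be a single positive number of years",
              "weightrx_invalid_profile")
  if (is.null(height_cm) == is.null(height_in))
    abort_wrx("supply exactly one of `height_cm` or `height_in`",
              "weightrx_invalid_profile")
  if (is.null(weight_kg) == is.null(weight_lb))
    abort_wrx("supply exactly one of `weight_kg` or `weight_lb`",
              "weightrx_invalid_profile")
  height_cm <- height_cm %||% in_to_cm(height_in)
  weight_kg <- weight_kg %||% lb_to_kg(weight_lb)
  if (!is.finite(height_cm) || height_cm <= 0)
    abort_wrx("height must be positive", "weightrx_invalid_profile")
  if (!is.finite(weight_kg) || weight_kg <= 0)
    abort_wrx("baseline weight must be positive", "weightrx_invalid_profile")
  if (!is.null(baseline_steps) &&
      (!is.numeric(baseline_steps) || baseline_steps < 0))
    abort_wrx("`baseline_steps` must be >= 0", "weightrx_invalid_profile")
  structure(
    list(sex = sex, age = age, height_cm = height_cm,
         weight_kg = weight_kg, baseline_steps = baseline_steps),
    class = "client_profile"
  )
}

#' @export
print.client_profile <- function(x, ...) {
  cat(sprintf("<client_profile> %s, %g y, %.1f cm (%.1f in), %.1f kg (%.1f lb)\n",
              x$sex, x$age, x$height_cm, cm_to_in(x$height_cm),
              x$weight_kg, kg_to_lb(x$weight_kg)))
  if (!is.null(x$baseline_steps))
    cat(sprintf("  baseline steps/day: %g\n", x$baseline_steps))
  invisible(x)
}

#' Energy prescription
#'
#' A maintenance energy intake plus a prescribed daily change.  Negative
#' `delta_intake` is a restriction; positive is a surplus (weight-gain
#' programs are supported by the same model).
#'
#' @param maintenance_intake Maintenance (weight-stable) intake,
#'   kcal/day (> 0).  Usually [maintenance_energy()].
#' @param delta_intake Prescribed change from maintenance, kcal/day.
#' @param horizon Program horizon in days (>= 0).
#' @return An object of class `energy_prescription`.
#' @export
energy_prescription <- function(maintenance_intake, delta_intake,
                                horizon = 365L) {
  if (!is.numeric(maintenance_intake) || maintenance_intake <= 0)
    abort_wrx("`maintenance_intake` must be > 0 kcal/day",
              "weightrx_invalid_prescription")
  if (!is.numeric(delta_intake) || length(delta_intake) != 1 ||
      !is.finite(delta_intake))
    abort_wrx("`delta_intake` must be a single finite number",
              "weightrx_invalid_prescription")
  if (maintenance_intake + delta_intake < 0)
    abort_wrx("prescribed intake (maintenance + delta) must be >= 0 kcal/day",
              "weightrx_invalid_prescription")
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 0)
    abort_wrx("`horizon` must be a non-negative number of days",
              "weightrx_invalid_prescription")
  structure(
    list(maintenance_intake = maintenance_intake,
         delta_intake = delta_intake,
         prescribed_intake = maintenance_intake + delta_intake,
         horizon = horizon),
    class = "energy_prescription"
  )
}

#' @export
print.energy_prescription <- function(x, ...) {
  cat(sprintf(
    "<energy_prescription> maintenance %.0f %+.0f = %.0f kcal/day over %d days\n",
    x$maintenance_intake, x$delta_intake, x$prescribed_intake, x$horizon))
  invisible(x)
}
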