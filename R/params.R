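#' Energy-balance model parameters
#'
#' Constants of the two-compartment model.  The defaults describe an
#' adult engaging in light-to-moderate physical activity and are the
#' parameterization used throughout the package; every constant can be
#' overridden here or via a YAML config block ([read_model_params()]).
#'
#' Components:
#' * `rho_fat`, `rho_ffm` — energy densities of fat mass and fat-free
#'   mass (kcal/kg).
#' * `pal` — physical-activity multiplier applied to resting metabolic
#'   rate; the default 1.5 corresponds to light-to-moderate activity
#'   (roughly the recommended 150 min/week).
#' * `tef` — thermic effect of feeding as a fraction of intake.
#' * `comp_per_kg` — metabolic compensation, kcal/day of expenditure
#'   change per kg of weight change from baseline (beyond the resting
#'   component).  Its default is calibrated so the reference scenario
#'   (50-year-old female, 65 in, 200 lb, 500 kcal/day restriction)
#'   loses 17.4 lb (8.7 %) over 12 months, the behavior of validated
#'   energy-balance weight-loss predictors for that input.
#' * `forbes_slope`, `forbes_intercept` — Forbes-type body-composition
#'   curve `ffm = slope * log(fat) + intercept[sex]` (kg), used both to
#'   assign baseline composition and to partition energy imbalance
#'   between compartments.
#' * `rmr_coef` — sex-specific linear resting-metabolic-rate regression
#'   on weight (kg), height (cm) and age (years).
#'
#' @param rho_fat,rho_ffm Energy densities, kcal/kg (> 0).
#' @param pal Activity multiplier (>= 1).
#' @param tef Thermic effect of feeding, fraction of intake in [0, 0.5).
#' @param comp_per_kg Metabolic compensation, kcal/day per kg (>= 0).
#' @param forbes_slope Slope of the Forbes curve, kg per log-kg.
#' @param forbes_intercept Named numeric, intercepts (kg) for
#'   `female` and `male`.
#' @param rmr_coef List with elements `weight`, `height`, `age`
#'   (kcal/day per unit) and named `intercept` for each sex.
#' @return An object of class `model_params`.
#' @export
model_params <- function(rho_fat = 9440,
                         rho_ffm = 1816,
                         pal = 1.5,
                         tef = 0.10,
                         comp_per_kg = 37.3043,
                         forbes_slope = 10.4,
                         forbes_intercept = c(female = 14.2, male = 23.2),
                         rmr_coef = list(weight = 9.99, height = 6.25,
                                         age = -4.92,
                                         intercept = c(female = -161,
                                                       male = 5))) {
  if (rho_fat <= 0 || rho_ffm <= 0)
    abort_wrx("tissue energy densities must be positive", "weightrx_invalid_params")
  if (pal < 1) abort_wrx("`pal` must be >= 1", "weightrx_invalid_params")
  if (tef < 0 || tef >= 0.5)
    abort_wrx("`tef` must be in [0, 0.5)", "weightrx_invalid_params")
  if (comp_per_kg < 0)
    abort_wrx("`comp_per_kg` must be >= 0", "weightrx_invalid_params")
  if (forbes_slope <= 0)
    abort_wrx("`forbes_slope` must be positive", "weightrx_invalid_params")
  if (!all(c("female", "male") %in% names(forbes_intercept)))
    abort_wrx("`forbes_intercept` needs `female` and `male` entries",
              "weightrx_invalid_params")
  if (!all(c("weight", "height", "age", "intercept") %in% names(rmr_coef)) ||
      !all(c("female", "male") %in% names(rmr_coef$intercept)))
    abort_wrx("`rmr_coef` needs weight/height/age and sex intercepts",
              "weightrx_invalid_params")
  structure(
    list(rho_fat = rho_fat, rho_ffm = rho_ffm, pal = pal, tef = tef,
         comp_per_kg = comp_per_kg, forbes_slope = forbes_slope,
         forbes_intercept = forbes_intercept, rmr_coef = rmr_coef),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  rho_fat %g, rho_ffm %g kcal/kg; pal %g; tef %g\n",
              x$rho_fat, x$rho_ffm, x$pal, x$tef))
  cat(sprintf("  comp_per_kg %g kcal/day/kg; Forbes slope %g, intercepts F %g / M %g kg\n",
              x$comp_per_kg, x$forbes_slope,
              x$forbes_intercept[["female"]], x$forbes_intercept[["male"]]))
  invisible(x)
}

#' Read / write model parameters as a YAML config block
#'
#' @param path File path.
#' @param params A `model_params` object.
#' @return `read_model_params()` returns a `model_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$forbes_intercept <- unlist(cfg$forbes_intercept)
  if (!is.null(cfg$rmr_coef$intercept))
    cfg$rmr_coef$intercept <- unlist(cfg$rmr_coef$intercept)
  do.call(model_params, cfg)
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  x <- unclass(params)
  x$forbes_intercept <- as.list(x$forbes_intercept)
  x$rmr_coef$intercept <- as.list(x$rmr_coef$intercept)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Resting metabolic rate regression
#'
#' Linear sex-specific regression on weight, height and age.
#'
#' @param weight_kg Weight in kg.
#' @param height_cm Height in cm.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param params A [model_params()] object.
#' @return RMR in kcal/day (never negative).
#' @export
resting_metabolic_rate <- function(weight_kg, height_cm, age, sex,
                                   params = model_params()) {
  co <- params$rmr_coef
  pmax(0, co$weight * weight_kg + co$height * height_cm + co$age * age +
         co$intercept[[sex]])
}

# Forbes-type curve: ffm implied by fat mass, and its inverse used to
# split a measured body weight into (fat, ffm).  Because the partition
# rule below is the derivative of this same curve, a trajectory started
# on the curve stays on it, so re-initializing from any later weight is
# consistent.
forbes_ffm <- function(fat_kg, sex, params) {
  params$forbes_slope * log(fat_kg) + params$forbes_intercept[[sex]]
}

#' Split body weight into fat and fat-free mass
#'
#' Inverts the Forbes-type body-composition curve to find the fat mass
#' consistent with total weight for the given sex.
#'
#' @param weight_kg Total body weight, kg.
#' @inheritParams resting_metabolic_rate
#' @return Named numeric `c(fat_kg, ffm_kg)` summing to `weight_kg`.
#' @export
initial_composition <- function(weight_kg, sex, params = model_params()) {
  f <- function(fat) fat + forbes_ffm(fat, sex, params) - weight_kg
  # fat + slope*log(fat) is increasing, so the root is unique
  lower <- 1e-6
  upper <- max(weight_kg, 2)
  while (f(upper) < 0) upper <- upper * 2
  fat <- uniroot(f, c(lower, upper), tol = 1e-10)$root
  c(fat_kg = fat, ffm_kg = weight_kg - fat)
}

#' Energy-partition fraction
#'
#' Fraction of an energy imbalance routed to fat-free mass, a
#' Forbes-type function of current fat mass:
#' `p = C / (C + fat)` with `C = forbes_slope * rho_ffm / rho_fat`.
#'
#' @param fat_kg Fat mass, kg (> 0).
#' @param params A [model_params()] object.
#' @return Partition fraction in (0, 1).
#' @export
partition_fraction <- function(fat_kg, params = model_params()) {
  cc <- params$forbes_slope * params$rho_ffm / params$rho_fat
  cc / (cc + pmax(fat_kg, 1e-6))
}
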