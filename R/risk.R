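# Default lifetime-risk anchors for the anchored_spline strategy:
# (BMI category midpoint, lifetime T2DM risk) pairs patterned on the
# sex-averaged adult lifetime-risk estimates of Narayan et al. (2007),
# Diabetes Care 30:1562-1566.
default_diabetes_anchors <- function() {
  cbind(bmi = c(17, 21.75, 27.5, 32.5, 40),
        probability = c(0.10, 0.19, 0.33, 0.51, 0.72))
}

#' Build the BMI-to-lifetime-diabetes risk map
#'
#' Two strategies are supported. `"ecdf"` follows the empirical-CDF
#' construction: a dense uniform grid over the reference BMI range is
#' centered and standardized, multiplied by `diabetes_scale`, and the
#' probability at a BMI is the empirical CDF of those reference values
#' evaluated at the BMI's own scaled standardized value (so the reference
#' minimum maps to 0, the midpoint to 0.5, and the maximum to 1).
#' `"anchored_spline"` interpolates a monotone (Hyman-filtered cubic) spline
#' through `(BMI, lifetime risk)` anchors. Both maps clamp BMI outside the
#' supported range to the boundary probability and clip outputs to \[0, 1\].
#'
#' Neither uncalibrated map reproduces a given eligible-cohort mean risk;
#' use [calibrate_diabetes_map()] to hit a target mean by a monotone
#' log-odds shift.
#'
#' @param config A [sim_config()] (strategy, scale, reference range,
#'   anchors).
#' @param n_grid Reference grid size for the ecdf strategy (odd keeps the
#'   midpoint exactly on the grid).
#' @return An object of class `"diabetes_map"`.
#' @examples
#' m <- build_diabetes_map(sim_config())
#' evaluate_diabetes_risk(m, c(20, 37.5, 55))
#' @export
build_diabetes_map <- function(config = sim_config(), n_grid = 3501L) {
  range <- config$diabetes_ref_bmi_range
  map <- list(strategy = config$diabetes_map_strategy,
              bmi_min = range[1], bmi_max = range[2],
              offset = 0)
  if (config$diabetes_map_strategy == "ecdf") {
    grid <- seq(range[1], range[2], length.out = n_grid)
    z <- (grid - mean(grid)) / stats::sd(grid)
    map$ref_mean <- mean(grid)
    map$ref_sd <- stats::sd(grid)
    map$scale <- config$diabetes_scale
    map$ref_values <- sort(config$diabetes_scale * z)
  } else {
    anchors <- config$diabetes_anchors
    if (is.null(anchors)) anchors <- default_diabetes_anchors()
    anchors <- as_anchor_matrix(anchors)
    if (any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) <= 0)) {
      stop("diabetes anchors must be strictly increasing in both coordinates",
           call. = FALSE)
    }
    map$anchors <- anchors
    map$spline <- stats::splinefun(anchors[, 1], anchors[, 2],
                                   method = "hyman")
    # spline support: clamp to the anchor range, which may be wider or
    # narrower than the ecdf reference range
    map$bmi_min <- min(anchors[, 1])
    map$bmi_max <- max(anchors[, 1])
  }
  class(map) <- "diabetes_map"
  map
}

#' Evaluate lifetime diabetes risk at given BMI values
#'
#' Deterministic, monotone nondecreasing in BMI, bounded in \[0, 1\]. BMI
#' outside the supported range is clamped to the boundary value (lifetime
#' risk beyond the reference range is unsupported, so the map does not
#' extrapolate). Any calibration offset (see [calibrate_diabetes_map()]) is
#' applied on the log-odds scale.
#'
#' @param map A `"diabetes_map"`.
#' @param bmi Numeric vector of BMI values.
#' @return Probabilities, one per BMI.
#' @export
evaluate_diabetes_risk <- function(map, bmi) {
  stopifnot(inherits(map, "diabetes_map"))
  x <- pmin(pmax(bmi, map$bmi_min), map$bmi_max)
  p <- if (map$strategy == "ecdf") {
    v <- map$scale * (x - map$ref_mean) / map$ref_sd
    n <- length(map$ref_values)
    # counts reference values <= v with a 1e-9 tie tolerance, so that BMIs
    # lying on the reference grid are counted despite floating-point noise
    (findInterval(v + 1e-9, map$ref_values) - 1) / (n - 1)
  } else {
    map$spline(x)
  }
  p <- pmin(pmax(p, 0), 1)
  if (map$offset != 0) {
    eps <- 1e-9
    p <- stats::plogis(stats::qlogis(pmin(pmax(p, eps), 1 - eps)) + map$offset)
  }
  p
}

#' Calibrate the diabetes map to a target cohort mean
#'
#' Finds a single additive shift on the log-odds scale such that the mean
#' evaluated risk over the supplied (untreated) BMI values equals
#' `target_mean` within `tol`. The shift preserves monotonicity and the
#' \[0, 1\] bounds, and calibrating an already-calibrated map is a no-op up
#' to root-finding tolerance.
#'
#' @param map A `"diabetes_map"`.
#' @param bmis Untreated BMI values of the calibration cohort.
#' @param target_mean Target mean probability, in (0, 1).
#' @param tol Acceptable absolute deviation of the achieved mean.
#' @return The calibrated `"diabetes_map"` (with updated `offset`).
#' @export
calibrate_diabetes_map <- function(map, bmis, target_mean, tol = 1e-3) {
  stopifnot(inherits(map, "diabetes_map"))
  if (target_mean <= 0 || target_mean >= 1) {
    stop("target_mean must be in (0, 1)", call. = FALSE)
  }
  objective <- function(delta) {
    m <- map
    m$offset <- map$offset + delta
    mean(evaluate_diabetes_risk(m, bmis)) - target_mean
  }
  lo <- -35; hi <- 35
  if (objective(lo) > 0 || objective(hi) < 0) {
    stop("calibration target unreachable by a monotone log-odds shift",
         call. = FALSE)
  }
  delta <- stats::uniroot(objective, c(lo, hi), tol = 1e-10)$root
  map$offset <- map$offset + delta
  achieved <- mean(evaluate_diabetes_risk(map, bmis))
  if (abs(achieved - target_mean) > tol) {
    stop(sprintf("calibration failed: achieved mean %.6f vs target %.6f",
                 achieved, target_mean), call. = FALSE)
  }
  map
}

#' @export
print.diabetes_map <- function(x, ...) {
  cat(sprintf("<diabetes_map> strategy=%s, BMI range [%g, %g], log-odds offset %.4f\n",
              x$strategy, x$bmi_min, x$bmi_max, x$offset))
  invisible(x)
}

#' Build the adverse-event risk model
#'
#' Surgical adverse-event probability is logistic in the standardized
#' baseline covariate (weight in kg by default, optionally BMI) plus a sex
#' indicator: `p = plogis(intercept + ae_weight_coef * z + ae_male_coef *
#' is_male)`. The covariate is standardized against the supplied eligible
#' cohort, and the intercept is fitted so the cohort mean probability equals
#' `ae_target_mean`. With a positive covariate coefficient the probability
#' is strictly increasing in baseline weight, matching the observation that
#' heavier patients face higher surgical risk. The coefficients are
#' configurable model choices, not literature estimates.
#'
#' @param eligible Eligible cohort (needs `weight_kg` or `bmi`, and
#'   `is_male`).
#' @param config A [sim_config()].
#' @return An object of class `"ae_model"`.
#' @export
build_ae_model <- function(eligible, config = sim_config()) {
  xcol <- if (config$ae_covariate == "weight") "weight_kg" else "bmi"
  stopifnot(xcol %in% names(eligible), "is_male" %in% names(eligible))
  x <- eligible[[xcol]]
  center <- mean(x)
  scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) scale <- 1
  lp0 <- config$ae_weight_coef * (x - center) / scale +
    config$ae_male_coef * as.numeric(eligible$is_male)
  target <- config$ae_target_mean
  objective <- function(b0) mean(stats::plogis(b0 + lp0)) - target
  intercept <- stats::uniroot(objective, c(-40, 40), tol = 1e-10)$root
  structure(
    list(covariate = config$ae_covariate, column = xcol,
         center = center, scale = scale,
         coef_covariate = config$ae_weight_coef,
         coef_male = config$ae_male_coef,
         intercept = intercept, target_mean = target),
    class = "ae_model"
  )
}

#' Adverse-event probability for subjects
#'
#' Evaluates a fitted [build_ae_model()] on baseline measures.
#'
#' @param model An `"ae_model"`.
#' @param subjects Data frame with the model's covariate column
#'   (`weight_kg` or `bmi`) and `is_male`.
#' @return Probabilities, one per row.
#' @export
adverse_event_probability <- function(model, subjects) {
  stopifnot(inherits(model, "ae_model"))
  x <- subjects[[model$column]]
  if (is.null(x)) stop("subjects lack column ", model$column, call. = FALSE)
  if (any(x <= 0)) stop(model$column, " must be positive", call. = FALSE)
  z <- (x - model$center) / model$scale
  stats::plogis(model$intercept + model$coef_covariate * z +
                  model$coef_male * as.numeric(subjects$is_male))
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model> logit(p) = %.4f + %.2f * z(%s) + %.2f * male (cohort mean %.3f)\n",
              x$intercept, x$coef_covariate, x$column, x$coef_male,
              x$target_mean))
  invisible(x)
}

#' Build and calibrate both risk models for a cohort
#'
#' Constructs the diabetes map (calibrated so the untreated eligible-cohort
#' mean equals `diabetes_target_eligible_mean`) and the adverse-event model
#' (intercept-calibrated to `ae_target_mean`).
#'
#' @param eligible Eligible cohort.
#' @param config A [sim_config()].
#' @return A list with elements `diabetes_map` and `ae_model`.
#' @export
build_risk_models <- function(eligible, config = sim_config()) {
  dmap <- build_diabetes_map(config)
  dmap <- calibrate_diabetes_map(dmap, eligible$bmi,
                                 config$diabetes_target_eligible_mean)
  list(diabetes_map = dmap, ae_model = build_ae_model(eligible, config))
}

#' Per-subject risk profiles
#'
#' Assembles, for each eligible subject, the lifetime T2DM probability if
#' untreated (evaluated at baseline BMI), if treated (evaluated at
#' post-surgery BMI via the same map), and the adverse-event probability if
#' treated. Whenever PEWL is positive the treated diabetes probability is at
#' or below the untreated one, because the map is monotone and surgery
#' lowers BMI.
#'
#' @param eligible Eligible cohort.
#' @param outcomes Outcome tibble from [simulate_outcomes()].
#' @param models Risk models from [build_risk_models()].
#' @return A tibble `subject_id`, `p_t2dm_untreated`, `p_t2dm_treated`,
#'   `p_adverse_event`.
#' @export
compute_risk_profiles <- function(eligible, outcomes, models) {
  stopifnot(identical(eligible$id, outcomes$subject_id))
  tibble::tibble(
    subject_id = eligible$id,
    p_t2dm_untreated = evaluate_diabetes_risk(models$diabetes_map,
                                              eligible$bmi),
    p_t2dm_treated = evaluate_diabetes_risk(models$diabetes_map,
                                            outcomes$post_bmi),
    p_adverse_event = adverse_event_probability(models$ae_model, eligible)
  )
}
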