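#' Simulation configuration
#'
#' Construct the full parameter set for the cohort simulation, outcome models
#' and decision analysis. Defaults reproduce the published study conditions:
#' a 150,000-person population whose height and log-weight follow a bivariate
#' normal with female location/shape parameters and additive male offsets,
#' a surgery-eligibility cutoff of BMI 35, percent excess weight loss (PEWL)
#' distributed N(63, 23^2) with a 0.59-magnitude association with baseline
#' weight, a genomic predictor of PEWL distributed N(63, 7.6^2) with
#' correlation 0.316 to actual PEWL, risk maps calibrated so the eligible
#' cohort has mean lifetime T2DM risk 0.28 and mean adverse-event risk 0.049,
#' and a threshold sweep from 55 to 80 with 1000 fundable surgeries.
#'
#' @param n_population Number of subjects to simulate before outlier removal.
#' @param height_mean_f,height_sd_f Female height mean and SD (cm).
#' @param logweight_mean_f,logweight_sd_f Female log-weight mean and SD (log kg).
#' @param height_logweight_cov Covariance between height (cm) and log-weight
#'   (log kg). Interpreted as a covariance by default; set
#'   `cov_is_correlation = TRUE` to reinterpret the same number as a
#'   correlation.
#' @param cov_is_correlation Reinterpret `height_logweight_cov` as a
#'   correlation coefficient instead of a covariance.
#' @param male_height_offset,male_weight_offset Additive male offsets applied
#'   on the natural scales (cm, kg) after exponentiating weight.
#' @param male_fraction_cutoff Uniform-draw cutoff above which a subject is
#'   declared male (0.5 gives a balanced population).
#' @param weight_max,weight_min,height_min Outlier filters: subjects with
#'   weight above `weight_max` kg, below `weight_min` kg, or height below
#'   `height_min` cm are removed.
#' @param bmi_eligibility Surgery eligibility cutoff on BMI (inclusive).
#' @param ideal_bmi BMI defining ideal weight; excess weight is weight above
#'   the ideal-BMI weight at the subject's height.
#' @param pewl_mean,pewl_sd Target mean and SD of actual PEWL (% of excess
#'   weight).
#' @param pewl_weight_assoc Magnitude of the association between PEWL and
#'   baseline weight (standardized-scale mixing coefficient).
#' @param pewl_weight_assoc_sign Sign (+1 or -1) of the PEWL-weight
#'   association. The default -1 makes high responders the lighter patients,
#'   which is what drives adverse-event risk down as the decision threshold
#'   rises.
#' @param pewl_residual_coef Residual mixing coefficient for PEWL. `NULL`
#'   (default) uses `sqrt(1 - pewl_weight_assoc^2)` so the realized
#'   correlation magnitude equals `pewl_weight_assoc` exactly; set 0.85 for
#'   the literal published mix (realized magnitude about 0.57).
#' @param predictor_mean,predictor_sd Target mean and SD of the genomic
#'   prediction of PEWL.
#' @param predictor_pewl_corr Target correlation between predicted and actual
#'   PEWL (0.316 corresponds to predictive R^2 of 0.1).
#' @param diabetes_map_strategy `"ecdf"` (empirical-CDF construction over a
#'   uniform BMI reference grid) or `"anchored_spline"` (monotone spline
#'   through lifetime-risk anchors in the spirit of Narayan et al.).
#' @param diabetes_scale Scale applied to the standardized BMI in the ecdf
#'   construction.
#' @param diabetes_ref_bmi_range Length-2 BMI reference range for the
#'   diabetes map; evaluations outside it are clamped to the boundary.
#' @param diabetes_anchors Anchors for the `anchored_spline` strategy: a
#'   two-column matrix / data frame or list of `c(bmi, probability)` pairs,
#'   strictly increasing in both coordinates. `NULL` uses built-in defaults
#'   patterned on Narayan et al.'s lifetime-risk table.
#' @param diabetes_target_eligible_mean Calibration target for mean untreated
#'   lifetime T2DM risk over the eligible cohort.
#' @param ae_covariate Adverse-event model covariate: `"weight"` (baseline kg,
#'   default) or `"bmi"`.
#' @param ae_weight_coef Log-odds per SD of the (standardized) adverse-event
#'   covariate.
#' @param ae_male_coef Log-odds offset for males in the adverse-event model.
#' @param ae_target_mean Calibration target for mean adverse-event probability
#'   over the eligible cohort.
#' @param n_surgeries Number of surgeries fundable with the available budget.
#' @param budget_usd Total budget (documentation only; `n_surgeries` is the
#'   operative constraint).
#' @param tau_min,tau_max,tau_step Decision-threshold sweep over predicted
#'   PEWL (%).
#' @param eq1_weighted Use a population-size-weighted mean in the population
#'   case probability instead of the unweighted average of group means.
#' @param prevented_comparator Default comparator for cases prevented:
#'   `"random_allocation"` (same number of surgeries allocated without the
#'   test) or `"untreated_baseline"` (no one treated).
#' @param rng_seed Master seed; per-stage substreams are derived from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_population = 20000)
#' cfg$bmi_eligibility
#' @export
sim_config <- function(n_population = 150000,
                       height_mean_f = 160.6,
                       height_sd_f = 6.2,
                       logweight_mean_f = 4.2,
                       logweight_sd_f = 0.19,
                       height_logweight_cov = 0.59,
                       cov_is_correlation = FALSE,
                       male_height_offset = 13,
                       male_weight_offset = 9.4,
                       male_fraction_cutoff = 0.5,
                       weight_max = 180,
                       weight_min = 38,
                       height_min = 145,
                       bmi_eligibility = 35,
                       ideal_bmi = 25,
                       pewl_mean = 63.0,
                       pewl_sd = 23.0,
                       pewl_weight_assoc = 0.59,
                       pewl_weight_assoc_sign = -1,
                       pewl_residual_coef = NULL,
                       predictor_mean = 63.0,
                       predictor_sd = 7.6,
                       predictor_pewl_corr = 0.316,
                       diabetes_map_strategy = c("ecdf", "anchored_spline"),
                       diabetes_scale = 0.8,
                       diabetes_ref_bmi_range = c(20, 55),
                       diabetes_anchors = NULL,
                       diabetes_target_eligible_mean = 0.28,
                       ae_covariate = c("weight", "bmi"),
                       ae_weight_coef = 0.5,
                       ae_male_coef = 0.3,
                       ae_target_mean = 0.049,
                       n_surgeries = 1000,
                       budget_usd = 2e7,
                       tau_min = 55,
                       tau_max = 80,
                       tau_step = 1,
                       eq1_weighted = FALSE,
                       prevented_comparator = c("random_allocation",
                                                "untreated_baseline"),
                       rng_seed = 1L) {
  cfg <- list(
    n_population = n_population,
    height_mean_f = height_mean_f,
    height_sd_f = height_sd_f,
    logweight_mean_f = logweight_mean_f,
    logweight_sd_f = logweight_sd_f,
    height_logweight_cov = height_logweight_cov,
    cov_is_correlation = isTRUE(cov_is_correlation),
    male_height_offset = male_height_offset,
    male_weight_offset = male_weight_offset,
    male_fraction_cutoff = male_fraction_cutoff,
    weight_max = weight_max,
    weight_min = weight_min,
    height_min = height_min,
    bmi_eligibility = bmi_eligibility,
    ideal_bmi = ideal_bmi,
    pewl_mean = pewl_mean,
    pewl_sd = pewl_sd,
    pewl_weight_assoc = pewl_weight_assoc,
    pewl_weight_assoc_sign = pewl_weight_assoc_sign,
    pewl_residual_coef = pewl_residual_coef,
    predictor_mean = predictor_mean,
    predictor_sd = predictor_sd,
    predictor_pewl_corr = predictor_pewl_corr,
    diabetes_map_strategy = match.arg(diabetes_map_strategy),
    diabetes_scale = diabetes_scale,
    diabetes_ref_bmi_range = diabetes_ref_bmi_range,
    diabetes_anchors = diabetes_anchors,
    diabetes_target_eligible_mean = diabetes_target_eligible_mean,
    ae_covariate = match.arg(ae_covariate),
    ae_weight_coef = ae_weight_coef,
    ae_male_coef = ae_male_coef,
    ae_target_mean = ae_target_mean,
    n_surgeries = n_surgeries,
    budget_usd = budget_usd,
    tau_min = tau_min,
    tau_max = tau_max,
    tau_step = tau_step,
    eq1_weighted = isTRUE(eq1_weighted),
    prevented_comparator = match.arg(prevented_comparator),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks distributional parameters (positive SDs, a positive semidefinite
#' height/log-weight covariance), probability bounds, threshold ordering and
#' anchor monotonicity. Called by [sim_config()] and [read_sim_config()].
#'
#' @param cfg A `"sim_config"` object or a bare named list with the same
#'   fields.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)

  if (!is.numeric(cfg$n_population) || length(cfg$n_population) != 1 ||
      cfg$n_population <= 0) {
    stop_cfg("n_population must be a positive count")
  }
  for (f in c("height_sd_f", "logweight_sd_f", "pewl_sd", "predictor_sd")) {
    if (cfg[[f]] < 0) stop_cfg(paste(f, "must be nonnegative"))
  }
  probs <- c("male_fraction_cutoff", "diabetes_target_eligible_mean",
             "ae_target_mean")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_cfg(paste(f, "must be in [0, 1]"))
  }
  if (cfg$cov_is_correlation) {
    if (abs(cfg$height_logweight_cov) >= 1) {
      stop_cfg("height_logweight_cov as a correlation must lie in (-1, 1)")
    }
  } else {
    bound <- cfg$height_sd_f * cfg$logweight_sd_f
    if (abs(cfg$height_logweight_cov) > bound) {
      stop_cfg(sprintf(
        "height_logweight_cov (%.4g) exceeds height_sd_f * logweight_sd_f (%.4g): covariance matrix not positive semidefinite",
        cfg$height_logweight_cov, bound))
    }
  }
  if (abs(cfg$predictor_pewl_corr) > 1) {
    stop_cfg("predictor_pewl_corr must lie in [-1, 1]")
  }
  if (!cfg$pewl_weight_assoc_sign %in% c(-1, 1)) {
    stop_cfg("pewl_weight_assoc_sign must be +1 or -1")
  }
  if (cfg$pewl_weight_assoc < 0 || cfg$pewl_weight_assoc > 1) {
    stop_cfg("pewl_weight_assoc must be a magnitude in [0, 1]")
  }
  if (is.null(cfg$pewl_residual_coef)) {
    # implied sqrt(1 - a^2), always valid for a in [0, 1]
  } else if (cfg$pewl_residual_coef < 0) {
    stop_cfg("pewl_residual_coef must be nonnegative")
  }
  if (cfg$tau_min > cfg$tau_max) stop_cfg("tau_min must not exceed tau_max")
  if (cfg$tau_step <= 0) stop_cfg("tau_step must be positive")
  if (cfg$n_surgeries <= 0) stop_cfg("n_surgeries must be positive")
  if (length(cfg$diabetes_ref_bmi_range) != 2 ||
      diff(cfg$diabetes_ref_bmi_range) <= 0) {
    stop_cfg("diabetes_ref_bmi_range must be an increasing pair")
  }
  if (!is.null(cfg$diabetes_anchors)) {
    a <- as_anchor_matrix(cfg$diabetes_anchors)
    if (any(diff(a[, 1]) <= 0) || any(diff(a[, 2]) <= 0)) {
      stop_cfg("diabetes_anchors must be strictly increasing in both BMI and probability")
    }
    if (any(a[, 2] < 0 | a[, 2] > 1)) {
      stop_cfg("diabetes_anchors probabilities must be in [0, 1]")
    }
  }
  invisible(cfg)
}

# Normalize anchors given as a matrix, data frame, or list of pairs to an
# n x 2 numeric matrix (bmi, probability).
as_anchor_matrix <- function(anchors) {
  if (is.data.frame(anchors)) anchors <- as.matrix(anchors[, 1:2])
  if (is.list(anchors)) anchors <- do.call(rbind, lapply(anchors, as.numeric))
  anchors <- matrix(as.numeric(anchors), ncol = 2)
  anchors[order(anchors[, 1]), , drop = FALSE]
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file is a flat mapping whose keys are exactly the arguments of
#' [sim_config()]; unknown keys are an error (they are almost always typos,
#' and a silently ignored parameter would be worse). Missing keys take the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML or JSON
#'
#' @param cfg A `"sim_config"`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  population: %d (eligibility BMI >= %g, ideal BMI %g)\n",
              x$n_population, x$bmi_eligibility, x$ideal_bmi))
  cat(sprintf("  PEWL: N(%g, %g^2), weight association %+g\n",
              x$pewl_mean, x$pewl_sd,
              x$pewl_weight_assoc_sign * x$pewl_weight_assoc))
  cat(sprintf("  predictor: N(%g, %g^2), corr with PEWL %g\n",
              x$predictor_mean, x$predictor_sd, x$predictor_pewl_corr))
  cat(sprintf("  diabetes map: %s (target eligible mean %g)\n",
              x$diabetes_map_strategy, x$diabetes_target_eligible_mean))
  cat(sprintf("  adverse events: %s covariate (target mean %g)\n",
              x$ae_covariate, x$ae_target_mean))
  cat(sprintf("  budget: %d surgeries; tau sweep %g..%g by %g; seed %d\n",
              x$n_surgeries, x$tau_min, x$tau_max, x$tau_step, x$rng_seed))
  invisible(x)
}

# Per-stage substream seeds, derived deterministically from the master seed
# so stage-level reruns match full-pipeline runs. Offsets are fixed and
# documented: population 0, PEWL 1, predictor 2. Kept within 32-bit range.
stage_seed <- function(seed, stage = c("population", "pewl", "predictor")) {
  stage <- match.arg(stage)
  offset <- c(population = 0L, pewl = 1L, predictor = 2L)[[stage]]
  as.integer((as.numeric(seed) * 7L + offset) %% .Machine$integer.max)
}
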