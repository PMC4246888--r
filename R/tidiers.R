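#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a threshold sweep
#'
#' Long format: one row per (threshold, outcome, comparator) with the
#' prevented-case count, convenient for ggplot2 and dplyr summaries.
#'
#' @param x A `"threshold_sweep"`.
#' @param ... Unused.
#' @return A tibble `tau`, `outcome`, `comparator`, `n_prevented`.
#' @exportS3Method
tidy.threshold_sweep <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "tau",
                  dplyr::starts_with("n_prevented_")),
    -"tau", names_to = "key", values_to = "n_prevented")
  long$outcome <- ifelse(grepl("t2dm", long$key), "t2dm", "ae")
  long$comparator <- ifelse(grepl("random_allocation", long$key),
                            "random_allocation", "untreated_baseline")
  dplyr::select(long, "tau", "outcome", "comparator", "n_prevented")
}

#' Summarize a threshold sweep in one row
#'
#' @param x A `"threshold_sweep"`.
#' @param ... Unused.
#' @return A one-row tibble: number of thresholds, threshold range, budget,
#'   and the maximum prevented T2DM / adverse-event counts under the
#'   random-allocation comparator.
#' @exportS3Method
glance.threshold_sweep <- function(x, ...) {
  tibble::tibble(
    n_thresholds = nrow(x),
    tau_min = min(x$tau),
    tau_max = max(x$tau),
    n_surgeries = attr(x, "n_surgeries"),
    max_prevented_t2dm = max(x$n_prevented_t2dm_random_allocation,
                             na.rm = TRUE),
    max_prevented_ae = max(x$n_prevented_ae_random_allocation, na.rm = TRUE)
  )
}

#' Tabulate a diabetes risk map
#'
#' @param x A `"diabetes_map"`.
#' @param n Number of grid points over the supported BMI range.
#' @param ... Unused.
#' @return A tibble `bmi`, `probability`.
#' @exportS3Method
tidy.diabetes_map <- function(x, n = 200, ...) {
  bmi <- seq(x$bmi_min, x$bmi_max, length.out = n)
  tibble::tibble(bmi = bmi, probability = evaluate_diabetes_risk(x, bmi))
}

#' @exportS3Method
glance.diabetes_map <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, bmi_min = x$bmi_min,
                 bmi_max = x$bmi_max, logodds_offset = x$offset)
}

#' @exportS3Method
tidy.ae_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("z(", x$column, ")"), "is_male"),
    estimate = c(x$intercept, x$coef_covariate, x$coef_male)
  )
}

#' @exportS3Method
glance.ae_model <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, center = x$center,
                 scale = x$scale, target_mean = x$target_mean)
}

#' One-row summary of a pipeline run
#'
#' @param x A `"run_manifest"`.
#' @param ... Unused.
#' @return A one-row tibble of the headline numbers: eligible-cohort size,
#'   mean risks, predictor accuracy, and prevented T2DM cases at the top of
#'   the threshold sweep under both comparators.
#' @exportS3Method
glance.run_manifest <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_eligible = s$n_eligible,
    mean_ae_probability = s$mean_ae_probability,
    mean_t2dm_untreated = s$mean_t2dm_untreated,
    corr_predicted_actual_pewl = s$corr_predicted_actual_pewl,
    tau_ref = s$n_prevented_t2dm_at_tau_max$tau,
    n_prevented_t2dm_random_allocation =
      s$n_prevented_t2dm_at_tau_max$random_allocation,
    n_prevented_t2dm_untreated_baseline =
      s$n_prevented_t2dm_at_tau_max$untreated_baseline
  )
}
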