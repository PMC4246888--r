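# Pull the per-subject treated / untreated case probabilities for an
# outcome. Untreated subjects cannot experience a surgical adverse event,
# so the untreated AE probability is identically zero.
outcome_probs <- function(df, outcome = c("t2dm", "ae")) {
  outcome <- match.arg(outcome)
  if (outcome == "t2dm") {
    list(treated = df$p_t2dm_treated, untreated = df$p_t2dm_untreated)
  } else {
    list(treated = df$p_adverse_event, untreated = rep(0, nrow(df)))
  }
}

#' Assemble the decision-analysis frame
#'
#' Joins outcomes and risk profiles on `subject_id` into the single
#' per-subject table the decision operations consume.
#'
#' @param outcomes Tibble from [simulate_outcomes()].
#' @param risks Tibble from [compute_risk_profiles()].
#' @return A tibble with one row per eligible subject.
#' @export
decision_frame <- function(outcomes, risks) {
  dplyr::inner_join(tibble::as_tibble(outcomes), tibble::as_tibble(risks),
                    by = "subject_id")
}

#' Population case probability at a decision threshold
#'
#' Implements the published population-level case probability: subjects
#' with predicted PEWL strictly above `tau` form the treated group and
#' contribute their treated case probabilities; subjects strictly below
#' (and, by convention, exactly at) `tau` form the untreated group and
#' contribute their untreated probabilities. The default returns the
#' unweighted average of the two group means, exactly as the formula is
#' printed; `weighted = TRUE` instead weights the group means by group
#' size (the population mean). When one group is empty the mean of the
#' nonempty group is returned, since the printed formula is undefined there
#' and halving it would introduce a discontinuity.
#'
#' @param df Decision frame (see [decision_frame()]): needs
#'   `predicted_pewl` and the risk columns.
#' @param tau Decision threshold on predicted PEWL (%).
#' @param outcome `"t2dm"` or `"ae"`.
#' @param weighted Population-size-weighted variant.
#' @return A single probability.
#' @export
population_case_probability <- function(df, tau, outcome = c("t2dm", "ae"),
                                        weighted = FALSE) {
  if (nrow(df) == 0) stop("no eligible subjects", call. = FALSE)
  pr <- outcome_probs(df, outcome)
  treated <- df$predicted_pewl > tau
  n_t <- sum(treated)
  n_u <- nrow(df) - n_t
  if (n_t == 0) return(mean(pr$untreated))
  if (n_u == 0) return(mean(pr$treated))
  m_t <- mean(pr$treated[treated])
  m_u <- mean(pr$untreated[!treated])
  if (weighted) {
    (n_t * m_t + n_u * m_u) / (n_t + n_u)
  } else {
    (m_t + m_u) / 2
  }
}

#' Allocate the surgical budget at a threshold
#'
#' Subjects with predicted PEWL strictly above `tau` are ranked from
#' highest to lowest prediction and the top `n_surgeries` are allocated
#' surgery. Ties in the prediction are broken by ascending subject id so
#' the allocation is deterministic. Fewer than `n_surgeries` subjects may
#' qualify at high thresholds.
#'
#' @param df Decision frame with `subject_id` and `predicted_pewl`.
#' @param tau Decision threshold (%).
#' @param n_surgeries Maximum number of surgeries.
#' @return Vector of treated subject ids (possibly empty).
#' @export
allocate_surgeries <- function(df, tau, n_surgeries) {
  stopifnot(n_surgeries > 0)
  above <- dplyr::filter(df, .data$predicted_pewl > tau)
  above <- dplyr::arrange(above, dplyr::desc(.data$predicted_pewl),
                          .data$subject_id)
  utils::head(above$subject_id, n_surgeries)
}

#' Additional cases prevented by test-guided allocation
#'
#' Number of additional cases prevented, at threshold `tau`, by spending
#' the fixed surgical budget on the subjects with the highest predicted
#' PEWL above `tau`, relative to a no-test policy. Two comparators are
#' supported:
#' \describe{
#'   \item{`random_allocation`}{the same `n_surgeries` surgeries are
#'     performed first-come-first-serve, i.e. on a random draw of the
#'     eligible cohort, whose expected per-subject treated risk is the
#'     cohort mean: `N = n_surgeries * (mean treated risk over the cohort -
#'     mean treated risk over the allocated set)`.}
#'   \item{`untreated_baseline`}{the literal printed comparison against
#'     nobody being treated: `N = n_surgeries * (mean untreated risk over
#'     the cohort - mean treated risk over the allocated set)`.}
#' }
#' `random_allocation` is the default because the no-test policy is
#' described as treating the same number of patients first-come-first-serve
#' with the same finite resources.
#'
#' @param df Decision frame.
#' @param tau Decision threshold (%).
#' @param n_surgeries Surgical budget.
#' @param outcome `"t2dm"` or `"ae"`.
#' @param comparator `"random_allocation"` or `"untreated_baseline"`.
#' @return Expected additional cases prevented (may be fractional).
#' @export
cases_prevented <- function(df, tau, n_surgeries,
                            outcome = c("t2dm", "ae"),
                            comparator = c("random_allocation",
                                           "untreated_baseline")) {
  comparator <- match.arg(comparator)
  pr <- outcome_probs(df, outcome)
  treated_ids <- allocate_surgeries(df, tau, n_surgeries)
  if (length(treated_ids) == 0) {
    stop("no subjects above threshold: cases prevented undefined",
         call. = FALSE)
  }
  sel <- df$subject_id %in% treated_ids
  baseline <- if (comparator == "random_allocation") {
    mean(pr$treated)
  } else {
    mean(pr$untreated)
  }
  n_surgeries * (baseline - mean(pr$treated[sel]))
}

#' Threshold sweep
#'
#' Evaluates the population case probability and the
#' additional-cases-prevented quantities for both outcomes (T2DM and
#' adverse events) and both comparators over the configured grid of
#' decision thresholds. `n_treated` counts all subjects above the
#' threshold (before the budget cap, so `n_treated + n_untreated` equals
#' the eligible-cohort size); the cap applies inside the cases-prevented
#' columns. Thresholds at which no subject qualifies get `NA` prevented
#' counts rather than failing the sweep.
#'
#' @param df Decision frame.
#' @param config A [sim_config()] (threshold grid, budget, weighting).
#' @return A tibble of class `"threshold_sweep"`, one row per threshold:
#'   `tau`, `n_treated`, `n_untreated`, `p_case_t2dm`, `p_case_ae`, and
#'   `n_prevented_<outcome>_<comparator>` for the four combinations.
#' @examples
#' cfg <- sim_config(n_population = 20000)
#' eligible <- filter_eligible(simulate_population(cfg))
#' outcomes <- simulate_outcomes(eligible, cfg)
#' risks <- compute_risk_profiles(eligible, outcomes,
#'                                build_risk_models(eligible, cfg))
#' sweep <- threshold_sweep(decision_frame(outcomes, risks), cfg)
#' @export
threshold_sweep <- function(df, config) {
  taus <- seq(config$tau_min, config$tau_max, by = config$tau_step)
  prevented <- function(tau, outcome, comparator) {
    tryCatch(
      cases_prevented(df, tau, config$n_surgeries, outcome, comparator),
      error = function(e) NA_real_
    )
  }
  res <- purrr::map_dfr(taus, function(tau) {
    n_t <- sum(df$predicted_pewl > tau)
    tibble::tibble(
      tau = tau,
      n_treated = n_t,
      n_untreated = nrow(df) - n_t,
      p_case_t2dm = population_case_probability(df, tau, "t2dm",
                                                config$eq1_weighted),
      p_case_ae = population_case_probability(df, tau, "ae",
                                              config$eq1_weighted),
      n_prevented_t2dm_untreated_baseline =
        prevented(tau, "t2dm", "untreated_baseline"),
      n_prevented_t2dm_random_allocation =
        prevented(tau, "t2dm", "random_allocation"),
      n_prevented_ae_untreated_baseline =
        prevented(tau, "ae", "untreated_baseline"),
      n_prevented_ae_random_allocation =
        prevented(tau, "ae", "random_allocation")
    )
  })
  class(res) <- c("threshold_sweep", class(res))
  attr(res, "n_surgeries") <- config$n_surgeries
  res
}

#' Conditional risk curves for individual decision support
#'
#' Smooth estimates of the probability of diabetes with and without surgery
#' as a function of the genomic prediction, obtained by smoothing splines
#' (generalized cross-validation selects the effective degrees of freedom)
#' fitted to the per-subject treated and untreated probabilities against
#' predicted PEWL. Estimates are clipped to \[0, 1\] and the grid must lie
#' within the observed predictor range (no extrapolation).
#'
#' @param df Decision frame (at least 10 subjects).
#' @param grid Predictor values at which to evaluate the curves; defaults
#'   to 100 equally spaced points over the observed range.
#' @return A tibble of class `"decision_curve"` with columns
#'   `predicted_pewl`, `p_t2dm_treated`, `p_t2dm_untreated`.
#' @export
conditional_risk_curves <- function(df, grid = NULL) {
  if (nrow(df) < 10) {
    stop("conditional risk curves need at least 10 subjects", call. = FALSE)
  }
  rng <- range(df$predicted_pewl)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  if (any(grid < rng[1]) || any(grid > rng[2])) {
    stop("grid extends outside the observed predictor range", call. = FALSE)
  }
  smooth_curve <- function(y) {
    if (stats::sd(y) == 0) return(rep(y[1], length(grid)))
    fit <- stats::smooth.spline(df$predicted_pewl, y, cv = FALSE)
    pmin(pmax(stats::predict(fit, grid)$y, 0), 1)
  }
  res <- tibble::tibble(
    predicted_pewl = grid,
    p_t2dm_treated = smooth_curve(df$p_t2dm_treated),
    p_t2dm_untreated = smooth_curve(df$p_t2dm_untreated)
  )
  class(res) <- c("decision_curve", class(res))
  res
}
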