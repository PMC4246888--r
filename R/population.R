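#' Simulate the population cohort
#'
#' Draws `n_population` subjects from the anthropometric model: height and
#' log-weight are bivariate normal with the female location/shape parameters,
#' sex is assigned by a uniform draw against `male_fraction_cutoff`, male
#' offsets are added to height (cm) and weight (kg) on the natural scales
#' after exponentiating log-weight, and outliers (weight > `weight_max`,
#' weight < `weight_min`, height < `height_min`) are then removed. Stream
#' order is fixed (sex draws first, then the bivariate draws) so results are
#' reproducible given `(config, seed)`.
#'
#' Because outliers are dropped rather than resampled, the returned cohort
#' may be slightly smaller than `n_population`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this stage; defaults to the population
#'   substream of `config$rng_seed`.
#' @return A tibble of subjects with columns `id`, `is_male`, `height_cm`,
#'   `weight_kg`, `bmi`, `ideal_weight_kg`, `excess_weight_kg`, `eligible`.
#' @examples
#' cohort <- simulate_population(sim_config(n_population = 5000), seed = 1)
#' mean(cohort$eligible)
#' @export
simulate_population <- function(config,
                                seed = stage_seed(config$rng_seed, "population")) {
  validate_sim_config(config)
  n <- as.integer(config$n_population)

  cov_hl <- if (config$cov_is_correlation) {
    config$height_logweight_cov * config$height_sd_f * config$logweight_sd_f
  } else {
    config$height_logweight_cov
  }
  Sigma <- matrix(c(config$height_sd_f^2, cov_hl,
                    cov_hl, config$logweight_sd_f^2), 2, 2)

  set.seed(seed)
  is_male <- stats::runif(n) > config$male_fraction_cutoff
  draws <- MASS::mvrnorm(n, mu = c(config$height_mean_f,
                                   config$logweight_mean_f),
                         Sigma = Sigma)
  if (n == 1) draws <- matrix(draws, nrow = 1)

  height <- draws[, 1]
  weight <- exp(draws[, 2])
  height[is_male] <- height[is_male] + config$male_height_offset
  weight[is_male] <- weight[is_male] + config$male_weight_offset

  subjects <- tibble::tibble(
    id = seq_len(n),
    is_male = is_male,
    height_cm = height,
    weight_kg = weight
  )
  subjects <- dplyr::filter(
    subjects,
    .data$weight_kg <= config$weight_max,
    .data$weight_kg >= config$weight_min,
    .data$height_cm >= config$height_min
  )
  derive_body_measures(subjects, config)
}

#' Derive BMI, ideal weight, excess weight and eligibility
#'
#' Fills the body-measure columns from height and weight: BMI is
#' weight / (height in m)^2; ideal weight is the weight at `ideal_bmi` for
#' the subject's height; excess weight is weight minus ideal weight (may be
#' negative below the ideal BMI); eligibility is BMI at or above
#' `bmi_eligibility` (the cutoff is inclusive).
#'
#' @param subjects A data frame with `height_cm` and `weight_kg` columns.
#' @param config A [sim_config()] (only `ideal_bmi` and `bmi_eligibility`
#'   are used).
#' @return `subjects` as a tibble with `bmi`, `ideal_weight_kg`,
#'   `excess_weight_kg` and `eligible` columns added (recomputed if present).
#' @export
derive_body_measures <- function(subjects, config = sim_config()) {
  stopifnot(all(c("height_cm", "weight_kg") %in% names(subjects)))
  if (any(subjects$height_cm <= 0) || any(subjects$weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  h_m2 <- (subjects$height_cm / 100)^2
  dplyr::mutate(
    tibble::as_tibble(subjects),
    bmi = .data$weight_kg / h_m2,
    ideal_weight_kg = config$ideal_bmi * h_m2,
    excess_weight_kg = .data$weight_kg - .data$ideal_weight_kg,
    eligible = .data$bmi >= config$bmi_eligibility
  )
}

#' Filter to the surgery-eligible cohort
#'
#' Returns exactly the subjects flagged eligible (BMI at or above the
#' cutoff), preserving input order.
#'
#' @param subjects A cohort with an `eligible` column (see
#'   [derive_body_measures()]).
#' @return The eligible subset as a tibble.
#' @export
filter_eligible <- function(subjects) {
  stopifnot("eligible" %in% names(subjects))
  dplyr::filter(tibble::as_tibble(subjects), .data$eligible)
}
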