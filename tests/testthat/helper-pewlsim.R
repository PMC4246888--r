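# Shared fixtures, all built in code.

# Down-scaled configuration for fast unit tests; full-scale runs live in
# the acceptance tests.
small_config <- function(...) {
  args <- list(...)
  if (is.null(args$n_population)) args$n_population <- 20000
  do.call(sim_config, args)
}

# Disable the outlier filters so distribution parameters can be measured on
# the raw draws (the filters truncate the lower height tail, which biases
# the kept female height mean upward by about 0.1 cm).
unfiltered_config <- function(...) {
  args <- list(weight_min = 0, weight_max = 1e9, height_min = 0, ...)
  do.call(sim_config, args)
}

small_eligible <- function(seed = 101, ...) {
  cfg <- small_config(rng_seed = seed, ...)
  filter_eligible(simulate_population(cfg))
}

# Hand-buildable decision frame: predictions and per-subject probabilities
# given directly.
toy_frame <- function(pred, p_t, p_u, p_ae = rep(0.05, length(pred)),
                      id = seq_along(pred)) {
  tibble::tibble(
    subject_id = id,
    predicted_pewl = pred,
    p_t2dm_treated = p_t,
    p_t2dm_untreated = p_u,
    p_adverse_event = p_ae
  )
}

# Naive transcription of the printed population-level case probability:
# average of the treated-group mean (alpha > tau, treated probabilities)
# and the untreated-group mean (alpha < tau or alpha == tau, untreated
# probabilities), written with explicit loops, independent of the package
# implementation.
naive_case_probability <- function(pred, p_t, p_u, tau) {
  st <- 0; nt <- 0; su <- 0; nu <- 0
  for (i in seq_along(pred)) {
    if (pred[i] > tau) {
      st <- st + p_t[i]; nt <- nt + 1
    } else {
      su <- su + p_u[i]; nu <- nu + 1
    }
  }
  if (nt == 0) return(su / nu)
  if (nu == 0) return(st / nt)
  (st / nt + su / nu) / 2
}

# Count-based empirical CDF over a reference vector: fraction of reference
# values at or below x, on the (rank - 1) / (n - 1) convention with the
# same 1e-9 tie tolerance the package documents.
naive_ecdf <- function(ref, x) {
  vapply(x, function(xi) (sum(ref <= xi + 1e-9) - 1) / (length(ref) - 1),
         numeric(1))
}
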