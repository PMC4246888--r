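sweep_required_cols <- c("tau",
                         "n_prevented_t2dm_random_allocation",
                         "n_prevented_ae_random_allocation")

#' Plot prevented cases against the decision threshold
#'
#' Draws the clinical-utility figure: additional T2DM cases (red) and
#' adverse-event cases (blue) prevented by test-guided allocation of the
#' surgical budget, as a function of the decision threshold on predicted
#' PEWL. Columns are matched by name, so column order in a CSV is
#' irrelevant.
#'
#' @param sweep A `"threshold_sweep"` tibble, any data frame with the sweep
#'   columns, or a path to a sweep CSV.
#' @param output_path Optional figure file (`.png` or `.svg`); `NULL`
#'   returns the ggplot only.
#' @param comparator Which prevented-cases comparator to plot.
#' @param width,height Figure size in inches when writing a file.
#' @return The ggplot object, invisibly when a file is written.
#' @export
plot_sweep <- function(sweep, output_path = NULL,
                       comparator = c("random_allocation",
                                      "untreated_baseline"),
                       width = 6, height = 4) {
  comparator <- match.arg(comparator)
  if (is.character(sweep)) sweep <- readr::read_csv(sweep, show_col_types = FALSE)
  cols <- c("tau", paste0("n_prevented_t2dm_", comparator),
            paste0("n_prevented_ae_", comparator))
  missing <- setdiff(cols, names(sweep))
  if (length(missing)) {
    stop("sweep table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(sweep), dplyr::all_of(cols)),
    -"tau", names_to = "outcome", values_to = "n_prevented")
  long$outcome <- ifelse(grepl("t2dm", long$outcome), "T2DM",
                         "Adverse events")
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$tau, y = .data$n_prevented,
                                     colour = .data$outcome)) +
    ggplot2::geom_line(linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_point(size = 1.2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("T2DM" = "#c0392b",
                                            "Adverse events" = "#2166ac")) +
    ggplot2::labs(
      x = "Decision threshold on predicted excess weight loss (%)",
      y = "Additional cases prevented",
      colour = NULL,
      title = "Clinical utility of genomic prediction under a fixed surgical budget"
    ) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(output_path)) {
    ggplot2::ggsave(output_path, gg, width = width, height = height,
                    dpi = 150)
    return(invisible(output_path))
  }
  gg
}

#' @rdname plot_sweep
#' @param object A `"threshold_sweep"`.
#' @param ... Passed to [plot_sweep()].
#' @exportS3Method
autoplot.threshold_sweep <- function(object, ...) {
  plot_sweep(object, output_path = NULL, ...)
}

#' Plot conditional risk curves
#'
#' Probability of diabetes with and without surgery as a smooth function of
#' the genomic prediction of PEWL, for individual decision support.
#'
#' @param object A `"decision_curve"` from [conditional_risk_curves()].
#' @param ... Unused.
#' @exportS3Method
autoplot.decision_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"predicted_pewl",
                              names_to = "arm", values_to = "probability")
  long$arm <- ifelse(long$arm == "p_t2dm_treated", "With surgery",
                     "Without surgery")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$predicted_pewl,
                               y = .data$probability,
                               colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Predicted excess weight loss (%)",
                  y = "Lifetime T2DM probability", colour = NULL) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(legend.position = "bottom")
}
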