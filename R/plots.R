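# ggplot2 displays of the main result types.

#' Plot the distribution of ensemble scores
#'
#' Bar chart of how many patients received each ensemble score; the spikes
#' at 0 and M are the unanimously classified patients.
#'
#' @param scores Tibble from [ensemble_score()].
#' @return A ggplot object.
#' @export
plot_ensemble_scores <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("patient_id", "score", "n_variants") %in% names(scores))) {
    abort_input("`scores` must come from ensemble_score().")
  }
  M <- scores$n_variants[1]
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_bar(fill = "grey35") +
    ggplot2::scale_x_continuous(limits = c(-0.5, M + 0.5)) +
    ggplot2::labs(x = sprintf("ensemble score (high-risk votes of %d)", M),
                  y = "patients",
                  title = "Ensemble score distribution") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a risk classification
#'
#' @param survival Data frame with `patient_id`, `time`, `event`.
#' @param classification Risk-classification tibble; unclassified patients
#'   are excluded.
#' @return A ggplot object with one step curve per risk group.
#' @export
plot_kaplan_meier <- function(survival, classification) {
  km <- kaplan_meier(survival, classification)
  start <- dplyr::summarise(dplyr::group_by(km, .data$group),
                            time = 0, surv = 1, .groups = "drop")
  km2 <- dplyr::bind_rows(start, km[c("group", "time", "surv")])
  ggplot2::ggplot(km2, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "risk group",
                  title = "Kaplan-Meier survival by risk group") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble-size sweep
#'
#' Log2 mean hazard ratio (and mean percentage of patients classified) as a
#' function of the number of pipelines in the ensemble.
#'
#' @param object An `ensemble_sweep` from [sweep_ensemble_size()].
#' @param ... Unused.
#' @return A ggplot object (two panels combined with patchwork when the
#'   package is available, otherwise the hazard-ratio panel alone).
#' @method autoplot ensemble_sweep
#' @export
autoplot.ensemble_sweep <- function(object, ...) {
  s <- summarise_sweep(object)
  p_hr <- ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$log2_mean_hr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pipelines in ensemble",
                  y = "log2 mean hazard ratio") +
    ggplot2::theme_minimal()
  p_pct <- ggplot2::ggplot(s, ggplot2::aes(x = .data$n,
                                           y = .data$mean_pct_classified)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pipelines in ensemble", y = "% patients classified") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p_hr + patchwork::plot_spacer() + p_pct +
      patchwork::plot_layout(widths = c(1, 0.05, 1))
  } else {
    p_hr
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of inter-pipeline concordance
#'
#' @param concordance Variant x variant correlation matrix from
#'   [pipeline_concordance()].
#' @return A ggplot tile plot.
#' @export
plot_concordance <- function(concordance) {
  if (!is.matrix(concordance) || is.null(rownames(concordance))) {
    abort_input("`concordance` must be a named square matrix.")
  }
  d <- tibble::as_tibble(concordance, rownames = "variant_a")
  d <- tidyr::pivot_longer(d, -"variant_a", names_to = "variant_b",
                           values_to = "rho")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant_a, y = .data$variant_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = "Inter-pipeline concordance of per-gene q-values") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
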