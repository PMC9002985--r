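#' Forest plot of bootstrapped mediation effects
#'
#' One panel per outcome, effects on the y axis, sons and daughters
#' side by side, percentile intervals as horizontal ranges.
#'
#' @param object a `serimed_boot` object.
#' @param contrast which exposure contrast to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.serimed_boot <- function(object, contrast = "before_puberty", ...) {
  dat <- filter(object$effects, .data$contrast == !!contrast)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$effect,
                                    colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome), scales = "free_x") +
    ggplot2::labs(x = "effect (outcome units)", y = NULL, colour = NULL,
                  title = paste0("Natural effects: ", contrast, " vs never")) +
    ggplot2::theme_minimal()
}

#' Plot a confounder-sensitivity grid
#'
#' Match proportion and average absolute estimate difference against the
#' confounder strength, by number of confounders.
#'
#' @param grid tibble from [run_grid()].
#' @return a ggplot object.
#' @export
plot_sensitivity_grid <- function(grid) {
  long <- grid |>
    select("beta_u", "n_confounders", "match_proportion", "avg_abs_diff") |>
    tidyr::pivot_longer(c("match_proportion", "avg_abs_diff"),
                        names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta_u, y = .data$value,
                                     colour = factor(.data$n_confounders))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "confounder effect (beta_U)", y = NULL,
                  colour = "confounders") +
    ggplot2::theme_minimal()
}
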