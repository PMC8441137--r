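#' Decay-curve plot for a stage-1 fit
#'
#' Expected probability of data recovery against years since publication,
#' with the narrowest-interval ribbon, computed by [predict_recovery()] on
#' a dense age grid (the plotted curve and any tabulated prediction share
#' one computation path). Optionally overlays the observed per-age raw
#' recovery fractions, sized by the number of papers.
#'
#' @param object A `stage1_fit`.
#' @param ages Age grid.
#' @param study_type Type or `"marginal"`.
#' @param show_data Overlay observed per-age fractions.
#' @param mass Interval mass.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stage1_fit
#' @export
autoplot.stage1_fit <- function(object, ages = 0:26,
                                study_type = "marginal",
                                show_data = TRUE, mass = 0.89, ...) {
  curve <- predict_recovery(object, ages, study_type, mass = mass)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::labs(x = "years since publication",
                  y = "probability of data recovery") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (show_data) {
    obs <- object$data |>
      dplyr::filter(.data$age <= max(ages)) |>
      dplyr::group_by(.data$age) |>
      dplyr::summarise(frac = mean(.data$recovered), n = dplyr::n())
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(y = .data$frac, size = .data$n),
      shape = 1, show.legend = FALSE)
  }
  p
}

#' Posterior-density plot of the stage probabilities
#'
#' Density of the posterior draws of `p1`-`p4` and the combined rate
#' `p_r`, marginalised across the sample, mirroring the standard
#' presentation of staged reproducibility posteriors.
#'
#' @param object An `audit_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot audit_report
#' @export
autoplot.audit_report <- function(object, ...) {
  f1 <- object$stage1_fit; f234 <- object$stages_fit
  p1 <- pooled_recovery(f1, draws = TRUE)
  dens <- tibble::tibble(quantity = "p1", value = p1)
  if (!is.null(f234)) {
    p234 <- lapply(2:4, function(s)
      marginal_stage_prob(f234, s, draws = TRUE))
    n <- min(length(p1), lengths(p234))
    pr <- combined_rate(p1[seq_len(n)], p234[[1]][seq_len(n)],
                        p234[[2]][seq_len(n)], p234[[3]][seq_len(n)])
    dens <- dplyr::bind_rows(
      dens,
      tibble::tibble(quantity = "p2", value = p234[[1]]),
      tibble::tibble(quantity = "p3", value = p234[[2]]),
      tibble::tibble(quantity = "p4", value = p234[[3]]),
      tibble::tibble(quantity = "p_r", value = pr))
  }
  dens$quantity <- factor(dens$quantity, c("p1", "p2", "p3", "p4", "p_r"))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey70", colour = NA) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "probability", y = NULL) +
    ggplot2::theme_minimal()
}

#' Half-life plot by study type
#'
#' Posterior mean and narrowest interval of the data half-life for each
#' study type and pooled.
#'
#' @param fit A `stage1_fit` with the exponential link.
#' @param mass Interval mass.
#' @return A ggplot object.
#' @export
plot_half_lives <- function(fit, mass = 0.89) {
  hl <- half_life_table(fit, mass = mass)
  ggplot2::ggplot(hl, ggplot2::aes(x = .data$estimate,
                                   y = .data$study_type)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "data half-life (years)", y = NULL) +
    ggplot2::theme_minimal()
}
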