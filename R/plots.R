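#' Overlay of observed and fitted unlabeled-fraction time courses
#'
#' @param object An `mfa_fit`.
#' @param ... Unused.
#' @return A ggplot: one facet per observed metabolite, observed points
#'   with the fitted trajectory, time on a log axis.
#' @export
autoplot.mfa_fit <- function(object, ...) {
  obs <- object$dataset$timecourse
  pred <- object$predicted
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = pred, colour = "#B2182B") +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time after label switch (s)",
                  y = "unlabeled fractional content") +
    ggplot2::theme_minimal()
}

#' Simulated unlabeled-fraction trajectories
#'
#' @param object A `trajectory_set`.
#' @param ... Unused.
#' @return A ggplot of per-pool unlabeled fractions over time.
#' @export
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value,
                               colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "unlabeled fraction",
                  colour = "pool") +
    ggplot2::theme_minimal()
}
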