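# ggplot2 views of runs, fits and sweeps (semilog axes mirroring the usual
# presentation of swelling experiments).

#' Plot field profiles of a run
#'
#' Network fraction and ion concentration profiles at the recorded snapshot
#' times, faceted by field.
#'
#' @param object A `gel_run`.
#' @param fields Character vector of snapshot columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gel_run <- function(object,
                             fields = c("theta_n", "c_Na", "c_Ca",
                                        "b_Na", "b_C2", "alpha"),
                             ...) {
  long <- tidyr::pivot_longer(object$snapshots,
                              cols = dplyr::all_of(fields),
                              names_to = "field", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$value,
                                     colour = .data$time,
                                     group = .data$time)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "x (µm)", y = NULL, colour = "t (s)")
}

#' Plot the peak-density decay
#'
#' `delta_theta = theta_n_max - theta_n_ss` against time on a semilog axis.
#'
#' @param run A `gel_run` (or several, in a named list).
#' @return A ggplot.
#' @export
plot_delta_theta <- function(run) {
  runs <- if (inherits(run, "gel_run")) list(run = run) else run
  d <- purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(r$metrics, label = paste0(nm, " (", r$config$bath_Na, " M)"))
  })
  ggplot2::ggplot(dplyr::filter(d, .data$delta_theta > 0),
                  ggplot2::aes(.data$time, .data$delta_theta,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t (s)", y = expression(Delta * theta), colour = NULL)
}

#' @rdname fit_decay_rate
#' @param object A `gel_rate_fit`.
#' @export
autoplot.gel_rate_fit <- function(object, ...) {
  d <- object$data
  pred <- exp(predict(object$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$delta_L_inv)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = pred), linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "t (s)", y = expression(Delta * L^-1 ~ (mu * m^-1)),
      title = sprintf("gamma = %.3g /s", object$gamma))
}

#' @rdname gamma_sweep
#' @param object A `gel_sweep`.
#' @param ... Unused.
#' @export
autoplot.gel_sweep <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$gamma)),
                  ggplot2::aes(.data$bath_Na, .data$gamma,
                               colour = .data$case, group = .data$case)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bath Na (M)", y = expression(gamma ~ (s^-1)),
                  colour = NULL)
}

#' @importFrom stats predict
NULL
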