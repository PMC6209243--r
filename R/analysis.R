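# Quantification of swelling: peak-density decay, front tracking, the
# inverse-front-width scaling law, and exponential rate fitting.

# Internal front finder on raw vectors: rightmost downward crossing of the
# threshold, linearly interpolated between cell centers.
front_loc <- function(x, theta_n, threshold = 0.01) {
  n <- length(x)
  above <- theta_n > threshold
  below <- theta_n <= threshold
  cross <- which(above[-n] & below[-1])
  if (length(cross) == 0) return(NA_real_)
  i <- max(cross)
  x[i] + (threshold - theta_n[i]) * (x[i + 1] - x[i]) /
    (theta_n[i + 1] - theta_n[i])
}

#' Steady-state network fraction
#'
#' The network volume fraction of the uniform long-time state, fixed by mass
#' conservation: the domain average of the initial profile.
#'
#' @param data A data frame with a `theta_n` column (e.g. a snapshot from
#'   [as_tibble.gel_state()]) or a `gel_state`.
#' @return The scalar `theta_n_ss`.
#' @export
steady_state_fraction <- function(data) {
  if (inherits(data, "gel_state")) return(mean(data$theta_n))
  mean(data$theta_n)
}

#' Swelling-front location
#'
#' The rightmost location where the network volume fraction crosses the
#' threshold (0.01 by default: 99% solvent to the right of the front),
#' located by linear interpolation between adjacent cell centers.
#'
#' @param data A data frame with `x` and `theta_n` columns, or a `gel_state`.
#' @param threshold Network fraction defining the front.
#' @return The front position `L*` (um), or `NA` if the profile never
#'   crosses the threshold (front absent).
#' @export
front_location <- function(data, threshold = 0.01) {
  if (inherits(data, "gel_state")) {
    return(front_loc(data$x, data$theta_n, threshold))
  }
  front_loc(data$x, data$theta_n, threshold)
}

#' Fit the exponential front-decay rate
#'
#' Ordinary least-squares fit of `ln(delta_L_inv)` against time inside the
#' fit window, where `delta_L_inv = 1/L*(t) - 1/L` is the inverse-width
#' excess of the network globule. Under exponential relaxation of the peak
#' density, mass conservation makes `delta_L_inv` decay exponentially too;
#' the fitted decay rate `gamma = -slope` is the early-time swelling rate.
#' The window (default 0.2 to 0.8 s) excludes both the start-up transient
#' and the collapse when the front reaches the right wall.
#'
#' @param data A data frame with `time` and `delta_L_inv` columns (e.g.
#'   `tidy()` of a [run_gel()] result), or a `gel_run`.
#' @param window Numeric length-2 fit window in seconds.
#' @return An object of class `gel_rate_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods; `$gamma` is the decay rate (1/s).
#' @examples
#' t <- seq(0, 1, 0.01)
#' fit <- fit_decay_rate(tibble::tibble(time = t, delta_L_inv = exp(-3 * t)))
#' fit$gamma   # 3
#' @export
fit_decay_rate <- function(data, window = c(0.2, 0.8)) {
  if (inherits(data, "gel_run")) data <- data$metrics
  keep <- !is.na(data$delta_L_inv) & data$delta_L_inv > 0 &
    data$time >= window[1] - 1e-12 & data$time <= window[2] + 1e-12
  d <- data[keep, c("time", "delta_L_inv")]
  if (nrow(d) < 3) {
    abort("need at least 3 positive delta_L_inv samples inside the window")
  }
  fit <- lm(log(delta_L_inv) ~ time, data = d)
  structure(list(
    gamma = -unname(coef(fit)[2]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    window = window, n = nrow(d), data = d, model = fit
  ), class = "gel_rate_fit")
}

#' @export
print.gel_rate_fit <- function(x, ...) {
  cat(sprintf(
    "<gel_rate_fit> gamma = %.4g /s (R^2 = %.4f, %d points on [%g, %g] s)\n",
    x$gamma, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname fit_decay_rate
#' @param x A `gel_rate_fit`.
#' @param ... Unused.
#' @export
tidy.gel_rate_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble(term = c("log_amplitude", "gamma"),
         estimate = c(unname(coef(x$model)[1]), x$gamma),
         std.error = unname(s[, "Std. Error"]))
}

#' @rdname fit_decay_rate
#' @export
glance.gel_rate_fit <- function(x, ...) {
  tibble(gamma = x$gamma, r.squared = x$r_squared, nobs = x$n,
         window_lo = x$window[1], window_hi = x$window[2])
}

#' Swelling rate across bath sodium molarities
#'
#' Runs one swelling experiment per bath sodium concentration (chloride
#' re-balanced for electroneutrality each time), fits the front-decay rate on
#' each, and tabulates the results. Failures of individual runs are recorded
#' as `NA` rows and the sweep continues.
#'
#' @param bath_Na Vector of bath sodium molarities (M).
#' @param case Case preset name (see [case_presets()]).
#' @param window Fit window passed to [fit_decay_rate()].
#' @param ... Further arguments to [gel_config()] (e.g. `n_cells`, `t_end`).
#' @return A tibble of class `gel_sweep` with columns `case`, `bath_Na`,
#'   `gamma`, `r_squared`, `error`.
#' @export
gamma_sweep <- function(bath_Na, case = "sparse_Na_preferred",
                        window = c(0.2, 0.8), ...) {
  rows <- purrr::map(bath_Na, function(m) {
    res <- tryCatch({
      run <- run_gel(gel_config(case = case, bath_Na = m, ...))
      fit <- fit_decay_rate(run, window)
      tibble(case = case, bath_Na = m, gamma = fit$gamma,
             r_squared = fit$r_squared, error = NA_character_)
    }, error = function(e) {
      tibble(case = case, bath_Na = m, gamma = NA_real_,
             r_squared = NA_real_, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gel_sweep", class(out))
  out
}
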