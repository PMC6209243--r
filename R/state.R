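# Spatial state of the gel on a staggered 1D grid: scalars (volume fractions,
# concentrations, potential) at cell centers, velocities at faces. Faces are
# numbered 0..n (walls included); velocity vectors have length n + 1 with
# zeros pinned at both walls.

new_gel_state <- function(x, h, theta_n, c_Na, c_Ca, c_Cl,
                          b_Na, b_Ca, b_C2, Psi, time = 0) {
  n <- length(x)
  structure(list(
    x = x, h = h, n = n, time = time,
    theta_n = theta_n,
    c_Na = c_Na, c_Ca = c_Ca, c_Cl = c_Cl,
    b_Na = b_Na, b_Ca = b_Ca, b_C2 = b_C2,
    Psi = Psi,
    u_n = numeric(n + 1), u_s = numeric(n + 1)
  ), class = "gel_state")
}

#' @export
print.gel_state <- function(x, ...) {
  cat(sprintf("<gel_state> t = %.4g s, %d cells, theta_n in [%.3g, %.3g]\n",
              x$time, x$n, min(x$theta_n), max(x$theta_n)))
  invisible(x)
}

#' Tidy view of a gel state
#'
#' One row per grid cell with the volume fractions, dissolved and bound
#' concentrations, electric potential, and the derived free-site density,
#' crosslink fraction and interaction parameter.
#'
#' @param x A `gel_state`.
#' @param config The run configuration (supplies `z_tilde` and energies for
#'   the derived columns); optional.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.gel_state <- function(x, config = NULL, ...) {
  st <- x
  out <- tibble(
    time = st$time, x = st$x,
    theta_n = st$theta_n, theta_s = 1 - st$theta_n,
    c_Na = st$c_Na, c_Ca = st$c_Ca, c_Cl = st$c_Cl,
    b_Na = st$b_Na, b_Ca = st$b_Ca, b_C2 = st$b_C2,
    Psi = st$Psi
  )
  if (!is.null(config)) {
    out$M_free <- free_site_density(x$theta_n, x$b_Na, x$b_Ca, x$b_C2,
                                    config$z_tilde, tol = 1e-6)
    out$alpha <- crosslink_fraction(x$b_C2, x$theta_n, config$z_tilde,
                                    tol = 1e-6)
    out$I <- interaction_parameter(out$alpha, config$energies, tol = 1e-6)
  }
  out
}

# Net charge density per total volume (should vanish pointwise):
# theta_s * (c_Na + 2 c_Ca - c_Cl) - M + b_Ca.
charge_density <- function(state, z_tilde) {
  theta_s <- 1 - state$theta_n
  M <- z_tilde * state$theta_n - state$b_Na - state$b_Ca - 2 * state$b_C2
  theta_s * (state$c_Na + 2 * state$c_Ca - state$c_Cl) - M + state$b_Ca
}

# Integrated elemental content and network volume (per unit cross-section).
conservation_totals <- function(state) {
  theta_s <- 1 - state$theta_n
  h <- state$h
  c(network = h * sum(state$theta_n),
    Na = h * sum(theta_s * state$c_Na + state$b_Na),
    Ca = h * sum(theta_s * state$c_Ca + state$b_Ca + state$b_C2),
    Cl = h * sum(theta_s * state$c_Cl))
}

#' Check gel-state invariants
#'
#' Verifies positivity, the volume-fraction constraint, the site balance and
#' pointwise electroneutrality of a state; errors with a description of the
#' worst violation if any check fails.
#'
#' @param state A `gel_state`.
#' @param config The run configuration.
#' @param charge_tol Tolerance on `max |charge| / max |c|`.
#' @return `state`, invisibly.
#' @export
check_gel_state <- function(state, config, charge_tol = 1e-6) {
  if (any(state$theta_n <= 0 | state$theta_n >= 1)) {
    abort("theta_n out of (0, 1)")
  }
  conc <- c(state$c_Na, state$c_Ca, state$c_Cl,
            state$b_Na, state$b_Ca, state$b_C2)
  if (any(conc < -1e-12)) abort("negative concentration")
  M <- free_site_density(state$theta_n, state$b_Na, state$b_Ca, state$b_C2,
                         config$z_tilde, tol = 1e-8)
  q <- charge_density(state, config$z_tilde)
  rel <- max(abs(q)) / max(abs(state$c_Na), abs(state$c_Cl))
  if (rel > charge_tol) {
    abort(sprintf("electroneutrality violated: relative charge %.3e", rel))
  }
  invisible(state)
}

# --- small numerics helpers --------------------------------------------------

# Tridiagonal (Thomas) solve; lower[i] multiplies x[i-1], upper[i] x[i+1].
thomas_solve <- function(lower, diag, upper, rhs) {
  m <- length(diag)
  if (m == 1L) return(rhs / diag)
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:m) {
    den <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / den
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / den
  }
  x <- numeric(m)
  x[m] <- dp[m]
  for (i in (m - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Face average of a cell-centered field (interior faces, length n - 1).
face_mean <- function(v) 0.5 * (v[-length(v)] + v[-1])

# Difference across interior faces: v[i+1] - v[i], length n - 1.
face_diff <- function(v) diff(v)
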