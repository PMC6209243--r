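# Shared fixtures. Expensive simulations are memoized in a session-level
# cache so several test files can interrogate the same run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# The reference experiment: sparse binding, sodium preferred, 0.02 M bath
# sodium. t_end = 1.6 s covers the fit window, the front's arrival at the
# right wall, and the onset of the late-time exponential relaxation.
exemplar_run <- function(n_cells = 256, t_end = 1.6) {
  cached(sprintf("exemplar_%d_%g", n_cells, t_end), {
    run_gel(gel_config("sparse_Na_preferred", bath_Na = 0.02,
                       n_cells = n_cells, t_end = t_end))
  })
}

# A spatially uniform composition at its binding equilibrium, used for
# fixed-point and stationarity checks.
uniform_equilibrium_state <- function(config, theta_n = 0.1,
                                      T_Na = 0.02, T_Ca = 0.003) {
  T_Cl <- electroneutral_chloride(T_Na, T_Ca, theta_n, config$z_tilde)
  eq <- solve_equilibrium(
    tibble::tibble(T_Na = T_Na, T_Ca = T_Ca, T_Cl = T_Cl),
    config$ions, config$z_tilde, theta_n = theta_n)
  n <- config$n_cells
  h <- config$L / n
  st <- gelswell:::new_gel_state(
    x = (seq_len(n) - 0.5) * h, h = h,
    theta_n = rep(theta_n, n),
    c_Na = rep(eq$c_Na, n), c_Ca = rep(eq$c_Ca, n), c_Cl = rep(eq$c_Cl, n),
    b_Na = rep(eq$b_Na, n), b_Ca = rep(eq$b_Ca, n), b_C2 = rep(eq$b_C2, n),
    Psi = numeric(n))
  st
}

# Binary NaCl diffusion with unequal diffusivities against the classical
# electroneutral single-mode decay with D_amb = 2 D_Na D_Cl/(D_Na + D_Cl);
# returns the L2 error of the simulated sodium profile.
ambipolar_error_acc <- function(n, dt, t_end = 0.05) {
  cfg <- gel_config("sparse_Na_preferred", n_cells = n)
  cfg$ions <- ion_set(0, 0, 0, 0, D_Na = 2.5e3, D_Ca = 2.5e3, D_Cl = 1e3)
  h <- cfg$L / n
  x <- (seq_len(n) - 0.5) * h
  c0 <- 0.05 + 0.02 * cos(pi * x / cfg$L)
  st <- gelswell:::new_gel_state(
    x = x, h = h, theta_n = rep(1e-9, n),
    c_Na = c0, c_Ca = rep(0, n), c_Cl = c0,
    b_Na = rep(0, n), b_Ca = rep(0, n), b_C2 = rep(0, n), Psi = numeric(n))
  st$Psi <- solve_electric_potential(st, cfg)
  u0 <- numeric(n + 1)
  for (k in seq_len(round(t_end / dt))) {
    st <- advance_ions(st, u0, u0, dt, cfg)
    if (gelswell:::is_step_reject(st)) stop("ion update rejected")
  }
  D_amb <- 2 * 2.5e3 * 1e3 / (2.5e3 + 1e3)
  exact <- 0.05 + 0.02 * cos(pi * x / cfg$L) *
    exp(-D_amb * (pi / cfg$L)^2 * t_end)
  sqrt(mean((st$c_Na - exact)^2))
}

# Random admissible well-mixed totals for property checks.
random_totals <- function(n, z_tilde = 0.1, theta_n = 0.5) {
  tibble::tibble(
    T_Na = stats::runif(n, 1e-4, 0.05),
    T_Ca = stats::runif(n, 1e-4, 0.05),
    theta_n = stats::runif(n, 0.05, 0.7)
  )
}
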