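# Initial-condition construction and the split time step:
# mechanics -> network advection -> ion transport with potential closure ->
# implicit reactions.

#' Build the initial condition
#'
#' Constructs the initial spatial profiles: a dense, highly crosslinked inner
#' region at the left of the domain and an essentially network-free bath,
#' joined by a tanh transition centered at `x0`. The inner and bath
#' compositions are each placed at their well-mixed binding equilibrium (via
#' [solve_equilibrium()]) and the conserved quantities (network fraction,
#' solvent-weighted dissolved content, bound concentrations) are blended with
#' the same tanh profile, which keeps the blended state exactly electroneutral
#' pointwise. Bath chloride balances the bath cations.
#'
#' @param config A [gel_config()].
#' @return A `gel_state` at `time = 0`.
#' @export
build_initial_condition <- function(config) {
  n <- config$n_cells
  h <- config$L / n
  x <- (seq_len(n) - 0.5) * h

  inner <- solve_equilibrium(
    tibble(T_Na = config$inner$T_Na, T_Ca = config$inner$T_Ca,
           T_Cl = config$inner$T_Cl),
    config$ions, config$z_tilde, theta_n = config$theta_inner
  )
  bath <- solve_equilibrium(
    tibble(T_Na = config$bath_Na, T_Ca = config$bath_Ca,
           T_Cl = bath_chloride(config)),
    config$ions, config$z_tilde, theta_n = config$theta_bath
  )

  w <- 0.5 * (1 - tanh((x - config$x0) / config$front_width))
  theta_n <- config$theta_bath + (config$theta_inner - config$theta_bath) * w
  theta_s <- 1 - theta_n
  qmix <- function(col) {
    w * (inner$theta_s * inner[[col]]) + (1 - w) * (bath$theta_s * bath[[col]])
  }
  bmix <- function(col) w * inner[[col]] + (1 - w) * bath[[col]]

  st <- new_gel_state(
    x = x, h = h, theta_n = theta_n,
    c_Na = qmix("c_Na") / theta_s,
    c_Ca = qmix("c_Ca") / theta_s,
    c_Cl = qmix("c_Cl") / theta_s,
    b_Na = bmix("b_Na"), b_Ca = bmix("b_Ca"), b_C2 = bmix("b_C2"),
    Psi = numeric(n)
  )
  st$Psi <- solve_electric_potential(st, config)
  check_gel_state(st, config)
  st
}

#' One split time step
#'
#' Advances the state by `dt`: (1) solve the quasi-static velocities;
#' (2) advect the network fraction conservatively; (3) advect, diffuse and
#' drift the ions with the electroneutrality re-closure; (4) apply the stiff
#' binding reactions implicitly. Returns either the new state or a rejection
#' object (CFL or solver failure) that the caller answers by halving `dt`.
#'
#' @param state A `gel_state`.
#' @param config A [gel_config()].
#' @param dt Time step (s).
#' @param mech Optional precomputed velocity solution for this state.
#' @return A `gel_state`, or a `gel_step_reject` object.
#' @export
gel_step <- function(state, config, dt, mech = NULL) {
  mech <- mech %||% solve_velocities(state, config)
  umax <- max(abs(mech$u_n), abs(mech$u_s))
  if (umax * dt / state$h > config$cfl) {
    return(step_reject("advective CFL exceeded"))
  }
  adv <- advect_scalar(state$theta_n, mech$u_n, dt, state$h)
  theta_new <- pmax(adv$field, 1e-12)
  if (any(theta_new > 0.99)) {
    return(step_reject("network fraction approaching unity"))
  }
  st <- state
  st$theta_n <- theta_new
  out <- advance_ions(st, mech$u_n, mech$u_s, dt, config,
                      theta_flux = adv$flux, theta_n_prev = state$theta_n)
  if (is_step_reject(out)) return(out)
  out$time <- state$time + dt
  out
}

#' Run a swelling experiment
#'
#' Integrates a configuration from its initial condition to `t_end` with
#' adaptive time stepping (advective CFL, halving on step rejection),
#' recording the swelling metrics at the `metric_dt` cadence and full field
#' snapshots at the `snapshot_dt` cadence.
#'
#' @param config A [gel_config()].
#' @param quiet Suppress the progress message.
#' @return An object of class `gel_run`: a list with `config`,
#'   `theta_n_ss` (steady-state network fraction implied by mass
#'   conservation), `metrics` (tibble: `time`, `theta_n_max`, `delta_theta`,
#'   `front_L`, `delta_L_inv`, conservation and electroneutrality
#'   diagnostics), `snapshots` (long tibble of field profiles), the initial
#'   and final states, and step counters.
#' @examples
#' \donttest{
#' cfg <- gel_config("sparse_Na_preferred", bath_Na = 0.02, n_cells = 64,
#'                   t_end = 0.05)
#' run <- run_gel(cfg)
#' tail(tidy(run))
#' }
#' @export
run_gel <- function(config, quiet = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  state <- build_initial_condition(config)
  theta_ss <- mean(state$theta_n)
  cons0 <- conservation_totals(state)

  metric_row <- function(st) {
    cons <- conservation_totals(st)
    q <- charge_density(st, config$z_tilde)
    tibble(
      time = st$time,
      theta_n_max = max(st$theta_n),
      front_L = front_loc(st$x, st$theta_n, 0.01),
      drift_network = cons[["network"]] / cons0[["network"]] - 1,
      drift_Na = cons[["Na"]] / cons0[["Na"]] - 1,
      drift_Ca = cons[["Ca"]] / cons0[["Ca"]] - 1,
      drift_Cl = cons[["Cl"]] / cons0[["Cl"]] - 1,
      rel_charge = max(abs(q)) / max(st$c_Na, st$c_Cl)
    )
  }

  metrics <- list(metric_row(state))
  snaps <- list(as_tibble(state, config))
  initial_state <- state
  next_metric <- config$metric_dt
  next_snap <- config$snapshot_dt
  dt_prop <- config$dt_max
  steps <- 0L; rejects <- 0L

  while (state$time < config$t_end - 1e-12) {
    mech <- solve_velocities(state, config)
    umax <- max(abs(mech$u_n), abs(mech$u_s))
    dt <- min(config$dt_max,
              if (umax > 0) config$cfl * state$h / umax else Inf,
              config$t_end - state$time,
              next_metric - state$time + 1e-15,
              next_snap - state$time + 1e-15)
    dt <- max(dt, 0)
    repeat {
      out <- gel_step(state, config, dt, mech = mech)
      if (!is_step_reject(out)) break
      rejects <- rejects + 1L
      dt <- dt / 2
      if (dt < config$dt_min) {
        abort(sprintf(
          "time step collapsed below dt_min at t = %.6g s: %s",
          state$time, out$reason))
      }
    }
    state <- out
    steps <- steps + 1L
    if (state$time >= next_metric - 1e-12) {
      metrics[[length(metrics) + 1]] <- metric_row(state)
      next_metric <- next_metric + config$metric_dt
    }
    if (state$time >= next_snap - 1e-12) {
      snaps[[length(snaps) + 1]] <- as_tibble(state, config)
      next_snap <- next_snap + config$snapshot_dt
    }
    if (!quiet && steps %% 200 == 0) {
      message(sprintf("t = %.3f s (dt = %.2e, steps = %d)",
                      state$time, dt, steps))
    }
  }
  snaps[[length(snaps) + 1]] <- as_tibble(state, config)

  metrics <- dplyr::bind_rows(metrics)
  metrics$delta_theta <- metrics$theta_n_max - theta_ss
  metrics$delta_L_inv <- ifelse(is.na(metrics$front_L), NA_real_,
                                1 / metrics$front_L - 1 / config$L)
  structure(list(
    config = config,
    theta_n_ss = theta_ss,
    metrics = metrics,
    snapshots = dplyr::distinct(dplyr::bind_rows(snaps),
                                .data$time, .data$x, .keep_all = TRUE),
    initial_state = initial_state,
    final_state = state,
    steps = steps, rejected_steps = rejects,
    wall_time = proc.time()[["elapsed"]] - t_start
  ), class = "gel_run")
}

#' @export
print.gel_run <- function(x, ...) {
  cat(sprintf("<gel_run> %s, bath Na %g M\n", x$config$case, x$config$bath_Na))
  cat(sprintf("  t = %.3g s in %d steps (%d rejected), %.1f s wall\n",
              x$final_state$time, x$steps, x$rejected_steps, x$wall_time))
  cat(sprintf("  theta_n: max %.4f -> %.4f (steady state %.4f)\n",
              max(x$initial_state$theta_n), max(x$final_state$theta_n),
              x$theta_n_ss))
  invisible(x)
}

#' @rdname run_gel
#' @param x A `gel_run`.
#' @param ... Unused.
#' @export
tidy.gel_run <- function(x, ...) x$metrics

#' @rdname run_gel
#' @export
glance.gel_run <- function(x, ...) {
  tibble(
    case = x$config$case, bath_Na = x$config$bath_Na,
    theta_n_ss = x$theta_n_ss,
    theta_n_max_final = max(x$final_state$theta_n),
    t_end = x$final_state$time, steps = x$steps,
    max_drift = max(abs(c(x$metrics$drift_network, x$metrics$drift_Na,
                          x$metrics$drift_Ca, x$metrics$drift_Cl))),
    max_rel_charge = max(x$metrics$rel_charge)
  )
}
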