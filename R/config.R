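# Run configuration: the constant parameter block, the four named case
# presets that differ in binding-site density and cation preference, grid and
# time-stepping control.

# The four experimental regimes. "Na preferred" means K_Na < K_Ca (tighter
# sodium binding); "dense"/"sparse" refer to the site density z_tilde = 1 or
# 0.1 M per network volume. Inner totals are per liter of total volume; the
# inner chloride is the electroneutral value and is checked on construction.
case_table <- function() {
  tibble(
    case       = c("dense_Na_preferred", "sparse_Na_preferred",
                   "dense_Ca_preferred", "sparse_Ca_preferred"),
    z_tilde    = c(1, 0.1, 1, 0.1),
    T_Ca_inner = c(0.25, 0.0253, 0.25, 0.0253),
    T_Na_inner = c(0.005, 0.001, 0.005, 0.001),
    T_Cl_inner = c(0.005, 0.0016, 0.005, 0.0016),
    k_Ca_on    = c(1e6, 1e6, 1e7, 1e7),
    k_Ca_off   = c(1e3, 1e3, 1e3, 1e3),
    k_Na_on    = c(5e6, 5e6, 5e5, 5e5),
    k_Na_off   = c(5e2, 5e2, 5e2, 5e2)
  )
}

#' Case presets
#'
#' The four named experimental regimes (dense/sparse binding sites crossed
#' with sodium-/calcium-preferred binding) as a tibble of kinetic constants,
#' site densities and inner-region ion totals. The tabulated inner chloride is
#' verified against [electroneutral_chloride()] at access.
#'
#' @param case Optional preset name; if given, the single matching row.
#' @return A tibble of presets.
#' @export
case_presets <- function(case = NULL) {
  tab <- case_table()
  stopifnot(all(abs(tab$T_Cl_inner -
                      electroneutral_chloride(tab$T_Na_inner, tab$T_Ca_inner,
                                              0.5, tab$z_tilde)) < 1e-12))
  if (!is.null(case)) {
    case <- match.arg(case, tab$case)
    tab <- tab[tab$case == case, ]
  }
  tab
}

#' Mechanical parameters
#'
#' Phase viscosities, interphase drag and the energy-density scale that
#' multiplies all chemical-potential gradients in the force balance. Units are
#' internally consistent with lengths in um and time in s once the potential
#' scale is fixed; only ratios and the overall magnitude relative to the ion
#' diffusivities matter. The defaults are a calibration: they place the
#' swelling of the reference (sparse, sodium-preferred, 0.02 M bath) run on
#' the observed seconds timescale with front-decay rate gamma ~ 2.4 /s.
#'
#' @param nu_n,nu_s Network and solvent viscosities.
#' @param xi Interphase drag coefficient.
#' @param potential_scale Energy-density scale multiplying the mu-gradient
#'   force terms.
#' @return A list of class `gel_mech`.
#' @export
mechanical_params <- function(nu_n = 0.25, nu_s = 0.25, xi = 1,
                              potential_scale = 12.2) {
  if (any(c(nu_n, nu_s, xi, potential_scale) <= 0)) {
    abort("mechanical parameters must be strictly positive")
  }
  structure(list(nu_n = nu_n, nu_s = nu_s, xi = xi,
                 potential_scale = potential_scale),
            class = "gel_mech")
}

#' Simulation configuration
#'
#' Assembles everything a run needs: the case preset (kinetics, site density,
#' inner totals), bath composition, energetic and mechanical parameters, the
#' grid, and time-stepping control. Bath chloride is always the electroneutral
#' balance of the bath sodium and calcium.
#'
#' @param case One of `"sparse_Na_preferred"`, `"dense_Na_preferred"`,
#'   `"sparse_Ca_preferred"`, `"dense_Ca_preferred"`.
#' @param bath_Na Total bath sodium (M). The experiments span 2e-4 to 2e-1 M,
#'   extended up to 2 M.
#' @param bath_Ca Total bath calcium (M).
#' @param L Domain length (um).
#' @param n_cells Number of grid cells.
#' @param x0 Center of the initial tanh transition (um).
#' @param front_width Width parameter of the tanh transition (um).
#' @param theta_inner,theta_bath Initial network volume fraction in the inner
#'   region and the bath floor.
#' @param energies [interaction_energies()] parameters (the preset `z_tilde`
#'   is inserted automatically).
#' @param mech [mechanical_params()].
#' @param t_end Final time (s).
#' @param dt_max,dt_min Time-step bounds (s).
#' @param cfl Advective CFL factor in (0, 1).
#' @param metric_dt Cadence of the swelling-metric time series (s).
#' @param snapshot_dt Cadence of full field snapshots (s); `Inf` keeps only
#'   the initial and final states.
#' @param mu_s0 Solvent standard free energy (constant).
#' @param picard_tol,picard_max Convergence control of the coupled
#'   drift-diffusion/electroneutrality iteration.
#' @param reaction_tol Newton tolerance of the implicit reaction solve (M).
#' @return A list of class `gel_config`.
#' @examples
#' cfg <- gel_config("sparse_Na_preferred", bath_Na = 0.02, n_cells = 64,
#'                   t_end = 0.05)
#' @export
gel_config <- function(case = "sparse_Na_preferred", bath_Na = 0.02,
                       bath_Ca = 0.001, L = 25, n_cells = 256, x0 = 5,
                       front_width = 0.25, theta_inner = 0.5,
                       theta_bath = 1e-9,
                       energies = interaction_energies(),
                       mech = mechanical_params(),
                       t_end = 1, dt_max = 1e-3, dt_min = 1e-9, cfl = 0.4,
                       metric_dt = 0.01, snapshot_dt = 0.1, mu_s0 = 0,
                       picard_tol = 1e-12, picard_max = 25,
                       reaction_tol = 1e-13) {
  preset <- case_presets(case)
  if (bath_Na <= 0 || bath_Ca < 0) abort("bath totals must be positive")
  if (n_cells < 8) abort("n_cells too small to resolve the front")
  if (cfl <= 0 || cfl >= 1) abort("cfl must be in (0, 1)")
  energies$z_tilde <- preset$z_tilde
  cfg <- structure(list(
    case = preset$case,
    z_tilde = preset$z_tilde,
    inner = list(T_Na = preset$T_Na_inner, T_Ca = preset$T_Ca_inner,
                 T_Cl = preset$T_Cl_inner),
    bath_Na = bath_Na, bath_Ca = bath_Ca,
    ions = ion_set(preset$k_Na_on, preset$k_Na_off,
                   preset$k_Ca_on, preset$k_Ca_off),
    energies = energies, mech = mech,
    L = L, n_cells = as.integer(n_cells), x0 = x0, front_width = front_width,
    theta_inner = theta_inner, theta_bath = theta_bath,
    t_end = t_end, dt_max = dt_max, dt_min = dt_min, cfl = cfl,
    metric_dt = metric_dt, snapshot_dt = snapshot_dt, mu_s0 = mu_s0,
    picard_tol = picard_tol, picard_max = as.integer(picard_max),
    reaction_tol = reaction_tol
  ), class = "gel_config")
  cfg
}

#' @export
print.gel_config <- function(x, ...) {
  cat("<gel_config>\n")
  cat(sprintf("  case: %s  (z_tilde = %g M)\n", x$case, x$z_tilde))
  cat(sprintf("  bath: Na %g M, Ca %g M, Cl %g M (electroneutral)\n",
              x$bath_Na, x$bath_Ca, bath_chloride(x)))
  cat(sprintf("  inner totals: Na %g, Ca %g, Cl %g M; theta_n %g\n",
              x$inner$T_Na, x$inner$T_Ca, x$inner$T_Cl, x$theta_inner))
  cat(sprintf("  grid: %d cells on [0, %g] um; front at %g um (w = %g um)\n",
              x$n_cells, x$L, x$x0, x$front_width))
  cat(sprintf("  time: t_end %g s, dt in [%g, %g] s, CFL %g\n",
              x$t_end, x$dt_min, x$dt_max, x$cfl))
  invisible(x)
}

# Electroneutral bath chloride for a config (bath has essentially no network).
bath_chloride <- function(config) {
  electroneutral_chloride(config$bath_Na, config$bath_Ca,
                          config$theta_bath, config$z_tilde)
}

# --- YAML round trip ---------------------------------------------------------

config_to_list <- function(config) {
  list(
    case = config$case, bath_Na = config$bath_Na, bath_Ca = config$bath_Ca,
    L = config$L, n_cells = config$n_cells, x0 = config$x0,
    front_width = config$front_width, theta_inner = config$theta_inner,
    theta_bath = config$theta_bath,
    energies = unclass(config$energies)[c("eps1", "eps2", "eps3", "eps4",
                                          "N", "c_water")],
    mech = unclass(config$mech),
    t_end = config$t_end, dt_max = config$dt_max, dt_min = config$dt_min,
    cfl = config$cfl, metric_dt = config$metric_dt,
    snapshot_dt = config$snapshot_dt, mu_s0 = config$mu_s0,
    picard_tol = config$picard_tol, picard_max = config$picard_max,
    reaction_tol = config$reaction_tol
  )
}

#' Write / read a configuration as YAML
#'
#' The YAML schema is the flat argument list of [gel_config()] with nested
#' `energies` and `mech` blocks; the load -> dump -> load round trip is
#' lossless.
#'
#' @param config A [gel_config()] object.
#' @param path File path.
#' @return `read_gel_config()` returns a `gel_config`;
#'   `write_gel_config()` returns `path` invisibly.
#' @export
write_gel_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_gel_config
#' @export
read_gel_config <- function(path) {
  lst <- yaml::read_yaml(path)
  required <- c("case", "bath_Na")
  missing <- setdiff(required, names(lst))
  if (length(missing)) {
    abort(paste0("config file is missing required field(s): ",
                 paste(missing, collapse = ", ")))
  }
  en <- do.call(interaction_energies, lst$energies %||% list())
  me <- do.call(mechanical_params, lst$mech %||% list())
  args <- lst[setdiff(names(lst), c("energies", "mech"))]
  do.call(gel_config, c(args, list(energies = en, mech = me)))
}

# Stable hash of the resolved configuration, stamped into output files.
config_hash <- function(config) {
  rlang::hash(config_to_list(config))
}
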