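# Binding/unbinding chemistry between dissolved cations and network sites.
#
# Dissolved concentrations c_j are in moles per liter of *solvent*; bound
# concentrations b_j (and the free-site density M) are in moles per liter of
# *total* volume. The site balance is
#     z_tilde * theta_n = M + b_Na + b_Ca + 2 * b_C2,
# where z_tilde is the density of negative sites per unit network volume.

#' Free (unbound) network site density
#'
#' Negative network charge not currently bound to a cation, from the site
#' balance `M = z_tilde * theta_n - b_Na - b_Ca - 2 * b_C2`. Doubly bound
#' calcium occupies two sites.
#'
#' @param theta_n Network volume fraction (dimensionless, in `[0, 1]`).
#' @param b_Na,b_Ca,b_C2 Bound sodium, singly bound calcium and doubly bound
#'   (crosslinking) calcium concentrations, in M per total volume.
#' @param z_tilde Site density per unit network volume (M).
#' @param tol Tolerance for forgiving round-off level over-occupancy.
#' @return Free-site concentration `M` (M per total volume), same length as
#'   the inputs (which recycle as usual).
#' @examples
#' free_site_density(0.5, z_tilde = 1)                 # empty network: 0.5 M
#' free_site_density(0.5, b_C2 = 0.25, z_tilde = 1)    # fully crosslinked: 0
#' @export
free_site_density <- function(theta_n, b_Na = 0, b_Ca = 0, b_C2 = 0, z_tilde,
                              tol = 1e-10) {
  M <- z_tilde * theta_n - b_Na - b_Ca - 2 * b_C2
  scale <- pmax(z_tilde * theta_n, 1e-12)
  if (any(M < -tol * pmax(scale, 1))) {
    abort("inconsistent composition: bound ions exceed available network sites")
  }
  pmax(M, 0)
}

#' Crosslink fraction
#'
#' Ratio of the current crosslink (doubly bound calcium) concentration to the
#' maximum possible, `alpha = 2 * b_C2 / (z_tilde * theta_n)`.
#'
#' @inheritParams free_site_density
#' @param tol Tolerance beyond which values outside `[0, 1]` are an error;
#'   within tolerance they are clamped.
#' @return `alpha` in `[0, 1]`.
#' @export
crosslink_fraction <- function(b_C2, theta_n, z_tilde, tol = 1e-8) {
  if (any(theta_n <= 0)) abort("degenerate network: theta_n must be positive")
  alpha <- 2 * b_C2 / (z_tilde * theta_n)
  if (any(alpha < -tol | alpha > 1 + tol)) {
    abort("crosslink fraction outside [0, 1]: inconsistent composition")
  }
  pmin(pmax(alpha, 0), 1)
}

#' Electroneutral chloride total
#'
#' Total chloride that makes a composition (dissolved + bound ions + network
#' sites) electroneutral: `T_Cl = T_Na + 2 * T_Ca - z_tilde * theta_n`.
#' The bath limit uses `theta_n ~ 0` so `T_Cl ~ T_Na + 2 * T_Ca`.
#'
#' @param T_Na,T_Ca Total (dissolved + bound) sodium and calcium, in M per
#'   total volume.
#' @inheritParams free_site_density
#' @return Total chloride (M per total volume).
#' @examples
#' electroneutral_chloride(0.005, 0.25, 0.5, 1)    # dense inner region: 5 mM
#' electroneutral_chloride(0.001, 0.0253, 0.5, 0.1) # sparse inner: 1.6 mM
#' @export
electroneutral_chloride <- function(T_Na, T_Ca, theta_n = 0, z_tilde = 0) {
  T_Cl <- T_Na + 2 * T_Ca - z_tilde * theta_n
  if (any(T_Cl < 0)) {
    abort("infeasible composition: electroneutral chloride would be negative")
  }
  T_Cl
}

# Reaction right-hand sides per unit total volume (rates of the bound states).
# Vectorized over cells. Returns the three bound rates; the dissolved sinks
# that conserve elemental totals are -r_Na and -(r_Ca + r_C2) divided by
# theta_s (dissolved concentrations being per solvent volume).
reaction_rhs <- function(theta_s, M, c_Na, c_Ca, b_Na, b_Ca, b_C2, kin) {
  r_Na <- kin$k_Na_on * theta_s * M * c_Na - kin$k_Na_off * theta_s^2 * b_Na
  r_Ca <- kin$k_Ca_on * theta_s * M * c_Ca - kin$k_Ca_off * theta_s^2 * b_Ca
  r_X  <- 0.5 * kin$k_Ca_on * M * b_Ca - 2 * kin$k_Ca_off * b_C2
  list(db_Na = r_Na, db_Ca = r_Ca - r_X, db_C2 = r_X)
}

#' Mass-action reaction rates of a well-mixed composition
#'
#' Time derivatives of the bound states under the binding/unbinding reactions,
#' together with the matched dissolved-concentration sinks chosen so that the
#' elemental totals `T_Na = theta_s * c_Na + b_Na` and
#' `T_Ca = theta_s * c_Ca + b_Ca + b_C2` are exactly invariant under pure
#' reaction.
#'
#' @param comp Data frame of compositions, one row per state, with columns
#'   `theta_n`, `c_Na`, `c_Ca`, `b_Na`, `b_Ca`, `b_C2` (as produced by
#'   [solve_equilibrium()]).
#' @param ions Ion table from [ion_set()].
#' @param z_tilde Site density per network volume (M).
#' @return A tibble with columns `db_Na`, `db_Ca`, `db_C2` (bound, M/s per
#'   total volume) and `dc_Na`, `dc_Ca`, `dc_Cl` (dissolved, M/s per solvent
#'   volume).
#' @export
reaction_rates <- function(comp, ions, z_tilde) {
  kin <- ion_constants(ions)
  theta_s <- 1 - comp$theta_n
  M <- free_site_density(comp$theta_n, comp$b_Na, comp$b_Ca, comp$b_C2, z_tilde)
  r <- reaction_rhs(theta_s, M, comp$c_Na, comp$c_Ca,
                    comp$b_Na, comp$b_Ca, comp$b_C2, kin)
  tibble(
    db_Na = r$db_Na, db_Ca = r$db_Ca, db_C2 = r$db_C2,
    dc_Na = -r$db_Na / theta_s,
    dc_Ca = -(r$db_Ca + r$db_C2) / theta_s,
    dc_Cl = 0
  )
}

# Site-balance residual at free-site density M, with dissolved/bound
# concentrations eliminated through the totals. Used by the equilibrium solver.
# At equilibrium: b_Na = M c_Na / (K_Na theta_s), b_Ca = M c_Ca / (K_Ca theta_s),
# b_C2 = M b_Ca / (4 K_Ca).
eq_site_residual <- function(M, T_Na, T_Ca, theta_s, Z, K_Na, K_Ca) {
  b_Na <- if (is.finite(K_Na)) T_Na * M / (K_Na * theta_s^2 + M) else 0
  if (is.finite(K_Ca)) {
    den <- theta_s + M / (K_Ca * theta_s) + M^2 / (4 * K_Ca^2 * theta_s)
    c_Ca <- T_Ca / den
    b_Ca <- M * c_Ca / (K_Ca * theta_s)
    b_C2 <- M^2 * c_Ca / (4 * K_Ca^2 * theta_s)
  } else {
    b_Ca <- 0; b_C2 <- 0
  }
  M + b_Na + b_Ca + 2 * b_C2 - Z
}

#' Well-mixed binding equilibrium
#'
#' Solves the binding/unbinding chemistry of a spatially uniform composition
#' for the dissolved and bound concentrations at which all reactions balance,
#' given the elemental totals. The problem is reduced to a guaranteed-bracket
#' scalar root-find in the free-site density `M` on `[0, z_tilde * theta_n]`,
#' with all concentrations eliminated through the total-mass constraints.
#'
#' @param totals Data frame with one row per composition and columns `T_Na`,
#'   `T_Ca` (totals per liter of total volume), optionally `T_Cl` and
#'   `theta_n`. Totals are dissolved + bound.
#' @param ions Ion table from [ion_set()].
#' @param z_tilde Site density per network volume (M).
#' @param theta_n Network volume fraction; defaults to the `theta_n` column of
#'   `totals`.
#' @param tol Absolute site-balance residual tolerance (molar units).
#' @return A tibble with one row per input row: `theta_n`, `theta_s`, the
#'   dissolved `c_*` and bound `b_*` concentrations, `M_free`, the crosslink
#'   fraction `alpha`, and the site-balance `residual`.
#' @examples
#' totals <- tibble::tibble(T_Na = 0.001, T_Ca = 0.0253, theta_n = 0.5)
#' solve_equilibrium(totals, ion_set(5e6, 5e2, 1e6, 1e3), z_tilde = 0.1)
#' @export
solve_equilibrium <- function(totals, ions, z_tilde, theta_n = NULL,
                              tol = 1e-12) {
  kin <- ion_constants(ions)
  theta_n <- theta_n %||% totals$theta_n
  if (is.null(theta_n)) abort("theta_n must be given (argument or column)")
  n <- nrow(totals)
  theta_n <- rep_len(theta_n, n)
  z_tilde <- rep_len(z_tilde, n)
  if (any(totals$T_Na < 0 | totals$T_Ca < 0)) abort("totals must be >= 0")
  if (any(theta_n <= 0 | theta_n >= 1)) abort("theta_n must be in (0, 1)")

  out <- purrr::map_dfr(seq_len(n), function(i) {
    T_Na <- totals$T_Na[i]; T_Ca <- totals$T_Ca[i]
    th_n <- theta_n[i]; th_s <- 1 - th_n; Z <- z_tilde[i] * th_n
    g <- function(M) eq_site_residual(M, T_Na, T_Ca, th_s, Z,
                                      kin$K_Na, kin$K_Ca)
    g_up <- g(Z)
    if (g_up <= 0) {
      M <- Z   # no cations available to bind
    } else {
      M <- uniroot(g, c(0, Z), f.lower = -Z, f.upper = g_up,
                   tol = .Machine$double.eps * max(Z, 1e-6))$root
      # Newton polish with a central-difference derivative
      for (it in 1:5) {
        r0 <- g(M)
        if (abs(r0) < 1e-16 * max(Z, 1)) break
        hM <- max(1e-9 * Z, 1e-18)
        dg <- (g(min(M + hM, Z)) - g(max(M - hM, 0))) /
          (min(M + hM, Z) - max(M - hM, 0))
        M_new <- M - r0 / dg
        if (!is.finite(M_new)) break
        M <- min(max(M_new, 0), Z)
      }
    }
    b_Na <- if (is.finite(kin$K_Na)) T_Na * M / (kin$K_Na * th_s^2 + M) else 0
    c_Na <- (T_Na - b_Na) / th_s
    if (is.finite(kin$K_Ca)) {
      den <- th_s + M / (kin$K_Ca * th_s) + M^2 / (4 * kin$K_Ca^2 * th_s)
      c_Ca <- T_Ca / den
      b_Ca <- M * c_Ca / (kin$K_Ca * th_s)
      b_C2 <- M^2 * c_Ca / (4 * kin$K_Ca^2 * th_s)
    } else {
      c_Ca <- T_Ca / th_s; b_Ca <- 0; b_C2 <- 0
    }
    resid <- M + b_Na + b_Ca + 2 * b_C2 - Z
    if (abs(resid) > tol) {
      abort(sprintf("equilibrium solver failed to converge (residual %.3e M)",
                    resid))
    }
    T_Cl <- if ("T_Cl" %in% names(totals)) totals$T_Cl[i] else NA_real_
    tibble(
      theta_n = th_n, theta_s = th_s,
      c_Na = c_Na, c_Ca = c_Ca, c_Cl = T_Cl / th_s,
      b_Na = b_Na, b_Ca = b_Ca, b_C2 = b_C2,
      M_free = M, alpha = 2 * b_C2 / Z, residual = resid
    )
  })
  out
}

#' Integrate well-mixed binding kinetics
#'
#' Stiff integration of the zero-gradient, zero-velocity reduction of the
#' transport/reaction system: only the binding and unbinding reactions act, at
#' fixed volume fractions. Serves as a brute-force dynamic route to the same
#' equilibrium computed algebraically by [solve_equilibrium()], and conserves
#' the elemental totals by construction.
#'
#' @param comp One-row data frame with columns `theta_n`, `c_Na`, `c_Ca`,
#'   `c_Cl`, `b_Na`, `b_Ca`, `b_C2` (an initial well-mixed composition).
#' @param ions Ion table from [ion_set()].
#' @param z_tilde Site density per network volume (M).
#' @param t_end Final time (s).
#' @param times Output times; defaults to 50 log-spaced points.
#' @param rtol,atol Integrator tolerances (passed to [deSolve::ode()]).
#' @return A tibble trajectory with columns `time`, the six concentrations,
#'   `M_free`, `alpha`, and the running totals `T_Na`, `T_Ca`.
#' @export
integrate_kinetics <- function(comp, ions, z_tilde, t_end,
                               times = NULL, rtol = 1e-10, atol = 1e-14) {
  stopifnot(nrow(comp) == 1)
  kin <- ion_constants(ions)
  th_n <- comp$theta_n; th_s <- 1 - th_n
  y0 <- c(c_Na = comp$c_Na, c_Ca = comp$c_Ca, c_Cl = comp$c_Cl,
          b_Na = comp$b_Na, b_Ca = comp$b_Ca, b_C2 = comp$b_C2)
  if (is.null(times)) {
    times <- c(0, exp(seq(log(max(t_end * 1e-8, 1e-12)), log(t_end),
                          length.out = 49)))
  }
  rhs <- function(t, y, parms) {
    M <- free_site_density(th_n, y["b_Na"], y["b_Ca"], y["b_C2"], z_tilde,
                           tol = 1e-6)
    r <- reaction_rhs(th_s, M, y["c_Na"], y["c_Ca"],
                      y["b_Na"], y["b_Ca"], y["b_C2"], kin)
    list(c(-r$db_Na / th_s, -(r$db_Ca + r$db_C2) / th_s, 0,
           r$db_Na, r$db_Ca, r$db_C2))
  }
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("stiff kinetics integration failed; try loosening rtol/atol")
  }
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out$M_free <- free_site_density(th_n, out$b_Na, out$b_Ca, out$b_C2, z_tilde,
                                  tol = 1e-6)
  out$alpha <- 2 * out$b_C2 / (z_tilde * th_n)
  out$T_Na <- th_s * out$c_Na + out$b_Na
  out$T_Ca <- th_s * out$c_Ca + out$b_Ca + out$b_C2
  out
}
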