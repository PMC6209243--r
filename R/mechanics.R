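# Quasi-static force balance of the two phases on the staggered grid. In 1D
# the volume-averaged incompressibility together with the zero-Dirichlet wall
# conditions pins theta_n * u_n + theta_s * u_s = 0 at every face, so the
# solvent velocity and the pressure can be eliminated exactly: multiplying the
# network balance by theta_s, the solvent balance by theta_n and subtracting
# cancels the pressure gradient and leaves a single elliptic (tridiagonal)
# problem for u_n. The pressure is recovered afterwards from the network
# balance. Rows are rescaled by the face network fraction so the operator
# stays well conditioned in the bath where theta_n sits at its 1e-9 floor.

# Potentials and related fields at cell centers.
compute_potentials <- function(state, config) {
  en <- config$energies
  alpha <- crosslink_fraction(state$b_C2, state$theta_n, config$z_tilde,
                              tol = 1e-6)
  I <- interaction_parameter(alpha, en, tol = 1e-6)
  mu_n0 <- network_standard_energy(alpha, en)
  sigma_I <- ionic_molality(state$c_Na, state$c_Ca, state$c_Cl, en$c_water)
  list(
    alpha = alpha, I = I, sigma_I = sigma_I,
    mu_s = solvent_potential(state$theta_n, sigma_I, I, en, config$mu_s0),
    mu_n = network_potential(state$theta_n, I, mu_n0, state$Psi, en),
    phi_Na = state$c_Na / en$c_water,
    phi_Ca = state$c_Ca / en$c_water,
    phi_Cl = state$c_Cl / en$c_water
  )
}

# Ionic force per unit solvent fraction at interior faces:
# sum_j phi_j d(mu_j)/dx, written so no logarithms of small concentrations
# are ever formed (phi * d log(phi) = d phi).
ion_force_faces <- function(pot, Psi, h) {
  dphi <- face_diff(pot$phi_Na) + face_diff(pot$phi_Ca) + face_diff(pot$phi_Cl)
  sig_f <- face_mean(pot$sigma_I)
  zphi_f <- face_mean(pot$phi_Na) + 2 * face_mean(pot$phi_Ca) -
    face_mean(pot$phi_Cl)
  (dphi - 2 * sig_f * face_diff(pot$sigma_I) + zphi_f * face_diff(Psi)) / h
}

#' Solve the quasi-static velocity field
#'
#' Solves the coupled network/solvent force balance for the phase velocities
#' and pressure, given the current composition and potentials. Wall
#' velocities are zero (closed container) and the volume-averaged
#' incompressibility constraint is satisfied exactly by construction.
#'
#' @param state A `gel_state`.
#' @param config A [gel_config()].
#' @param potentials Optional precomputed potential set (internal reuse).
#' @return A list with `u_n`, `u_s` (face velocities, um/s, walls included),
#'   `p` (cell-center pressure, gauge `p = 0` at the right wall), and the
#'   maximum absolute discrete residuals of both momentum equations.
#' @export
solve_velocities <- function(state, config, potentials = NULL) {
  pot <- potentials %||% compute_potentials(state, config)
  mech <- config$mech
  n <- state$n; h <- state$h
  thn <- state$theta_n; ths <- 1 - thn
  thn_f <- face_mean(thn); ths_f <- 1 - thn_f
  ratio <- thn_f / ths_f
  nu_n <- mech$nu_n; nu_s <- mech$nu_s; xi <- mech$xi
  S <- mech$potential_scale
  m <- n - 1

  # network viscous term, tridiagonal in u (interior faces 1..m)
  inv_h2 <- 1 / h^2
  sub  <- ths_f * thn[1:m] * nu_n * inv_h2
  diag <- -ths_f * (thn[1:m] + thn[2:(m + 1)]) * nu_n * inv_h2
  sup  <- ths_f * thn[2:(m + 1)] * nu_n * inv_h2
  # solvent viscous term through w = (theta_n/theta_s) u at faces
  bsub  <- thn_f * nu_s * ths[1:m] * inv_h2
  bdiag <- -thn_f * nu_s * (ths[1:m] + ths[2:(m + 1)]) * inv_h2
  bsup  <- thn_f * nu_s * ths[2:(m + 1)] * inv_h2
  sub  <- sub + bsub * c(0, ratio[seq_len(m - 1)])
  diag <- diag + bdiag * ratio
  sup  <- sup + bsup * c(ratio[-1], 0)
  # interphase drag (after eliminating u_s, u_n - u_s = u_n / theta_s)
  diag <- diag - xi * thn_f

  dmu_n <- face_diff(pot$mu_n) / h
  dmu_s <- face_diff(pot$mu_s) / h
  fion <- ion_force_faces(pot, state$Psi, h)
  rhs <- S * thn_f * ths_f * (dmu_n - dmu_s - fion)

  # rescale rows by the face network fraction for conditioning
  u <- thomas_solve(sub / thn_f, diag / thn_f, sup / thn_f, rhs / thn_f)

  u_n <- c(0, u, 0)
  u_s <- c(0, -ratio * u, 0)

  # pressure from the network balance, integrated from the right wall
  dudx <- diff(u_n) / h                       # cell-centered strain rate
  visc_n <- (thn[2:(m + 1)] * nu_n * dudx[2:(m + 1)] -
               thn[1:m] * nu_n * dudx[1:m]) / h
  dpdx <- (visc_n - xi * thn_f * u) / thn_f - S * dmu_n
  p <- c(rev(cumsum(rev(dpdx))) * -h, 0)
  p <- p - p[n]                                # gauge: p = 0 at right wall

  # residuals of both discrete momentum balances (solvent implied by
  # construction; computed as a diagnostic)
  wsx <- c(0, -ratio * u, 0)                   # u_s at faces
  dwdx <- diff(wsx) / h
  visc_s <- (ths[2:(m + 1)] * nu_s * dwdx[2:(m + 1)] -
               ths[1:m] * nu_s * dwdx[1:m]) / h
  drag <- xi * thn_f * ths_f * (u - (-ratio * u))
  res_n <- visc_n - drag - thn_f * S * dmu_n - thn_f * dpdx
  res_s <- visc_s + drag - ths_f * S * dmu_s - ths_f * dpdx -
    ths_f * S * fion
  list(u_n = u_n, u_s = u_s, p = p,
       residual_n = max(abs(res_n)), residual_s = max(abs(res_s)))
}

#' Per-phase force densities
#'
#' The driving force fields of the two momentum balances at interior faces:
#' the potential-gradient and pressure forces on each phase, the ionic force
#' transferred to the solvent, and the interphase drag (equal and opposite on
#' the two phases by construction).
#'
#' @inheritParams solve_velocities
#' @return A tibble with one row per interior face: `x` (face position),
#'   `f_network`, `f_solvent` (potential + pressure + ionic forces) and
#'   `drag_n`, `drag_s`.
#' @export
force_density <- function(state, config) {
  pot <- compute_potentials(state, config)
  sol <- solve_velocities(state, config, pot)
  h <- state$h; n <- state$n
  thn_f <- face_mean(state$theta_n); ths_f <- 1 - thn_f
  S <- config$mech$potential_scale
  dp <- face_diff(sol$p) / h
  fion <- ion_force_faces(pot, state$Psi, h)
  u_int <- sol$u_n[2:n]
  us_int <- sol$u_s[2:n]
  drag <- config$mech$xi * thn_f * ths_f * (u_int - us_int)
  tibble(
    x = state$h * seq_len(n - 1),
    f_network = -thn_f * S * face_diff(pot$mu_n) / h - thn_f * dp,
    f_solvent = -ths_f * S * face_diff(pot$mu_s) / h - ths_f * dp -
      ths_f * S * fion,
    drag_n = -drag,
    drag_s = drag
  )
}
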