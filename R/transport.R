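# Electrodiffusive transport of the dissolved ions and advection of all
# transported fields. Dissolved species are evolved in their conserved form
# q_j = theta_s * c_j (moles per total volume): advected explicitly with the
# solvent velocity (first-order upwind), then diffused/drifted implicitly with
# Scharfetter-Gummel face fluxes. The electric potential has no field equation
# of its own; it is closed by requiring zero net charge flux through every
# face (the 1D closed-container form of bulk electroneutrality), which is
# solved pointwise per face and coupled to the implicit diffusion through a
# Picard iteration. Bound species ride the network velocity.

# Bernoulli function B(x) = x / (e^x - 1) and its derivative, numerically
# stable across the whole real line.
bern <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  big <- x > 500
  out[big] <- 0
  neg <- x < -500
  out[neg] <- -x[neg]
  mid <- !small & !big & !neg
  out[mid] <- x[mid] / expm1(x[mid])
  out
}

dbern <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  out[small] <- -0.5 + x[small] / 6
  big <- x > 30
  out[big] <- -pmax(x[big] - 1, 0) * exp(-x[big])
  neg <- x < -30
  out[neg] <- -1
  mid <- !small & !big & !neg
  e <- expm1(x[mid])
  out[mid] <- (e - x[mid] * (e + 1)) / e^2
  out
}

#' Electrodiffusive face flux of a dissolved species
#'
#' Flux `-D * theta_s * (dc/dx + z * c * dPsi/dx)` evaluated at cell faces,
#' zero at both walls. The default Scharfetter-Gummel scheme evaluates the
#' face concentration with exponential upwinding in the drift, which keeps
#' concentrations positive at arbitrarily steep potential gradients; the
#' centered scheme is the plain second-order evaluation.
#'
#' @param c Cell-centered concentration (M per solvent volume).
#' @param theta_s Cell-centered solvent fraction.
#' @param Psi Cell-centered electric potential (thermal-voltage units).
#' @param D Diffusivity (um^2/s).
#' @param z Valence.
#' @param h Grid spacing (um).
#' @param scheme `"sg"` (Scharfetter-Gummel, default) or `"centered"`.
#' @return Face flux vector of length `length(c) + 1` (walls included, zero).
#' @export
electrodiffusive_flux <- function(c, theta_s, Psi, D, z, h,
                                  scheme = c("sg", "centered")) {
  scheme <- match.arg(scheme)
  n <- length(c)
  ths_f <- face_mean(theta_s)
  F <- numeric(n + 1)
  if (scheme == "centered") {
    F[2:n] <- -D * ths_f * (face_diff(c) / h +
                              z * face_mean(c) * face_diff(Psi) / h)
  } else {
    v <- z * face_diff(Psi)
    F[2:n] <- (D * ths_f / h) * (bern(v) * c[1:(n - 1)] - bern(-v) * c[2:n])
  }
  F
}

# First-order upwind advective face fluxes (walls zero).
upwind_flux <- function(field, u_faces) {
  n <- length(field)
  F <- numeric(n + 1)
  u <- u_faces[2:n]
  F[2:n] <- pmax(u, 0) * field[1:(n - 1)] + pmin(u, 0) * field[2:n]
  F
}

#' Conservative upwind advection
#'
#' One explicit conservative finite-volume step of `d(field)/dt +
#' d(field * u)/dx = 0` with zero wall fluxes. The total content is preserved
#' to round-off; a CFL violation is an error.
#'
#' @param field Cell-centered field.
#' @param u_faces Face velocities (length `length(field) + 1`, walls first and
#'   last).
#' @param dt Time step (s).
#' @param h Grid spacing (um).
#' @return A list with the updated `field` and the face `flux` used.
#' @export
advect_scalar <- function(field, u_faces, dt, h) {
  if (max(abs(u_faces)) * dt / h > 1) {
    abort("CFL violation in advection step", class = "gel_cfl_error")
  }
  F <- upwind_flux(field, u_faces)
  list(field = field - (dt / h) * diff(F), flux = F)
}

# Zero-net-charge-flux closure at interior faces: solve, per face, for the
# potential difference dpsi that makes the total (diffusive + drift) ionic
# charge flux cancel the supplied advected charge flux G. Monotone scalar
# Newton, vectorized over faces.
solve_face_dpsi <- function(cNa, cCa, cCl, ths_f, kin, h, G, dpsi,
                            tol = 1e-12, max_iter = 60) {
  n <- length(cNa)
  iL <- 1:(n - 1); iR <- 2:n
  cf <- list(Na = list(z = 1, D = kin$D_Na, L = cNa[iL], R = cNa[iR]),
             Ca = list(z = 2, D = kin$D_Ca, L = cCa[iL], R = cCa[iR]),
             Cl = list(z = -1, D = kin$D_Cl, L = cCl[iL], R = cCl[iR]))
  scale <- G * 0
  for (sp in cf) {
    scale <- scale + abs(sp$z) * (sp$D * ths_f / h) * (sp$L + sp$R)
  }
  scale <- pmax(scale, 1e-300) + abs(G)
  for (it in seq_len(max_iter)) {
    g <- G
    gp <- numeric(length(G))
    for (sp in cf) {
      v <- sp$z * dpsi
      coef <- sp$D * ths_f / h
      g <- g + sp$z * coef * (bern(v) * sp$L - bern(-v) * sp$R)
      gp <- gp + sp$z^2 * coef * (dbern(v) * sp$L + dbern(-v) * sp$R)
    }
    if (max(abs(g) / scale) < tol) {
      return(list(dpsi = dpsi, converged = TRUE, iters = it))
    }
    step <- g / gp
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -5), 5)
    dpsi <- dpsi - step
  }
  list(dpsi = dpsi, converged = FALSE, iters = max_iter)
}

#' Electroneutrality closure for the electric potential
#'
#' Computes the electric potential field implied by bulk electroneutrality:
#' in a closed 1D container the net ionic charge flux through every face must
#' vanish (diffusive + drift + any supplied advective charge flux), which
#' determines the potential difference across each face; the potential is
#' then accumulated with the gauge `Psi = 0` at the right wall.
#'
#' @param state A `gel_state`.
#' @param config A [gel_config()].
#' @param u_n,u_s Optional face velocities contributing advective charge
#'   fluxes; defaults to a quiescent state.
#' @return The cell-centered potential `Psi` (thermal-voltage units).
#' @export
solve_electric_potential <- function(state, config, u_n = NULL, u_s = NULL) {
  kin <- ion_constants(config$ions)
  n <- state$n; h <- state$h
  ths <- 1 - state$theta_n
  ths_f <- face_mean(ths)
  G <- numeric(n - 1)
  if (!is.null(u_s)) {
    G <- G + (upwind_flux(ths * state$c_Na, u_s) +
                2 * upwind_flux(ths * state$c_Ca, u_s) -
                upwind_flux(ths * state$c_Cl, u_s))[2:n]
  }
  if (!is.null(u_n)) {
    rho_b <- state$b_Na + 2 * state$b_Ca + 2 * state$b_C2 -
      config$z_tilde * state$theta_n
    G <- G + upwind_flux(rho_b, u_n)[2:n]
  }
  sol <- solve_face_dpsi(state$c_Na, state$c_Ca, state$c_Cl, ths_f, kin, h,
                         G, dpsi = face_diff(state$Psi))
  if (!sol$converged) abort("electroneutrality closure failed to converge")
  c(-rev(cumsum(rev(sol$dpsi))), 0)
}

# Coupled implicit update of the three dissolved species and the face
# potential differences: full Newton on the 4n-1 unknowns
# (c_Na, c_Ca, c_Cl at cells; dpsi at interior faces). The species equations
# are the implicit SG updates; the closure rows demand zero net charge flux
# (diffusive + drift + advected G) through every face. The Jacobian is
# banded (variables interleaved cell-major) and solved sparsely. Quadratic
# convergence from the warm start makes this the workhorse of each step.
coupled_transport_solve <- function(q_list, ths, ths_f, kin, dpsi, G, dt, h,
                                    tol = 1e-12, max_iter = 16) {
  n <- length(ths); m <- n - 1
  zs <- c(1, 2, -1)
  Ds <- c(kin$D_Na, kin$D_Ca, kin$D_Cl)
  r <- dt / h
  cs <- vector("list", 3)
  for (sp in 1:3) {
    cs[[sp]] <- sg_implicit_species(q_list[[sp]], ths, ths_f, Ds[sp], zs[sp],
                                    dpsi, dt, h)
  }
  scale <- abs(G)
  for (sp in 1:3) {
    scale <- scale + abs(zs[sp]) * (Ds[sp] * ths_f / h) *
      (cs[[sp]][1:m] + cs[[sp]][2:n])
  }
  scale <- pmax(scale, 1e-300)
  idx_c <- function(sp) 4 * (seq_len(n) - 1) + sp
  idx_p <- 4 * seq_len(m)
  N <- 4 * n - 1
  for (it in seq_len(max_iter)) {
    v <- lapply(1:3, function(sp) zs[sp] * dpsi)
    Bp <- lapply(v, bern); Bm <- lapply(v, function(x) bern(-x))
    dBp <- lapply(v, dbern); dBm <- lapply(v, function(x) dbern(-x))
    Kf <- lapply(1:3, function(sp) Ds[sp] * ths_f / h)
    FF <- lapply(1:3, function(sp) {
      Kf[[sp]] * (Bp[[sp]] * cs[[sp]][1:m] - Bm[[sp]] * cs[[sp]][2:n])
    })
    Cres <- G
    for (sp in 1:3) Cres <- Cres + zs[sp] * FF[[sp]]
    res <- numeric(N)
    qscale <- max(unlist(q_list), 1e-12)
    for (sp in 1:3) {
      res[idx_c(sp)] <- ths * cs[[sp]] +
        r * (c(FF[[sp]], 0) - c(0, FF[[sp]])) - q_list[[sp]]
    }
    if (max(abs(Cres) / scale) < tol &&
        max(abs(res[-idx_p])) / qscale < tol) {
      return(list(c_Na = cs[[1]], c_Ca = cs[[2]], c_Cl = cs[[3]],
                  dpsi = dpsi, converged = TRUE, iters = it))
    }
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (sp in 1:3) {
      ci <- cs[[sp]]
      rows <- idx_c(sp)
      dFdp <- Kf[[sp]] * zs[sp] *
        (dBp[[sp]] * ci[1:m] + dBm[[sp]] * ci[2:n])
      Ediag <- ths + r * (c(Kf[[sp]] * Bp[[sp]], 0) +
                            c(0, Kf[[sp]] * Bm[[sp]]))
      ii <- c(ii, rows, rows[1:m], rows[2:n], rows[1:m], rows[2:n])
      jj <- c(jj, rows, rows[2:n], rows[1:m], idx_p, idx_p)
      xx <- c(xx, Ediag,
              -r * Kf[[sp]] * Bm[[sp]],
              -r * Kf[[sp]] * Bp[[sp]],
              r * dFdp,
              -r * dFdp)
      # constraint rows
      ii <- c(ii, idx_p, idx_p)
      jj <- c(jj, rows[1:m], rows[2:n])
      xx <- c(xx, zs[sp] * Kf[[sp]] * Bp[[sp]],
              -zs[sp] * Kf[[sp]] * Bm[[sp]])
    }
    dCdp <- numeric(m)
    for (sp in 1:3) {
      dCdp <- dCdp + zs[sp]^2 * Kf[[sp]] *
        (dBp[[sp]] * cs[[sp]][1:m] + dBm[[sp]] * cs[[sp]][2:n])
    }
    ii <- c(ii, idx_p); jj <- c(jj, idx_p); xx <- c(xx, dCdp)
    res[idx_p] <- Cres
    J <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
    step <- tryCatch(as.numeric(Matrix::solve(J, res)),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      return(list(converged = FALSE))
    }
    lam <- 1
    floor_c <- -1e-12 * max(abs(unlist(cs)), 1e-9)
    for (bt in 1:6) {
      new_c <- lapply(1:3, function(sp) cs[[sp]] - lam * step[idx_c(sp)])
      if (min(unlist(new_c)) >= floor_c) break
      lam <- lam / 2
    }
    cs <- lapply(new_c, pmax, 0)
    dpsi <- dpsi - lam * pmin(pmax(step[idx_p], -5), 5)
  }
  list(converged = FALSE)
}

# Implicit Scharfetter-Gummel update of one dissolved species:
# theta_s * c + (dt/h) * div(F(c)) = q_star, tridiagonal in c.
sg_implicit_species <- function(q_star, ths, ths_f, D, z, dpsi, dt, h) {
  n <- length(q_star)
  v <- z * dpsi
  coef <- dt / h * (D * ths_f / h)
  Bp <- bern(v); Bm <- bern(-v)
  diag <- ths
  diag[1:(n - 1)] <- diag[1:(n - 1)] + coef * Bp
  diag[2:n] <- diag[2:n] + coef * Bm
  sup <- c(-coef * Bm, 0)[1:(n - 1)]
  sub <- c(0, -coef * Bp)[2:n]
  thomas_solve(c(0, sub), diag, c(sup, 0), q_star)
}

#' Advance the ionic fields by one time step
#'
#' Advects the bound species with the network velocity and the dissolved
#' species (in solvent-volume-weighted form) with the solvent velocity, then
#' performs the implicit electrodiffusion update coupled to the
#' electroneutrality closure, and finally applies the stiff binding reactions
#' implicitly per cell. When used inside [gel_step()] the network advection
#' flux of the same step is passed in so the charge bookkeeping is exact.
#'
#' @param state A `gel_state` whose `theta_n` is already at the new time
#'   level (network advection happens before the ion update).
#' @param u_n,u_s Face velocities (length `n + 1`).
#' @param dt Time step (s).
#' @param config A [gel_config()].
#' @param theta_flux Face flux of `theta_n` used in the network advection of
#'   this step (defaults to zero: no network motion).
#' @param theta_n_prev Network fraction before advection (defaults to the
#'   current one).
#' @return The updated `gel_state` (invisibly carries Picard diagnostics in
#'   attribute `"diagnostics"`).
#' @export
advance_ions <- function(state, u_n, u_s, dt, config,
                         theta_flux = NULL, theta_n_prev = NULL) {
  kin <- ion_constants(config$ions)
  n <- state$n; h <- state$h
  thn_prev <- theta_n_prev %||% state$theta_n
  ths_prev <- 1 - thn_prev
  thn <- state$theta_n; ths <- 1 - thn
  theta_flux <- theta_flux %||% numeric(n + 1)

  # -- explicit advection of bound species (network velocity)
  adv_b <- lapply(list(state$b_Na, state$b_Ca, state$b_C2),
                  advect_scalar, u_faces = u_n, dt = dt, h = h)
  b_Na <- adv_b[[1]]$field; b_Ca <- adv_b[[2]]$field; b_C2 <- adv_b[[3]]$field

  # -- explicit advection of dissolved content q = theta_s * c (solvent vel.)
  q <- lapply(list(ths_prev * state$c_Na, ths_prev * state$c_Ca,
                   ths_prev * state$c_Cl),
              advect_scalar, u_faces = u_s, dt = dt, h = h)

  # advected charge flux at interior faces; the implicit drift will cancel it
  G <- (q[[1]]$flux + 2 * q[[2]]$flux - q[[3]]$flux +
          adv_b[[1]]$flux + 2 * adv_b[[2]]$flux + 2 * adv_b[[3]]$flux -
          config$z_tilde * theta_flux)[2:n]

  # -- implicit electrodiffusion coupled to the electroneutrality closure
  ths_f <- face_mean(ths)
  sol <- coupled_transport_solve(
    list(q[[1]]$field, q[[2]]$field, q[[3]]$field), ths, ths_f, kin,
    dpsi = face_diff(state$Psi), G = G, dt = dt, h = h,
    tol = config$picard_tol, max_iter = config$picard_max)
  if (!sol$converged) {
    return(step_reject("coupled transport/electroneutrality solve failed"))
  }
  cNa <- sol$c_Na; cCa <- sol$c_Ca; cCl <- sol$c_Cl
  dpsi <- sol$dpsi

  if (min(cNa, cCa, cCl, b_Na, b_Ca, b_C2) < -1e-12) {
    return(step_reject("negative concentration after transport"))
  }

  # -- stiff implicit reactions, per cell
  rx <- react_implicit(thn, ths * cNa, ths * cCa, b_Na, b_Ca, b_C2,
                       kin, config$z_tilde, dt, tol = config$reaction_tol)
  if (!rx$converged) {
    return(step_reject("implicit reaction solve did not converge"))
  }

  out <- state
  out$c_Na <- pmax(rx$q_Na / ths, 0)
  out$c_Ca <- pmax(rx$q_Ca / ths, 0)
  out$c_Cl <- pmax(cCl, 0)
  out$b_Na <- rx$b_Na; out$b_Ca <- rx$b_Ca; out$b_C2 <- rx$b_C2
  out$Psi <- c(-rev(cumsum(rev(dpsi))), 0)
  out$u_n <- u_n; out$u_s <- u_s
  attr(out, "diagnostics") <- list(newton_iters = sol$iters)
  out
}

step_reject <- function(reason) {
  structure(list(reason = reason), class = "gel_step_reject")
}

is_step_reject <- function(x) inherits(x, "gel_step_reject")

# Backward-Euler solve of the binding reactions in each cell, Newton on the
# three bound states with dissolved concentrations eliminated through the
# conserved elemental totals (so conservation is exact by construction).
# Vectorized over cells; falls back to recursive step halving on the rare
# non-convergence.
react_implicit <- function(theta_n, q_Na, q_Ca, b_Na, b_Ca, b_C2, kin,
                           z_tilde, dt, tol = 1e-13, depth = 0) {
  ths <- 1 - theta_n
  T_Na <- q_Na + b_Na
  T_Ca <- q_Ca + b_Ca + b_C2
  Z <- z_tilde * theta_n
  kNon <- kin$k_Na_on; kNoff <- kin$k_Na_off
  kCon <- kin$k_Ca_on; kCoff <- kin$k_Ca_off
  b1 <- b_Na; b2 <- b_Ca; b3 <- b_C2
  ok <- FALSE
  for (it in seq_len(60)) {
    M <- Z - b1 - b2 - 2 * b3
    P <- kNon * (T_Na - b1)
    Q <- kCon * (T_Ca - b2 - b3)
    R1 <- M * P - kNoff * ths^2 * b1
    R2 <- M * Q - kCoff * ths^2 * b2 - 0.5 * kCon * M * b2 + 2 * kCoff * b3
    R3 <- 0.5 * kCon * M * b2 - 2 * kCoff * b3
    F1 <- b1 - b_Na - dt * R1
    F2 <- b2 - b_Ca - dt * R2
    F3 <- b3 - b_C2 - dt * R3
    if (max(abs(F1), abs(F2), abs(F3)) < tol) { ok <- TRUE; break }
    # Jacobian of F = b - b0 - dt R
    a11 <- 1 - dt * (-P - kNon * M - kNoff * ths^2)
    a12 <- 1 * 0 - dt * (-P)
    a13 <- -dt * (-2 * P)
    a21 <- -dt * (-Q + 0.5 * kCon * b2)
    a22 <- 1 - dt * (-Q - kCon * M - kCoff * ths^2 +
                       0.5 * kCon * b2 - 0.5 * kCon * M)
    a23 <- -dt * (-2 * Q - kCon * M + kCon * b2 + 2 * kCoff)
    a31 <- -dt * (-0.5 * kCon * b2)
    a32 <- -dt * (0.5 * kCon * (M - b2))
    a33 <- 1 - dt * (-kCon * b2 - 2 * kCoff)
    det <- a11 * (a22 * a33 - a23 * a32) -
      a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
    d1 <- (F1 * (a22 * a33 - a23 * a32) -
             a12 * (F2 * a33 - a23 * F3) +
             a13 * (F2 * a32 - a22 * F3)) / det
    d2 <- (a11 * (F2 * a33 - a23 * F3) -
             F1 * (a21 * a33 - a23 * a31) +
             a13 * (a21 * F3 - F2 * a31)) / det
    d3 <- (a11 * (a22 * F3 - F2 * a32) -
             a12 * (a21 * F3 - F2 * a31) +
             F1 * (a21 * a32 - a22 * a31)) / det
    b1 <- b1 - d1; b2 <- b2 - d2; b3 <- b3 - d3
    # project into the physical box
    b1 <- pmin(pmax(b1, 0), T_Na)
    b2 <- pmax(b2, 0); b3 <- pmax(b3, 0)
    over <- (b2 + b3) > T_Ca
    if (any(over)) {
      s <- T_Ca[over] / (b2[over] + b3[over])
      b2[over] <- b2[over] * s; b3[over] <- b3[over] * s
    }
    occ <- b1 + b2 + 2 * b3
    over <- occ > Z
    if (any(over)) {
      s <- Z[over] / occ[over] * (1 - 1e-14)
      b1[over] <- b1[over] * s; b2[over] <- b2[over] * s
      b3[over] <- b3[over] * s
    }
  }
  if (!ok) {
    if (depth >= 8) return(list(converged = FALSE))
    half <- react_implicit(theta_n, q_Na, q_Ca, b_Na, b_Ca, b_C2, kin,
                           z_tilde, dt / 2, tol, depth + 1)
    if (!half$converged) return(list(converged = FALSE))
    return(react_implicit(theta_n, half$q_Na, half$q_Ca, half$b_Na,
                          half$b_Ca, half$b_C2, kin, z_tilde, dt / 2, tol,
                          depth + 1))
  }
  list(converged = TRUE, b_Na = b1, b_Ca = b2, b_C2 = b3,
       q_Na = T_Na - b1, q_Ca = T_Ca - b2 - b3)
}
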