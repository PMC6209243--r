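# Quasi-static two-phase force balance: symmetry, gauge and consistency
# properties of the discrete operator, and an independently assembled oracle
# on a tiny grid.

smooth_state <- function(n, L = 25, amp = 0.15) {
  h <- L / n
  x <- (seq_len(n) - 0.5) * h
  cfg <- gel_config("sparse_Na_preferred", n_cells = n)
  thn <- 0.3 + amp * sin(2 * pi * x / L)
  st <- gelswell:::new_gel_state(
    x = x, h = h, theta_n = thn,
    c_Na = 0.02 + 0.005 * cos(pi * x / L),
    c_Ca = rep(1e-3, n),
    c_Cl = 0.022 + 0.005 * cos(pi * x / L),
    b_Na = rep(1e-4, n), b_Ca = rep(1e-4, n),
    b_C2 = 0.2 * 0.1 * thn / 2,
    Psi = 0.05 * sin(2 * pi * x / L))
  list(state = st, config = cfg)
}

test_that("uniform fields produce zero velocities", {
  cfg <- gel_config("sparse_Na_preferred", n_cells = 32)
  st <- uniform_equilibrium_state(cfg)
  sol <- solve_velocities(st, cfg)
  expect_equal(max(abs(sol$u_n)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sol$u_s)), 0, tolerance = 1e-12)
})

test_that("wall conditions and incompressibility hold by construction", {
  s <- smooth_state(64)
  sol <- solve_velocities(s$state, s$config)
  expect_identical(sol$u_n[c(1, 65)], c(0, 0))
  thn_f <- 0.5 * (s$state$theta_n[-64] + s$state$theta_n[-1])
  flux <- thn_f * sol$u_n[2:64] + (1 - thn_f) * sol$u_s[2:64]
  expect_lt(max(abs(flux)), 1e-14 * max(abs(sol$u_n)))
})

test_that("both discrete momentum residuals vanish", {
  s <- smooth_state(64)
  sol <- solve_velocities(s$state, s$config)
  scale <- max(abs(sol$u_n)) * s$config$mech$xi
  expect_lt(sol$residual_n, 1e-9 * max(scale, 1))
  expect_lt(sol$residual_s, 1e-9 * max(scale, 1))
})

test_that("velocities are invariant under a potential gauge shift", {
  s <- smooth_state(48)
  sol1 <- solve_velocities(s$state, s$config)
  st2 <- s$state
  st2$Psi <- st2$Psi + 3.7
  sol2 <- solve_velocities(st2, s$config)
  expect_equal(sol1$u_n, sol2$u_n, tolerance = 1e-10)
})

test_that("velocities are invariant under joint mechanical rescaling", {
  s <- smooth_state(48)
  sol1 <- solve_velocities(s$state, s$config)
  cfg2 <- s$config
  sc <- 7.3
  cfg2$mech <- mechanical_params(
    nu_n = s$config$mech$nu_n * sc, nu_s = s$config$mech$nu_s * sc,
    xi = s$config$mech$xi * sc,
    potential_scale = s$config$mech$potential_scale * sc)
  sol2 <- solve_velocities(s$state, cfg2)
  expect_equal(sol1$u_n, sol2$u_n, tolerance = 1e-12)
})

test_that("mirror-image fields give mirrored, sign-flipped velocities", {
  s <- smooth_state(48)
  sol1 <- solve_velocities(s$state, s$config)
  st2 <- s$state
  for (f in c("theta_n", "c_Na", "c_Ca", "c_Cl", "b_Na", "b_Ca", "b_C2",
              "Psi")) {
    st2[[f]] <- rev(s$state[[f]])
  }
  sol2 <- solve_velocities(st2, s$config)
  expect_equal(sol2$u_n, -rev(sol1$u_n), tolerance = 1e-10)
})

test_that("the solve matches an independently assembled small system", {
  # three cells, two interior faces: build the eliminated 2x2 linear system
  # by hand from the same discretization and compare
  n <- 3
  cfg <- gel_config("sparse_Na_preferred")
  h <- 1
  thn <- c(0.2, 0.35, 0.3); ths <- 1 - thn
  st <- gelswell:::new_gel_state(
    x = c(0.5, 1.5, 2.5), h = h, theta_n = thn,
    c_Na = c(0.01, 0.02, 0.015), c_Ca = rep(1e-3, 3),
    c_Cl = c(0.012, 0.022, 0.017),
    b_Na = rep(0, 3), b_Ca = rep(0, 3), b_C2 = rep(0, 3),
    Psi = c(0, 0.01, -0.01))
  pot <- gelswell:::compute_potentials(st, cfg)
  me <- cfg$mech; S <- me$potential_scale
  thn_f <- c(mean(thn[1:2]), mean(thn[2:3])); ths_f <- 1 - thn_f
  ratio <- thn_f / ths_f
  A <- matrix(0, 2, 2)
  # network viscous: theta_s_f * d(theta_n nu_n du/dx)/dx
  A[1, 1] <- -ths_f[1] * (thn[1] + thn[2]) * me$nu_n
  A[1, 2] <- ths_f[1] * thn[2] * me$nu_n
  A[2, 1] <- ths_f[2] * thn[2] * me$nu_n
  A[2, 2] <- -ths_f[2] * (thn[2] + thn[3]) * me$nu_n
  # solvent viscous through w = ratio * u
  A[1, 1] <- A[1, 1] - thn_f[1] * me$nu_s * (ths[1] + ths[2]) * ratio[1]
  A[1, 2] <- A[1, 2] + thn_f[1] * me$nu_s * ths[2] * ratio[2]
  A[2, 1] <- A[2, 1] + thn_f[2] * me$nu_s * ths[2] * ratio[1]
  A[2, 2] <- A[2, 2] - thn_f[2] * me$nu_s * (ths[2] + ths[3]) * ratio[2]
  # drag
  A[1, 1] <- A[1, 1] - me$xi * thn_f[1]
  A[2, 2] <- A[2, 2] - me$xi * thn_f[2]
  fion <- gelswell:::ion_force_faces(pot, st$Psi, h)
  rhs <- S * thn_f * ths_f *
    (diff(pot$mu_n) - diff(pot$mu_s) - fion)
  u_oracle <- solve(A, rhs)
  sol <- solve_velocities(st, cfg)
  expect_equal(sol$u_n[2:3], u_oracle, tolerance = 1e-12)
})

test_that("drag forces on the two phases cancel exactly", {
  s <- smooth_state(48)
  fd <- force_density(s$state, s$config)
  expect_equal(fd$drag_n + fd$drag_s, rep(0, 47))
})

test_that("velocity field converges at second order on smooth data", {
  sols <- lapply(c(64, 128, 256), function(n) {
    s <- smooth_state(n)
    solve_velocities(s$state, s$config)$u_n
  })
  # faces of the coarse grids are subsets of the finest grid's faces
  err <- function(u_c, u_f) {
    nc <- length(u_c) - 1; nf <- length(u_f) - 1
    max(abs(u_c - u_f[seq(1, nf + 1, by = nf / nc)]))
  }
  e1 <- err(sols[[1]], sols[[3]])
  e2 <- err(sols[[2]], sols[[3]])
  expect_gt(e1 / e2, 2.5)   # ~ 4 minus Richardson contamination
})
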