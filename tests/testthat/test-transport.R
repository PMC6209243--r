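# Electrodiffusive fluxes, advection, the electroneutrality closure, and the
# coupled ion update.

test_that("electrodiffusive flux reduces correctly in simple limits", {
  n <- 10; h <- 0.5
  x <- (seq_len(n) - 0.5) * h
  ths <- rep(1, n)
  # uniform concentration and potential: no flux
  expect_equal(electrodiffusive_flux(rep(2, n), ths, rep(0.3, n), 100, 1, h),
               rep(0, n + 1))
  # neutral species: pure Fickian flux -D theta_s dc/dx
  c_lin <- 1 + 0.2 * x
  F <- electrodiffusive_flux(c_lin, ths, 5 * x, 100, 0, h)
  expect_equal(F[2:n], rep(-100 * 0.2, n - 1))
  # centered scheme on linear ramps: hand-evaluated closed form
  Psi <- 0.1 * x
  Fc <- electrodiffusive_flux(c_lin, ths, Psi, 100, 1, h,
                              scheme = "centered")
  cf <- 0.5 * (c_lin[-n] + c_lin[-1])
  expect_equal(Fc[2:n], -100 * (0.2 + cf * 0.1))
  # SG agrees with centered at weak drift
  Fsg <- electrodiffusive_flux(c_lin, ths, Psi * 1e-4, 100, 1, h)
  Fce <- electrodiffusive_flux(c_lin, ths, Psi * 1e-4, 100, 1, h,
                               scheme = "centered")
  expect_equal(Fsg[2:n], Fce[2:n], tolerance = 1e-8)
})

test_that("upwind advection is conservative and exact for zero velocity", {
  n <- 40; h <- 25 / n
  f <- runif(n)
  still <- advect_scalar(f, numeric(n + 1), 1e-3, h)
  expect_identical(still$field, f)
  u <- c(0, runif(n - 1, -1, 1), 0)
  adv <- advect_scalar(f, u, 1e-3, h)
  expect_equal(sum(adv$field), sum(f), tolerance = 1e-14)
  expect_error(advect_scalar(f, u * 1e4, 1e-1, h), class = "gel_cfl_error")
})

test_that("potential closure is flat for symmetric binary electrolytes", {
  cfg <- gel_config("sparse_Na_preferred", n_cells = 32)
  n <- 32; h <- cfg$L / n
  x <- (seq_len(n) - 0.5) * h
  c0 <- 0.05 + 0.02 * cos(pi * x / cfg$L)
  st <- gelswell:::new_gel_state(
    x = x, h = h, theta_n = rep(1e-9, n),
    c_Na = c0, c_Ca = rep(0, n), c_Cl = c0,
    b_Na = rep(0, n), b_Ca = rep(0, n), b_C2 = rep(0, n), Psi = numeric(n))
  cfg$ions <- ion_set(0, 0, 0, 0)        # equal diffusivities, no binding
  Psi <- solve_electric_potential(st, cfg)
  expect_lt(max(abs(Psi)), 1e-12)
  # uniform state: constant potential
  st$c_Na <- rep(0.05, n); st$c_Cl <- rep(0.05, n)
  expect_lt(max(abs(solve_electric_potential(st, cfg))), 1e-12)
})

test_that("binary-salt transport follows ambipolar diffusion", {
  e1 <- ambipolar_error_acc(n = 32, dt = 1e-3)
  e2 <- ambipolar_error_acc(n = 64, dt = 5e-4)
  expect_lt(e1, 5e-4)          # ~1% of the mode amplitude
  expect_lt(e2, e1 / 1.7)      # first-order-in-dt dominated refinement
})

test_that("ion update conserves every species without network", {
  cfg <- gel_config("sparse_Na_preferred", n_cells = 32)
  n <- 32; h <- cfg$L / n
  x <- (seq_len(n) - 0.5) * h
  cNa <- 0.03 + 0.01 * cos(pi * x / cfg$L)
  cCa <- 0.002 + 1e-3 * sin(pi * x / cfg$L)^2
  # chloride balances the dissolved cations and the (floor-level) site charge
  cCl <- cNa + 2 * cCa - cfg$z_tilde * 1e-9 / (1 - 1e-9)
  st <- gelswell:::new_gel_state(
    x = x, h = h, theta_n = rep(1e-9, n),
    c_Na = cNa, c_Ca = cCa, c_Cl = cCl,
    b_Na = rep(0, n), b_Ca = rep(0, n), b_C2 = rep(0, n), Psi = numeric(n))
  st$Psi <- solve_electric_potential(st, cfg)
  tot0 <- gelswell:::conservation_totals(st)
  q0 <- gelswell:::charge_density(st, cfg$z_tilde)
  u0 <- numeric(n + 1)
  for (k in 1:50) st <- advance_ions(st, u0, u0, 1e-3, cfg)
  tot <- gelswell:::conservation_totals(st)
  expect_equal(tot[["Na"]], tot0[["Na"]], tolerance = 1e-12)
  expect_equal(tot[["Ca"]], tot0[["Ca"]], tolerance = 1e-12)
  expect_equal(tot[["Cl"]], tot0[["Cl"]], tolerance = 1e-12)
  q <- gelswell:::charge_density(st, cfg$z_tilde)
  expect_lt(max(abs(q - q0)) / max(st$c_Na), 1e-9)
})

test_that("uniform equilibrium state is a fixed point of the full step", {
  cfg <- gel_config("sparse_Na_preferred", n_cells = 64, dt_max = 1e-3)
  st <- uniform_equilibrium_state(cfg)
  st0 <- st
  for (k in 1:1000) {
    st <- gel_step(st, cfg, 1e-3)
    expect_false(gelswell:::is_step_reject(st))
  }
  expect_equal(st$theta_n, st0$theta_n, tolerance = 1e-12)
  expect_equal(st$c_Na, st0$c_Na, tolerance = 1e-10)
  expect_equal(st$b_C2, st0$b_C2, tolerance = 1e-10)
  expect_lt(max(abs(st$u_n)), 1e-12)
})
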