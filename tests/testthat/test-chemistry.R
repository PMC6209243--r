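# Binding chemistry: site bookkeeping, mass-action rates, the equilibrium
# solver and its dynamic (stiff ODE) counterpart.

na_pref_ions <- ion_set(5e6, 5e2, 1e6, 1e3)

test_that("free-site density follows the site balance", {
  expect_equal(free_site_density(0.5, z_tilde = 1), 0.5)
  expect_equal(free_site_density(0.5, b_C2 = 0.25, z_tilde = 1), 0)
  expect_equal(
    free_site_density(0.5, b_Na = 0.01, b_Ca = 0.005, b_C2 = 0.01,
                      z_tilde = 0.1),
    0.015)
  expect_error(free_site_density(0.1, b_Na = 0.5, z_tilde = 1),
               "exceed")
})

test_that("crosslink fraction is the doubly-bound share of site capacity", {
  expect_equal(crosslink_fraction(0, 0.5, 1), 0)
  expect_equal(crosslink_fraction(0.25, 0.5, 1), 1)
  expect_equal(crosslink_fraction(0.02, 0.5, 0.1), 0.8)
  expect_error(crosslink_fraction(0.1, 0, 1), "degenerate")
  expect_error(crosslink_fraction(0.2, 0.5, 0.1), "outside")
})

test_that("electroneutral chloride reproduces the tabulated inner values", {
  expect_equal(electroneutral_chloride(0.005, 0.25, 0.5, 1), 0.005)
  expect_equal(electroneutral_chloride(0.001, 0.0253, 0.5, 0.1), 0.0016)
  expect_equal(electroneutral_chloride(0.2, 0.001), 0.202)
  expect_error(electroneutral_chloride(0.001, 0.001, 0.5, 1), "negative")
})

test_that("reaction rates have mass-action structure and conserve elements", {
  # empty network binds at k_on * theta_s * M * c
  comp <- tibble::tibble(theta_n = 0.5, c_Na = 0.01, c_Ca = 0.002,
                         b_Na = 0, b_Ca = 0, b_C2 = 0)
  r <- reaction_rates(comp, na_pref_ions, z_tilde = 0.1)
  expect_equal(r$db_Na, 5e6 * 0.5 * 0.05 * 0.01)
  expect_gt(r$db_Ca, 0)
  # elemental totals are invariant under pure reaction: theta_s * dc + db = 0
  withr::with_seed(7, {
    comp <- tibble::tibble(
      theta_n = runif(20, 0.1, 0.7), c_Na = runif(20, 0, 0.1),
      c_Ca = runif(20, 0, 0.05), b_Na = runif(20, 0, 1e-3),
      b_Ca = runif(20, 0, 1e-3), b_C2 = runif(20, 0, 1e-3))
    r <- reaction_rates(comp, na_pref_ions, z_tilde = 1)
    theta_s <- 1 - comp$theta_n
    expect_equal(theta_s * r$dc_Na + r$db_Na, rep(0, 20))
    expect_equal(theta_s * r$dc_Ca + r$db_Ca + r$db_C2, rep(0, 20))
    expect_equal(r$dc_Cl, rep(0, 20))
  })
})

test_that("equilibrium with no calcium matches the scalar quadratic", {
  # with T_Ca = 0 the site balance is M + T_Na M / (K theta_s^2 + M) = Z,
  # a quadratic in M solved independently here
  K <- 1e-4; ths <- 0.5; Z <- 0.1 * 0.5; T_Na <- 0.004
  a <- 1; b <- K * ths^2 + T_Na - Z; cc <- -Z * K * ths^2
  M_exact <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  eq <- solve_equilibrium(tibble::tibble(T_Na = T_Na, T_Ca = 0),
                          na_pref_ions, z_tilde = 0.1, theta_n = 0.5)
  expect_equal(eq$M_free, M_exact, tolerance = 1e-10)
  expect_equal(eq$b_Ca, 0)
  expect_equal(eq$b_C2, 0)
  expect_equal(eq$alpha, 0)
})

test_that("equilibrium composition zeroes the reaction rates", {
  eq <- solve_equilibrium(
    tibble::tibble(T_Na = 0.001, T_Ca = 0.0253), na_pref_ions,
    z_tilde = 0.1, theta_n = 0.5)
  r <- reaction_rates(eq, na_pref_ions, z_tilde = 0.1)
  expect_lt(max(abs(c(r$db_Na, r$db_Ca, r$db_C2))), 1e-10)
  # site balance and capacity
  expect_lt(abs(eq$residual), 1e-12)
  expect_true(eq$alpha >= 0 && eq$alpha <= 1)
})

test_that("the four inner compositions equilibrate as computed", {
  # regression values from this solver, independently confirmed by a
  # root-find of the raw equilibrium relations and by the kinetics oracle
  tab <- case_presets()
  expected <- c(dense_Na_preferred = 0.87161, sparse_Na_preferred = 0.65555,
                dense_Ca_preferred = 0.95016, sparse_Ca_preferred = 0.86118)
  for (i in seq_len(nrow(tab))) {
    p <- tab[i, ]
    ions <- ion_set(p$k_Na_on, p$k_Na_off, p$k_Ca_on, p$k_Ca_off)
    eq <- solve_equilibrium(
      tibble::tibble(T_Na = p$T_Na_inner, T_Ca = p$T_Ca_inner),
      ions, p$z_tilde, theta_n = 0.5)
    expect_equal(eq$alpha, unname(expected[p$case]), tolerance = 1e-4,
                 label = p$case)
  }
})

test_that("weaker calcium binding never increases the crosslink fraction", {
  alphas <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1), function(K_Ca) {
    ions <- ion_set(5e6, 5e2, 1e6, 1e6 * K_Ca)
    solve_equilibrium(tibble::tibble(T_Na = 0.001, T_Ca = 0.0253),
                      ions, 0.1, theta_n = 0.5)$alpha
  }, numeric(1))
  expect_true(all(diff(alphas) <= 1e-12))
})

test_that("stiff kinetics relax to the algebraic equilibrium", {
  withr::with_seed(42, {
    totals <- random_totals(50)
    for (i in seq_len(nrow(totals))) {
      th_n <- totals$theta_n[i]; th_s <- 1 - th_n
      T_Na <- totals$T_Na[i]; T_Ca <- totals$T_Ca[i]
      comp0 <- tibble::tibble(
        theta_n = th_n, c_Na = T_Na / th_s, c_Ca = T_Ca / th_s,
        c_Cl = (T_Na + 2 * T_Ca) / th_s, b_Na = 0, b_Ca = 0, b_C2 = 0)
      tr <- integrate_kinetics(comp0, na_pref_ions, z_tilde = 0.1,
                               t_end = 0.5)
      eq <- solve_equilibrium(tibble::tibble(T_Na = T_Na, T_Ca = T_Ca),
                              na_pref_ions, 0.1, theta_n = th_n)
      last <- tr[nrow(tr), ]
      expect_equal(last$b_Na, eq$b_Na, tolerance = 1e-6)
      expect_equal(last$b_C2, eq$b_C2, tolerance = 1e-6)
      # elemental totals conserved along the trajectory
      expect_lt(max(abs(tr$T_Na / tr$T_Na[1] - 1)), 1e-10)
      expect_lt(max(abs(tr$T_Ca / tr$T_Ca[1] - 1)), 1e-10)
    }
  })
})

test_that("kinetics started at equilibrium stay put", {
  eq <- solve_equilibrium(tibble::tibble(T_Na = 0.005, T_Ca = 0.01),
                          na_pref_ions, 0.1, theta_n = 0.3)
  eq$c_Cl <- 0.01
  tr <- integrate_kinetics(eq, na_pref_ions, 0.1, t_end = 0.1)
  expect_lt(max(abs(tr$b_C2 / tr$b_C2[1] - 1)), 1e-7)
  expect_lt(max(abs(tr$c_Na / tr$c_Na[1] - 1)), 1e-7)
})
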