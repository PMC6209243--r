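# Swelling quantification: front tracking and exponential-rate fitting.

test_that("steady-state fraction is the domain mean", {
  expect_equal(steady_state_fraction(tibble::tibble(theta_n = rep(0.27, 10))),
               0.27)
  cfg <- gel_config("sparse_Na_preferred", n_cells = 64)
  st <- build_initial_condition(cfg)
  expect_equal(steady_state_fraction(st), mean(st$theta_n))
})

test_that("front location interpolates the rightmost crossing", {
  x <- 0:25
  theta <- 0.5 - 0.02 * x
  expect_equal(front_location(tibble::tibble(x = x, theta_n = theta)), 24.5)
  expect_true(is.na(front_location(tibble::tibble(x = x,
                                                  theta_n = rep(0.1, 26)))))
  # rightmost crossing wins when there are several
  theta2 <- c(rep(0.2, 10), rep(0.005, 5), rep(0.2, 6), rep(0.004, 5))
  L2 <- front_location(tibble::tibble(x = x, theta_n = theta2))
  expect_gt(L2, 20)
})

test_that("log-linear fitting recovers exact exponential rates", {
  t <- seq(0, 1, by = 0.01)
  fit <- fit_decay_rate(tibble::tibble(time = t,
                                       delta_L_inv = 0.17 * exp(-3 * t)))
  expect_equal(fit$gamma, 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- fit_decay_rate(tibble::tibble(time = t, delta_L_inv = rep(0.2, 101)))
  expect_equal(flat$gamma, 0, tolerance = 1e-12)
  expect_error(
    fit_decay_rate(tibble::tibble(time = c(0.3, 0.4), delta_L_inv = c(1, 2))),
    "at least 3")
  # broom-style accessors
  expect_equal(glance(fit)$gamma, 3, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate[2], 3, tolerance = 1e-12)
})

test_that("front advances monotonically while inside the domain", {
  run <- exemplar_run()
  fl <- run$metrics$front_L
  inside <- !is.na(fl)
  expect_true(all(diff(fl[inside]) > -1e-9))
  # delta_L_inv is positive and decreasing while the front is inside
  dli <- run$metrics$delta_L_inv[inside]
  expect_true(all(dli > 0))
  expect_true(all(diff(dli) < 1e-9))
})

test_that("the exemplar time course has the reported shape", {
  run <- exemplar_run()
  m <- run$metrics
  # rapid early decrease of delta_L_inv before ~0.2 s
  at02 <- which.min(abs(m$time - 0.2))
  early_drop <- m$delta_L_inv[1] / m$delta_L_inv[at02]
  expect_gt(early_drop, 2)
  # approximately log-linear on the fit window
  fit <- fit_decay_rate(run)
  expect_gt(fit$r_squared, 0.99)
  # the front reaches the right wall in finite time (~1.3-1.4 s)
  t_wall <- m$time[which(is.na(m$front_L))[1]]
  expect_gt(t_wall, 1)
  expect_lt(t_wall, 1.6)
  # late-time peak-density decay is approximately exponential
  late <- m[m$time > 1.1 & m$delta_theta > 0, ]
  lf <- lm(log(delta_theta) ~ time, data = late)
  expect_gt(summary(lf)$r.squared, 0.99)
})

test_that("sweep driver tabulates fits and records failures", {
  sw <- gamma_sweep(0.02, case = "sparse_Na_preferred", n_cells = 48,
                    t_end = 0.45, window = c(0.05, 0.4))
  expect_s3_class(sw, "gel_sweep")
  expect_false(is.na(sw$gamma))
  # an infeasible molarity is reported, not fatal
  sw2 <- suppressWarnings(
    gamma_sweep(-1, case = "sparse_Na_preferred", n_cells = 48, t_end = 0.1))
  expect_true(is.na(sw2$gamma))
  expect_false(is.na(sw2$error))
})
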