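# Core spring-damper system: regime switching, closed form vs integrator,
# derived quantities and the structural invariants of the model.

test_that("parameter validation rejects unphysical configurations", {
  expect_s3_class(kv_params(K = 0.1, C = 2), "kv_params")
  expect_error(kv_params(K = 0, C = 2), "'K'")
  expect_error(kv_params(K = 0.1, C = -1), "'C'")
  expect_error(kv_params(K = 0.1, C = 2, F_pert = 0), "'F_pert'")
  expect_error(kv_params(K = 0.1, C = 2, perc = 1.2), "'perc'")
  expect_error(kv_params(K = 0.1, C = 2, tau1 = 60, tau2 = 20), "'tau2'")
})

test_that("regime boundaries are half-open exactly as the model states", {
  p <- kv_params(K = 0.1, C = 2)
  expect_identical(classify_regime(20, p), "challenge")   # t = tau1
  expect_identical(classify_regime(60, p), "post")        # t = tau2
  expect_identical(classify_regime(20 - 1e-12, p), "pre")
  expect_identical(classify_regime(c(0, 25, 99), p),
                   c("pre", "challenge", "post"))
})

test_that("pre-challenge regime is pure first-order decay", {
  p <- kv_params(K = 0.1, C = 2, F_pert = 1)
  tt <- seq(0, 15, 0.5)
  tr <- simulate_closed_form(p, tt, x0 = 1)
  expect_equal(tr$x, exp(-0.05 * tt), tolerance = 1e-12)
  # from rest, nothing happens before the challenge
  tr0 <- simulate_closed_form(p, tt, x0 = 0)
  expect_true(all(tr0$x == 0))
})

test_that("closed form matches the numerical integrator on the standard grid", {
  for (par in list(c(0.1, 2, 1),        # the standard sweep configuration
                   c(0.028, 0.384, 0.1),  # slow physiological response
                   c(0.542, 9.809, 0.1),  # fast-saturating behavioural one
                   c(0.72, 0.06, 0.1))) { # underdamped combination
    p <- kv_params(K = par[1], C = par[2], F_pert = par[3])
    xc <- simulate_closed_form(p)$x
    xn <- simulate_numeric(p)$x
    expect_lt(max(abs(xc - xn)), 1e-6)
  }
})

test_that("closed form and integrator agree across random damping regimes", {
  set.seed(42)
  draws <- draw_params(25)
  for (i in seq_len(nrow(draws))) {
    p <- kv_params(K = draws$K[i], C = draws$C[i], F_pert = draws$F_pert[i])
    d <- max(abs(simulate_closed_form(p)$x - simulate_numeric(p)$x))
    expect_lt(d, 1e-6)
  }
})

test_that("x is continuous across both regime boundaries", {
  set.seed(7)
  draws <- draw_params(20)
  eps <- 1e-9
  for (i in seq_len(nrow(draws))) {
    p <- kv_params(K = draws$K[i], C = draws$C[i], F_pert = draws$F_pert[i])
    tt <- sort(c(20 - eps, 20, 60 - eps, 60))
    x <- simulate_closed_form(p, tt)$x
    expect_lt(abs(x[2] - x[1]), 1e-6 * max(1, abs(x[2])))
    expect_lt(abs(x[4] - x[3]), 1e-6 * max(1, abs(x[4])))
  }
})

test_that("recovery is strictly decreasing and has decay constant T", {
  p <- kv_params(K = 0.1, C = 2, F_pert = 1)
  T <- derive_quantities(p)$T
  post <- seq(60, 100, 0.5)
  x <- simulate_closed_form(p, post)$x
  expect_true(all(diff(x) < 0))
  xr <- simulate_closed_form(p, c(60, 60 + T))$x
  expect_equal(xr[2] / xr[1], exp(-1), tolerance = 1e-9)
})

test_that("derived quantities follow their defining ratios", {
  p <- kv_params(K = 0.1, C = 2, F_pert = 1)
  dq <- derive_quantities(p)
  expect_equal(dq$T, 20)
  expect_equal(dq$x_inf, 10)
  expect_true(dq$x_max >= 0 && dq$x_max <= dq$x_inf)
  # x_max approaches x_inf as the challenge window grows
  p_long <- kv_params(K = 0.1, C = 2, F_pert = 1, tau1 = 20, tau2 = 2000)
  expect_equal(derive_quantities(p_long)$x_max, 10, tolerance = 1e-9)
  # conservation across random draws: x_inf * K = perc * F_pert exactly
  set.seed(11)
  draws <- draw_params(50)
  for (i in seq_len(nrow(draws))) {
    pp <- kv_params(K = draws$K[i], C = draws$C[i], F_pert = draws$F_pert[i])
    expect_equal(derive_quantities(pp)$x_inf * pp$K, pp$perc * pp$F_pert)
  }
})

test_that("response is linear in the forcing when the mass is decoupled", {
  p1 <- kv_params(K = 0.1, C = 2, F_pert = 1)
  p3 <- kv_params(K = 0.1, C = 2, F_pert = 3)
  tt <- kv_grid(0, 100, 1)
  x1 <- simulate_closed_form(p1, tt, mass = 0.5)$x
  x3 <- simulate_closed_form(p3, tt, mass = 0.5)$x
  expect_equal(x3, 3 * x1, tolerance = 1e-10)
  # with the mass coupled as the model defines, x_inf scales and T does not
  d1 <- derive_quantities(p1); d3 <- derive_quantities(p3)
  expect_equal(d3$x_inf, 3 * d1$x_inf)
  expect_equal(d3$T, d1$T)
})

test_that("degenerate and malformed inputs are rejected", {
  p <- kv_params(K = 0.1, C = 2, F_pert = 1, perc = 0)
  expect_error(simulate_closed_form(p, kv_grid()), "degenerate mass")
  expect_error(simulate_numeric(p, kv_grid()), "degenerate mass")
  # but a grid entirely before the challenge is fine with perc = 0
  expect_silent(simulate_closed_form(p, seq(0, 15, 1)))
  p2 <- kv_params(K = 0.1, C = 2)
  expect_error(simulate_closed_form(p2, c(0, 2, 1)), "strictly increasing")
  expect_error(simulate_numeric(p2, c(3, 3, 4)), "strictly increasing")
  expect_error(simulate_closed_form(p2, c(30, 40), x0 = 1), "at rest")
})

test_that("trajectories label regimes and export to delimited text", {
  p <- kv_params(K = 0.1, C = 2, F_pert = 1)
  tr <- simulate_closed_form(p)
  expect_equal(nrow(tr), 1001L)
  expect_identical(tr$regime, classify_regime(tr$time, p))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_identical(back$regime, tr$regime)
})
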