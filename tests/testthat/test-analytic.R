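test_that("characteristic length and back-engineering reproduce the auxin numbers", {
  # default auxin kinetics: a ~2.4 cm decay length
  expect_equal(signif(characteristic_length(600, 1e-6), 2), 2.4e4)
  # fast-decay and slow-diffusion back-engineered variants both give 100 um
  expect_equal(characteristic_length(600, 0.06), 100)
  expect_equal(back_engineer_decay(600, 100), 0.06)
  expect_equal(back_engineer_diffusion(1e-6, 100), 0.01)
  expect_equal(signif(back_engineer_decay(600, 24495), 2), 1.0e-6)
  expect_equal(back_engineer_diffusion(0.06, 100), 600)
  # identity case and exact algebraic round-trips
  expect_equal(characteristic_length(0.37, 0.37), 1)
  for (D in c(0.01, 6, 600)) for (lam in c(5, 100, 2.4e4)) {
    expect_equal(characteristic_length(D, back_engineer_decay(D, lam)), lam)
    expect_equal(characteristic_length(back_engineer_diffusion(1e-3, lam),
                                       1e-3), lam)
  }
  expect_error(characteristic_length(600, 0), "infinite characteristic")
})

test_that("steady-state concentration follows the finite-domain solution", {
  # flat auxin gradient: only a 4% drop over the most distal millimetre
  p <- source_decay_params(D = 600, d = 1e-6, J = 1000, L = 1e6)
  drop_pct <- 100 * (1 - steady_state_concentration(p, 1000) /
                       steady_state_concentration(p, 0))
  expect_equal(round(drop_pct), 4)
  # long-domain limit at the source is C0 = J/sqrt(D*d)
  expect_equal(steady_state_concentration(p, 0),
               max_concentration(1000, 600, 1e-6), tolerance = 1e-3)
  # matches the discrete 1D operator's exact steady state
  p2 <- source_decay_params(D = 600, d = 0.06, J = 1000, L = 600)
  ss <- steady_state_source_decay_1d(p2, 0.5)
  expect_lt(max(abs(ss$concentration - steady_state_concentration(p2, ss$x)) /
                  steady_state_concentration(p2, ss$x)), 1e-4)
  # strictly decreasing and positive on [0, L]
  x <- seq(0, p2$L, length.out = 200)
  cc <- steady_state_concentration(p2, x)
  expect_true(all(cc > 0))
  expect_true(all(diff(cc) < 0))
  # Eq.-3 limit: within 1e-4 of C0*exp(-x/lambda) for x < L/2 when L > 10*lambda
  p3 <- source_decay_params(D = 600, d = 0.06, J = 1000, L = 1200)
  x3 <- seq(0, 600, 10)
  C0 <- max_concentration(1000, 600, 0.06)
  expect_lt(max(abs(steady_state_concentration(p3, x3) -
                      C0 * exp(-x3 / 100))) / C0, 1e-4)
  expect_error(steady_state_concentration(p2, -1), "outside")
  expect_error(steady_state_concentration(p2, p2$L + 1), "outside")
})

test_that("maximum concentration scales as J/sqrt(D*d)", {
  # raising decay from 1e-6 to 0.06 collapses the maximum ~245-fold
  ratio <- max_concentration(1, 600, 1e-6) / max_concentration(1, 600, 0.06)
  expect_equal(ratio, sqrt(0.06 / 1e-6))
  expect_equal(signif(ratio, 3), 245)
  expect_equal(max_concentration(0, 600, 0.06), 0)
  expect_error(max_concentration(10, 600, 0), "no finite steady maximum")
})

test_that("displacement and half-life metrics match closed forms and a walker oracle", {
  expect_equal(signif(rms_displacement(600, 0.06), 2), 140)
  expect_equal(rms_displacement(600, 0.06),
               sqrt(2) * characteristic_length(600, 0.06))
  expect_equal(signif(diffusive_spread(0.01, 3600), 2), 8.5)
  expect_equal(diffusive_spread(0, 100), 0)
  expect_equal(round(half_life(1e-6) / 86400), 8)
  expect_equal(round(half_life(0.06)), 12)
  expect_equal(half_life(0.12), half_life(0.06) / 2)
  expect_error(half_life(0), "positive decay")
  # Monte-Carlo random walkers: lifetime ~ Exp(d), displacement ~ N(0, 2Dt)
  set.seed(421)
  n <- 2e5
  life <- rexp(n, rate = 0.06)
  x <- rnorm(n, 0, sqrt(2 * 600 * life))
  expect_equal(sqrt(mean(x^2)), rms_displacement(600, 0.06), tolerance = 0.02)
  x2 <- rnorm(n, 0, sqrt(2 * 0.01 * 3600))
  expect_equal(sqrt(mean(x2^2)), diffusive_spread(0.01, 3600),
               tolerance = 0.02)
})

test_that("Thiele modulus gauges system size against gradient length", {
  expect_equal(thiele_modulus(480, 120), 4)
  expect_equal(thiele_modulus(73, 73), 1)
  expect_equal(round(thiele_modulus(1000, sqrt(600 / 1e-6)), 3), 0.041)
})

test_that("1D transient solver conserves mass and relaxes to the steady state", {
  # no influx, zero start: identically zero forever
  p0 <- source_decay_params(D = 600, d = 0.06, J = 0, L = 200)
  out0 <- simulate_source_decay_1d(p0, 4, c(10, 100))
  expect_true(all(out0$profiles == 0))
  # fast-decay variant: < 1% relative L2 from steady state within 5 minutes
  p <- source_decay_params(D = 600, d = 0.06, J = 1000, L = 1000)
  out <- simulate_source_decay_1d(p, 5, 300, dt = 0.02)
  ss <- steady_state_source_decay_1d(p, 5)
  l2 <- sqrt(sum((out$profiles[2, ] - ss$concentration)^2) /
               sum(ss$concentration^2))
  expect_lt(l2, 0.01)
  expect_lt(out$mass_balance_error, 1e-6)
  # well-mixed short domain relaxes as 1 - exp(-d t)
  pw <- source_decay_params(D = 600, d = 0.06, J = 100, L = 10)
  ow <- simulate_source_decay_1d(pw, 1, 0.5 / 0.06, dt = 0.001)
  ssw <- steady_state_source_decay_1d(pw, 1)
  expect_equal(ow$profiles[2, 1] / ssw$concentration[1], 1 - exp(-0.5),
               tolerance = 0.02)
  # under-resolved characteristic length warns
  expect_warning(simulate_source_decay_1d(p, 50, 1, dt = 0.5), "fewer than 10")
  expect_error(simulate_source_decay_1d(p, 5, 10, dt = -1), "positive")
})

test_that("1D discretisation is second-order accurate in space", {
  p <- source_decay_params(D = 600, d = 0.06, J = 1000, L = 600)
  err <- vapply(c(4, 2, 1), function(h) {
    ss <- steady_state_source_decay_1d(p, h)
    max(abs(ss$concentration - steady_state_concentration(p, ss$x)) /
          steady_state_concentration(p, ss$x))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)   # halving h cuts the error ~4-fold
  expect_lt(err[1] / err[2], 5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5)
})
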