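test_that("delay integration reproduces the ODE limit at zero delay and the
           classical onset of the linear test equation", {
  # tau = 0: x' = -x, plain exponential
  tr <- integrate_linear_dde(0, x0 = 1, t_end = 5, n_out = 200)
  expect_equal(tr$state[, "x"], exp(-tr$times), tolerance = 1e-6)
  expect_error(integrate_linear_dde(-1), ">= 0")
  # oscillation onset of x'(t) = -x(t - tau) at tau = pi/2: bisect on the
  # growth/decay of the late-time envelope
  grows <- function(tau) {
    tr <- integrate_linear_dde(tau, t_end = 120, n_out = 3000)
    y <- tr$state[, "x"]
    a1 <- max(abs(y[tr$times > 60 & tr$times < 90]))
    a2 <- max(abs(y[tr$times >= 90]))
    a2 > a1
  }
  lo <- 1.2; hi <- 2.0
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (grows(mid)) hi <- mid else lo <- mid
  }
  onset <- (lo + hi) / 2
  expect_equal(onset, pi / 2, tolerance = 0.02)
})

test_that("the reduced ATF4/GADD34 model oscillates only with delay, with a
           period growing in the delay", {
  expect_error(reduced_delay_model(tau = -1), ">= 0")
  h <- c(ATF4 = 0.2, GADD34 = 0.1)
  # no delay: damped approach to the intermediate fixed point
  om0 <- oscillation_metrics(
    integrate_dde(reduced_delay_model(PERKA = 2, tau = 0), h, t_end = 800),
    "ATF4")
  expect_false(om0$sustained)
  # sufficient delay: sustained oscillations, period increasing with delay
  periods <- vapply(c(5, 8, 12), function(tau) {
    om <- oscillation_metrics(
      integrate_dde(reduced_delay_model(PERKA = 2, tau = tau), h,
                    t_end = 800), "ATF4")
    expect_true(om$sustained)
    1 / om$frequency
  }, numeric(1))
  expect_true(all(diff(periods) > 0))
})

test_that("the reduced model keeps the three PERKA-controlled regimes", {
  h <- c(ATF4 = 0.2, GADD34 = 0.1)
  run <- function(P) {
    tr <- integrate_dde(reduced_delay_model(PERKA = P, tau = 6), h,
                        t_end = 800)
    n <- nrow(tr$state)
    list(atf4 = tr$state[n, "ATF4"],
         osc = oscillation_metrics(tr, "ATF4")$sustained)
  }
  low <- run(0.05); mid <- run(2); high <- run(60)
  expect_false(low$osc); expect_lt(low$atf4, 0.01)
  expect_true(mid$osc)
  expect_false(high$osc); expect_gt(high$atf4, 0.5)
})
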