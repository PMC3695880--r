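toy_prior <- function() {
  # toy oscillator: damping mu - 1 changes sign at mu = 1; angular
  # frequency omega; sustained oscillation exactly on mu > 1
  structure(data.frame(name = c("mu", "omega"),
                       lower = log(c(0.1, 0.5)),
                       upper = log(c(10, 2))),
            class = c("upr_prior", "data.frame"))
}

toy_frequency <- function(theta) {
  if (theta[["mu"]] > 1) theta[["omega"]] / (2 * pi) else 0
}

test_that("the Heaviside distance accepts on and above the threshold", {
  expect_identical(heaviside_distance(0.5, 0.2), 1)
  expect_identical(heaviside_distance(0.1, 0.2), 0)
  expect_identical(heaviside_distance(0.2, 0.2), 1)   # boundary accepts
  expect_error(heaviside_distance(-0.1, 0.2), ">= 0")
})

test_that("the SMC scan concentrates on the analytic oscillatory
           half-range of the toy oscillator", {
  abc <- abc_smc(function(th) th, toy_prior(), n_particles = 500,
                 n_generations = 5, seed = 21, epsilon0 = 1e-4,
                 frequency_fun = toy_frequency)
  expect_length(abc, 5)
  # hard-constraint audit: every particle of every generation meets its
  # generation's threshold
  for (g in seq_along(abc)) {
    expect_true(all(heaviside_distance(abc[[g]]$frequency,
                                       abc[[g]]$epsilon) == 1))
    expect_equal(sum(abc[[g]]$weights), 1)
  }
  # epsilon strictly increases
  eps <- vapply(abc, `[[`, numeric(1), "epsilon")
  expect_true(all(diff(eps) > 0))
  fin <- abc[[5]]
  # support lies within the oscillatory half-range mu > 1 ...
  expect_true(all(fin$particles[, "mu"] > 1))
  # ... and covers most of it (log-range coverage at N = 500)
  rng <- range(log(fin$particles[, "mu"]))
  expect_gt(diff(rng) / (log(10) - log(1)), 0.9)
  # rising epsilon selects ever-faster oscillators: omega shifts up
  expect_gt(stats::median(fin$particles[, "omega"]),
            stats::median(abc[[1]]$particles[, "omega"]))
})

test_that("identical seeds reproduce the populations bit for bit", {
  a <- abc_smc(function(th) th, toy_prior(), n_particles = 60,
               n_generations = 3, seed = 7, epsilon0 = 1e-4,
               frequency_fun = toy_frequency)
  b <- abc_smc(function(th) th, toy_prior(), n_particles = 60,
               n_generations = 3, seed = 7, epsilon0 = 1e-4,
               frequency_fun = toy_frequency)
  for (g in seq_along(a)) {
    expect_identical(a[[g]]$particles, b[[g]]$particles)
    expect_identical(a[[g]]$weights, b[[g]]$weights)
  }
  # a degenerate point-mass-like prior accepts every particle immediately
  tight <- structure(data.frame(name = c("mu", "omega"),
                                lower = log(c(4, 1)) - 1e-9,
                                upper = log(c(4, 1)) + 1e-9),
                     class = c("upr_prior", "data.frame"))
  d <- abc_smc(function(th) th, tight, n_particles = 50,
               n_generations = 2, seed = 1, epsilon0 = 1e-4,
               frequency_fun = toy_frequency)
  expect_equal(d[[1]]$acceptance_rate, 1)
})

test_that("marginal summaries recover known quantiles and correlation
           signs", {
  set.seed(31)
  n <- 2000
  u <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  pop <- list(particles = u, weights = rep(1 / n, n), frequency = runif(n))
  ms <- marginal_summaries(pop)
  expect_equal(unname(ms$quantiles["a", ]), c(0.05, 0.25, 0.5, 0.75, 0.95),
               tolerance = 0.05)
  # constructed positive association
  x <- runif(n)
  pop2 <- list(particles = cbind(a = x, b = x + 0.1 * runif(n)),
               weights = rep(1 / n, n), frequency = runif(n))
  ms2 <- marginal_summaries(pop2)
  expect_gt(ms2$rank_correlation["a", "b"], 0.9)
  # degenerate parameters are reported, not guessed
  pop3 <- list(particles = cbind(a = x, b = rep(2, n)),
               weights = rep(1 / n, n), frequency = runif(n))
  ms3 <- marginal_summaries(pop3)
  expect_identical(ms3$degenerate, "b")
  expect_true(is.na(ms3$rank_correlation["a", "b"]))
})

test_that("sensitivity scores isolate the driving parameter", {
  set.seed(32)
  n <- 1500
  th <- exp(matrix(rnorm(3 * n), n, 3,
                   dimnames = list(NULL, c("p1", "p2", "p3"))))
  # frequency depends on p2 alone
  pop <- list(particles = th, weights = rep(1 / n, n),
              frequency = log(th[, "p2"]) + rnorm(n, 0, 0.01))
  sm <- sensitivity_matrix(pop)
  expect_identical(names(which.max(sm$scores)), "p2")
  expect_gt(sm$scores[["p2"]], 10 * sm$scores[["p1"]])
  expect_gt(sm$scores[["p2"]], 10 * sm$scores[["p3"]])
  expect_lt(sm$scores[["p1"]], 0.1)
  # a degenerate parameter scores 0 and is flagged
  th2 <- th; th2[, "p3"] <- 1
  pop2 <- list(particles = th2, weights = rep(1 / n, n),
               frequency = log(th2[, "p2"]))
  sm2 <- sensitivity_matrix(pop2)
  expect_identical(sm2$degenerate, "p3")
  expect_identical(unname(sm2$scores["p3"]), 0)
})
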