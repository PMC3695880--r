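decay_model <- function(k = 3, x0 = 2) {
  model_spec("decay", list(species_def("X", "cytoplasm", x0)),
             list(reaction_def("deg", reactants = c(X = 1),
                               law = law_mass_action("k"))),
             c(k = k))
}

test_that("integration reproduces the exponential-decay closed form", {
  m <- decay_model(k = 3, x0 = 2)
  tr <- integrate_model(m, t_end = 2, n_out = 100)
  expect_equal(tr$state[, "X"], 2 * exp(-3 * tr$times), tolerance = 1e-6)
  d <- model_rhs(m, c(X = 2))
  expect_equal(unname(d), -6)
  # all rate constants zero: zero derivative
  expect_equal(unname(model_rhs(set_parameters(m, k = 0), c(X = 2))), 0)
})

test_that("protocol segments restart the integration at boundaries", {
  # synthesis at protocol rate, first-order decay: piecewise-relaxing
  m <- model_spec("prod", list(species_def("X", "ER", 0)),
                  list(reaction_def("syn", products = c(X = 1),
                                    law = law_const("mUFPT")),
                       reaction_def("deg", reactants = c(X = 1),
                                    law = law_mass_action("d"))),
                  c(mUFPT = 0, d = 0.5))
  pr <- stress_protocol(c(1, 4), durations = c(10, 10))
  expect_equal(protocol_rate(pr, 5), 1)
  expect_equal(protocol_rate(pr, 15), 4)
  expect_equal(protocol_rate(pr, 50), 4)   # held beyond the last segment
  tr <- integrate_model(m, protocol = pr, n_out = 401)
  x10 <- tr$state[which.min(abs(tr$times - 10)), "X"]
  expect_equal(unname(x10), (1 / 0.5) * (1 - exp(-0.5 * 10)),
               tolerance = 1e-5)
  x20 <- tr$state[nrow(tr$state), "X"]
  expect_equal(unname(x20), unname(8 + (x10 - 8) * exp(-0.5 * 10)),
               tolerance = 1e-5)
})

test_that("steady_state solves fixed points and labels stability", {
  m <- model_spec("kd", list(species_def("X", "ER", 0)),
                  list(reaction_def("syn", products = c(X = 1),
                                    law = law_const("k")),
                       reaction_def("deg", reactants = c(X = 1),
                                    law = law_mass_action("d"))),
                  c(k = 1.5, d = 0.3))
  ss <- steady_state(m)
  expect_equal(unname(ss$state[["X"]]), 5, tolerance = 1e-8)
  expect_true(ss$stable)
  expect_lt(ss$residual, 1e-10)
})

test_that("a stable steady state of the full model stays put", {
  m <- full_model()
  x0 <- unstressed_state()
  expect_lt(sqrt(sum(model_rhs(m, x0)^2)), 1e-8)
  tr <- integrate_model(m, initial = x0, t_end = 1000, n_out = 100)
  drift <- abs(tr$state[nrow(tr$state), ] - x0) / pmax(abs(x0), 1e-6)
  expect_lt(max(drift), 1e-4)
  ss <- steady_state(m, mUFPT = 0)
  expect_true(ss$stable)
})

test_that("an unstable fixed point inside the Hopf window is flagged", {
  m <- set_parameters(perk_model(), PERKA = 0.05)
  tr <- integrate_model(m, t_end = 2000, n_out = 200)
  guess <- colMeans(tr$state[150:200, ])   # cycle mean as a guess
  ss <- steady_state(m, guess = guess)
  expect_false(ss$stable)
  expect_lt(ss$residual, 1e-10)
})

test_that("halving tolerances barely changes trajectory checkpoints", {
  m <- full_model()
  x0 <- unstressed_state()
  pr <- stress_protocol(15, 300)
  t1 <- integrate_model(m, initial = x0, protocol = pr, n_out = 300,
                        rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_model(m, initial = x0, protocol = pr, n_out = 300,
                        rtol = 5e-9, atol = 5e-11)
  checks <- c(60, 150, 290)
  for (tc in checks) {
    i <- which.min(abs(t1$times - tc))
    dev <- abs(t1$state[i, ] - t2$state[i, ]) / pmax(abs(t1$state[i, ]),
                                                     1e-6)
    expect_lt(max(dev), 1e-3)
  }
})

test_that("oscillation metrics read frequency, amplitude and decay", {
  tt <- seq(0, 100, length.out = 4000)
  mk <- function(y) {
    structure(list(times = tt, state = cbind(x = y), obs = NULL,
                   protocol = NULL, solver = list(), model_name = "synth"),
              class = "upr_trajectory")
  }
  # constant series
  om <- oscillation_metrics(mk(rep(2, length(tt))), "x")
  expect_identical(om$frequency, 0)
  expect_false(om$sustained)
  # pure sine of period 8
  om <- oscillation_metrics(mk(5 + sin(2 * pi * tt / 8)), "x")
  expect_true(om$sustained)
  expect_equal(om$frequency, 1 / 8, tolerance = 0.01)
  # exponentially damped oscillation is not sustained
  om <- oscillation_metrics(mk(5 + exp(-tt / 15) * sin(2 * pi * tt / 8)),
                            "x")
  expect_false(om$sustained)
  # short window errors
  expect_error(oscillation_metrics(mk(sin(tt)), "x",
                                   transient_fraction = 0.999),
               "too short")
})

test_that("renormalisation maps ranges onto 0-100 with the constant
           convention", {
  tt <- 0:2
  traj <- structure(list(times = tt, state = cbind(a = c(1, 3, 5),
                                                   b = c(7, 7, 7)),
                         obs = NULL, protocol = NULL, solver = list(),
                         model_name = "synth"),
                    class = "upr_trajectory")
  rn <- renormalize_trajectory(traj, c("a", "b"))
  expect_equal(unname(rn$scaled[, "a"]), c(0, 50, 100))
  expect_equal(unname(rn$scaled[, "b"]), c(0, 0, 0))
  expect_error(renormalize_trajectory(traj, character(0)), "empty")
})

test_that("activation timing orders first crossings and reports absences", {
  tt <- seq(0, 10, by = 0.01)
  traj <- structure(list(
    times = tt,
    state = cbind(early = pmin(tt / 2, 1), late = pmin(pmax(tt - 5, 0), 1),
                  flat = rep(0, length(tt))),
    obs = NULL, protocol = NULL, solver = list(), model_name = "synth"),
    class = "upr_trajectory")
  at <- activation_timing(traj, c("early", "late", "flat"))
  expect_lt(at[["early"]], at[["late"]])
  expect_true(is.na(at[["flat"]]))
  at2 <- activation_timing(traj, c("early", "early"))
  expect_equal(at2[[1]], at2[[2]])
})

test_that("the moderate full-model run shows the documented activation
           order", {
  m <- full_model()
  tr <- integrate_model(m, initial = unstressed_state(),
                        protocol = stress_protocol(15, 150), n_out = 3000)
  at <- activation_timing(tr, c("eIF2aP", "ATF4", "CHOP", "GADD34"))
  expect_true(all(diff(at) > 0))   # eIF2aP, then ATF4, then CHOP, then GADD34
  # translation attenuation precedes the rise of folding capacity
  at2 <- activation_timing(tr, c("eIF2aP", "BiPT"))
  expect_lt(at2[["eIF2aP"]], at2[["BiPT"]])
  # receptors activate together and are then tuned down; ATF6 cleavage is
  # more resistant to being tuned down than the kinase receptors
  rn <- renormalize_trajectory(tr, c("IRE1A", "PERKA", "ATF6cleaved_pct"))
  late <- rn$times > 120
  expect_lt(mean(rn$scaled[late, "PERKA"]),
            mean(rn$scaled[late, "ATF6cleaved_pct"]))
})
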