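test_that("continuation tracks a trivial stable branch", {
  f <- function(x, p) p - x
  br <- continue_branch(f, "p", c(0, 2), guess = 0, n_steps = 20)
  pars <- vapply(br, `[[`, numeric(1), "parameter")
  states <- vapply(br, function(b) b$state[1], numeric(1))
  expect_equal(states, pars, tolerance = 1e-8)
  expect_true(all(vapply(br, `[[`, logical(1), "stable")))
  expect_length(detect_hopf(br, f), 0)
})

test_that("pseudo-arclength continuation traverses the cubic's folds", {
  f <- function(x, p) p + x - x^3
  br <- continue_branch(f, "p", c(-1, 1), guess = -1.3247, n_steps = 200)
  folds <- sort(vapply(detect_folds(br), `[[`, numeric(1), "parameter"))
  analytic <- 2 / (3 * sqrt(3))
  expect_length(folds, 2)
  expect_equal(folds, c(-analytic, analytic), tolerance = 1e-3)
  # the S-shaped branch covers all three solution sheets
  states <- vapply(br, function(b) b$state[1], numeric(1))
  expect_lt(min(states), -1)
  expect_gt(max(states), 1)
})

test_that("Hopf detection recovers the normal form to high accuracy", {
  g <- function(z, mu) c(mu * z[1] - z[2] - z[1] * sum(z^2),
                         z[1] + mu * z[2] - z[2] * sum(z^2))
  br <- continue_branch(g, "mu", c(-0.5, 0.5), guess = c(0, 0),
                        n_steps = 40)
  hp <- detect_hopf(br, g)
  expect_length(hp, 1)
  expect_lt(abs(hp[[1]]$parameter), 1e-6)
  expect_equal(hp[[1]]$omega, 1, tolerance = 1e-6)
  # a linear, uniformly stable 2-d system has no Hopf point
  h <- function(z, p) c(-z[1] + p * z[2] * 0 - z[2], z[1] - z[2])
  br2 <- continue_branch(h, "p", c(0, 1), guess = c(0, 0), n_steps = 10)
  expect_length(detect_hopf(br2, h), 0)
})

test_that("limit-cycle amplitude of the Hopf normal form scales as
           sqrt(mu)", {
  # simulate the normal form at mu > 0 through the package machinery is not
  # possible (plain function), so check the envelope logic on a model_spec
  # realisation via polar dynamics embedded in mass-action-like laws is
  # overkill; integrate directly and reuse oscillation_metrics
  sim_r <- function(mu) {
    f <- function(t, z, p) {
      r2 <- sum(z^2)
      list(c(mu * z[1] - z[2] - z[1] * r2, z[1] + mu * z[2] - z[2] * r2))
    }
    sol <- deSolve::ode(c(0.05, 0), seq(0, 400, by = 0.1), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
    keep <- sol[, 1] > 200
    max(abs(sol[keep, 2]))
  }
  for (mu in c(0.04, 0.16, 0.36)) {
    expect_equal(sim_r(mu), sqrt(mu), tolerance = 0.02)
  }
})

test_that("the PERK branch carries exactly two Hopf points with an
           unstable inter-Hopf segment", {
  m <- perk_model()
  ss <- steady_state(set_parameters(m, PERKA = 0.002))
  br <- continue_branch(m, "PERKA", c(0.002, 0.6), guess = ss$state,
                        n_steps = 80)
  hp <- detect_hopf(br, m)
  expect_length(hp, 2)
  lo <- hp[[1]]$parameter; hi <- hp[[2]]$parameter
  expect_lt(lo, hi)
  bt <- branch_table(br, m)
  inside <- bt$parameter > lo * 1.1 & bt$parameter < hi * 0.9
  outside <- bt$parameter < lo * 0.9 | bt$parameter > hi * 1.1
  expect_true(all(!bt$stable[inside]))
  expect_true(all(bt$stable[outside]))
  # stability labels agree with simulation from a slightly perturbed state
  # (skip near-neutral points right at the Hopf crossings)
  idx <- round(seq(1, nrow(bt), length.out = 12))
  idx <- idx[abs(bt$re_lead[idx]) > 0.01]
  expect_gte(length(idx), 5)
  for (i in idx) {
    mm <- set_parameters(m, PERKA = bt$parameter[i])
    x0 <- stats::setNames(as.numeric(bt[i, species_ids(m)]) * (1 + 1e-3),
                          species_ids(m))
    tr <- integrate_model(mm, initial = x0, t_end = 800, n_out = 100)
    ref <- as.numeric(bt[i, species_ids(m)])
    drift <- max(abs(tr$state[nrow(tr$state), ] - ref) /
                   pmax(abs(ref), 1e-4))
    if (bt$stable[i]) expect_lt(drift, 1e-2) else expect_gt(drift, 1e-2)
  }
})

test_that("envelopes collapse towards the Hopf points and span the CHOP
           range mid-window", {
  m <- perk_model()
  env <- limit_cycle_envelope(m, "PERKA",
                              grid = c(0.012, 0.05, 0.12, 0.25),
                              species = "CHOPlevel", t_end = 1500)
  width <- env$max - env$min
  expect_true(all(env$sustained[2:3]))
  # interior widths dominate the near-boundary widths
  expect_gt(width[2], width[1])
  expect_gt(width[2], width[4])
  # mid-window oscillation spans between low and high CHOP levels
  expect_lt(env$min[2], 0.3)
  expect_gt(env$max[2], 1)
})

test_that("bistability detection: monotone systems are empty, the cubic
           matches its analytic window", {
  m <- model_spec("mono", list(species_def("X", "ER", 0)),
                  list(reaction_def("syn", products = c(X = 1),
                                    law = law_const("k")),
                       reaction_def("deg", reactants = c(X = 1),
                                    law = law_mass_action("d"))),
                  c(k = 1, d = 0.5))
  bi <- detect_bistability(m, "k", c(0.2, 2), n_steps = 20, t_eq = 60)
  expect_false(bi$bistable)
  expect_null(bi$intervals)
})

test_that("the apoptosis switch is bistable with hysteresis over CHOP", {
  m <- apop_model()
  bi <- detect_bistability(m, "CHOP", c(0, 3), n_steps = 60, t_eq = 800,
                           species = "BAXa")
  expect_true(bi$bistable)
  expect_false(is.null(bi$intervals))
  expect_gt(bi$up_threshold, bi$down_threshold)
  # swept states differ inside the window: hysteresis loop in BAXa
  mid <- (bi$intervals$lower[1] + bi$intervals$upper[1]) / 2
  i <- which.min(abs(bi$up[, "parameter"] - mid))
  expect_gt(abs(bi$down[i, "BAXa"] - bi$up[i, "BAXa"]), 0.1)
})

test_that("activity-state classification maps the three stress presets", {
  m <- full_model()
  x0 <- unstressed_state()
  thr <- scenario_thresholds_cached()
  lab <- function(mu) {
    classify_activity_state(m, "mUFPT", mu, thresholds = thr,
                            t_end = 1500, initial = x0)$label
  }
  expect_identical(lab(12), "low")
  expect_identical(lab(15), "intermediate")
  expect_identical(lab(18), "high")
})
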