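test_that("tqssa rate matches its stated examples and the classical limit", {
  expect_identical(tqssa_rate(kc = 1, Km = 1, St = 0, Et = 5), 0)
  expect_equal(tqssa_rate(kc = 1, Km = 0, St = 1, Et = 1), 1)
  # low-enzyme regime: classical Michaelis-Menten value
  expect_equal(tqssa_rate(kc = 1, Km = 1, St = 100, Et = 1),
               1 * 1 * 100 / (1 + 100), tolerance = 1e-2)
  # reduces to classical MM within 1% whenever Et <= 0.01 (St + Km)
  set.seed(41)
  for (i in 1:50) {
    St <- runif(1, 0.5, 50); Km <- runif(1, 0.1, 5)
    Et <- 0.01 * (St + Km) * runif(1)
    kc <- runif(1, 0.1, 3)
    expect_equal(tqssa_rate(kc, Km, St, Et), kc * Et * St / (Km + St),
                 tolerance = 1e-2)
  }
})

test_that("tqssa rate agrees with the brute-force mass-action scheme", {
  set.seed(42)
  for (i in 1:100) {
    kc <- runif(1, 0.1, 2)
    Km <- runif(1, 0.2, 5)
    St <- runif(1, 0.1, 10)
    Et <- runif(1, 0.1, 10)
    oracle <- mass_action_qss_rate(kc, Km, St, Et)
    expect_equal(tqssa_rate(kc, Km, St, Et), oracle,
                 tolerance = 0.05, label = sprintf(
                   "tqssa(kc=%.3f,Km=%.3f,St=%.3f,Et=%.3f)", kc, Km, St, Et))
  }
})

test_that("tqssa rate is symmetric, bounded and monotone", {
  set.seed(43)
  for (i in 1:200) {
    kc <- runif(1, 0, 3); Km <- runif(1, 0, 5)
    St <- runif(1, 0, 20); Et <- runif(1, 0, 20)
    v <- tqssa_rate(kc, Km, St, Et)
    expect_identical(v, tqssa_rate(kc, Km, Et, St))   # exact symmetry
    expect_gte(v, 0)
    expect_lte(v, kc * min(St, Et) + 1e-12)
    # monotone non-decreasing in both totals
    expect_gte(tqssa_rate(kc, Km, St * 1.1 + 0.01, Et), v - 1e-12)
    expect_gte(tqssa_rate(kc, Km, St, Et * 1.1 + 0.01), v - 1e-12)
  }
  expect_error(tqssa_rate(1, 1, -1, 1), "non-negative")
  expect_error(tqssa_rate(-1, 1, 1, 1), "non-negative")
})

test_that("regulation rate reproduces the promoter-occupancy oracle", {
  expect_identical(regulation_rate(list()), 0)
  act <- regulator_term(concentration = 2, kc = 2, Km = 2)
  expect_equal(regulation_rate(list(act)), 1)   # half-saturation: kc/2
  # activator + pure repressor, both at occupancy weight 1: enumerate the
  # promoter states free / activator-bound / repressor-bound
  rep <- regulator_term(concentration = 2, kc = 0, Km = 2)
  weights <- c(free = 1, act = 2 / 2, rep = 2 / 2)
  oracle <- 2 * weights["act"] / sum(weights)
  expect_equal(regulation_rate(list(act, rep)), unname(oracle))
  expect_equal(regulation_rate(list(act, rep)), 2 / 3)
})

test_that("regulation rate is bounded and repressors never increase it", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(1:5, 1)
    regs <- lapply(seq_len(n), function(j) {
      regulator_term(concentration = runif(1, 0, 10),
                     kc = runif(1, 0, 3) * rbinom(1, 1, 0.7),
                     Km = runif(1, 0.1, 5))
    })
    v <- regulation_rate(regs)
    expect_gte(v, 0)
    expect_lt(v, max(vapply(regs, `[[`, numeric(1), "kc")) + 1e-12)
    # adding a pure repressor can only decrease the rate
    more <- c(regs, list(regulator_term(runif(1, 0, 10), 0, runif(1, 0.1, 5))))
    expect_lte(regulation_rate(more), v + 1e-12)
    # a lone activator saturates towards its kc
    a <- regulator_term(1e9, kc = 2.5, Km = 1)
    expect_equal(regulation_rate(list(a)), 2.5, tolerance = 1e-6)
  }
  expect_error(regulator_term(1, 1, 0), "Km")
})

test_that("hill response hits its midpoint and complement identities", {
  for (h in c(1, 2, 4, 10)) {
    expect_equal(hill_response(3, hill_params(3, h)), 0.5)
    expect_equal(hill_response(3, hill_params(3, h, "repressing")), 0.5)
  }
  expect_identical(hill_response(0, hill_params(1, 2)), 0)
  expect_equal(hill_response(2, hill_params(1, 4, "repressing")), 1 / 17)
  # repressing is the complement of activating
  x <- seq(0, 5, by = 0.25)
  p <- hill_params(1.2, 3)
  pr <- hill_params(1.2, 3, "repressing")
  expect_equal(hill_response(x, p) + hill_response(x, pr), rep(1, length(x)))
  expect_error(hill_response(-1, p), ">= 0")
})

test_that("receptor fluxes follow the three activation variants", {
  std <- receptor_params(kf = 1, kr = 1, n = 2)
  expect_equal(receptor_fluxes(std, R = 1, Ract = 0.5),
               c(vact = 1, vdeact = 0.5))
  stab0 <- receptor_params(kf = 1, kr = 1, n = 2, extIRE = 0,
                           variant = "ufp_stabilised")
  expect_equal(receptor_fluxes(stab0, R = 1, Ract = 0.5, UFP = 7),
               c(vact = 1, vdeact = 0.5))
  dir <- receptor_params(kf = 5, kr = 2, n = 4, variant = "direct_ufp")
  expect_equal(receptor_fluxes(dir, R = 3, Ract = 1, UFP = 0),
               c(vact = 0, vdeact = 2))
  # stabilisation divides the deactivation flux
  stab <- receptor_params(kf = 1, kr = 2, n = 2, extIRE = 0.5,
                          variant = "ufp_stabilised")
  expect_equal(receptor_fluxes(stab, R = 1, Ract = 1, UFP = 2)[["vdeact"]],
               2 / (1 + 0.5 * 2))
  expect_error(receptor_params(kf = 1, kr = 1, n = 0), "positive integer")
  expect_error(receptor_fluxes(std, R = -1, Ract = 0), ">= 0")
})

test_that("the one-receptor subsystem settles on the algebraic root", {
  # standard variant with conservation R + n*Ract = total
  n <- 4; kf <- 50; kr <- 1; total <- 2
  m <- model_spec("receptor_only",
    list(species_def("R", "ER", total), species_def("Ract", "ER", 0)),
    list(reaction_def("act", reactants = c(R = n), products = c(Ract = 1),
                      law = law_mass_action("kf")),
         reaction_def("deact", reactants = c(Ract = 1), products = c(R = n),
                      law = law_mass_action("kr"))),
    c(kf = kf, kr = kr))
  ss <- steady_state(m)
  root <- uniroot(function(R) kf * R^n - kr * (total - R) / n,
                  c(0, total), tol = 1e-14)$root
  expect_equal(unname(ss$state[["R"]]), root, tolerance = 1e-8)
  expect_equal(unname(ss$state[["Ract"]]), (total - root) / n,
               tolerance = 1e-8)
})
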