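relax_obs <- function(model, ufpt, t_eq = 3000) {
  module_relaxed_obs(model, ufpt, t_eq)
}

test_that("the generic receptor module gives a steep, lagged response", {
  m <- build_receptor_module()
  grid <- c(0, 2, 4, 6, 8, 12, 20)
  ra <- vapply(grid, function(u) relax_obs(m, u)[["RA"]], numeric(1))
  # monotone non-decreasing in total UFP
  expect_true(all(diff(ra) >= -1e-8))
  # initial lag: response at low UFP is a tiny fraction of the final level
  expect_lt(ra[2], 0.02 * ra[length(ra)])
  expect_gt(ra[length(ra)], 0.1)
})

test_that("direct UFP involvement lowers basal activity relative to
           stabilisation", {
  ref <- upr_reference_params()
  ra_basal <- function(variant) {
    pars <- receptor_params(kf = ref[["kfIRE1"]], kr = ref[["krIRE1"]],
                            n = ref[["nIRE1"]], extIRE = 0.1,
                            variant = variant)
    relax_obs(build_receptor_module(pars), 0)[["RA"]]
  }
  expect_lt(ra_basal("direct_ufp"), ra_basal("ufp_stabilised") + 1e-12)
  # and UFP elevates activation for either hypothesis
  for (v in c("direct_ufp", "ufp_stabilised")) {
    pars <- receptor_params(kf = ref[["kfIRE1"]], kr = ref[["krIRE1"]],
                            n = ref[["nIRE1"]], extIRE = 0.1, variant = v)
    m <- build_receptor_module(pars)
    expect_gt(relax_obs(m, 12)[["RA"]], relax_obs(m, 0)[["RA"]])
  }
})

test_that("higher association and cooperativity steepen the threshold", {
  ref <- upr_reference_params()
  curve_for <- function(kf, n) {
    pars <- receptor_params(kf = kf, kr = ref[["krIRE1"]], n = n)
    m <- build_receptor_module(pars)
    grid <- seq(0, 14, by = 1)
    vapply(grid, function(u) relax_obs(m, u)[["RA"]], numeric(1))
  }
  steepness <- function(y) {
    y <- y / max(y)
    u20 <- which(y >= 0.2)[1]
    u80 <- which(y >= 0.8)[1]
    u80 - u20   # grid steps from 20% to 80% activation: fewer = steeper
  }
  std <- curve_for(ref[["kfIRE1"]], 4)
  coop <- curve_for(ref[["kfIRE1"]] * 10, 6)
  expect_lte(steepness(coop), steepness(std))
  # higher cooperativity also delays the onset
  expect_gte(which(coop / max(coop) >= 0.2)[1],
             which(std / max(std) >= 0.2)[1])
})

test_that("IRE1 branch: BiP rises ~3.5-fold to a plateau, with a lag", {
  m <- build_ire1_branch()
  b <- vapply(c(0, 20, 400, 1500), function(u) relax_obs(m, u)[["BiPT"]],
              numeric(1))
  fold <- b[4] / b[1]
  expect_gte(fold, 3); expect_lte(fold, 4)
  # plateau: the last doubling of UFP adds little BiP
  expect_lt(abs(b[4] - b[3]) / b[3], 0.15)
})

test_that("external XBP1 drive raises the plateau; external BiP drive the
           basal level", {
  m0 <- build_ire1_branch()
  mx <- build_ire1_branch(ire1_config(extXBP = 1))
  mb <- build_ire1_branch(ire1_config(extBiP = 0.1))
  expect_gt(relax_obs(mx, 1500)[["BiPT"]], relax_obs(m0, 1500)[["BiPT"]])
  expect_equal(relax_obs(mx, 0)[["BiPT"]], relax_obs(m0, 0)[["BiPT"]],
               tolerance = 0.02)
  expect_gt(relax_obs(mb, 0)[["BiPT"]], 1.2 * relax_obs(m0, 0)[["BiPT"]])
  # elevated basal BiP delays IRE1 activation (elongated lag)
  act_u <- function(m) {
    grid <- c(0, 10, 20, 40, 80, 160, 320)
    a <- vapply(grid, function(u) relax_obs(m, u)[["IRE1A"]], numeric(1))
    grid[which(a > 0.05)[1]]
  }
  expect_gte(act_u(mb), act_u(m0))
})

test_that("the ATF6 branch amplifies basal and maximal folding capacity", {
  mi <- build_ire1_branch()
  ma <- build_atf6_branch()
  expect_gt(relax_obs(ma, 0)[["BiPT"]], relax_obs(mi, 0)[["BiPT"]])
  expect_gt(relax_obs(ma, 1500)[["BiPT"]], relax_obs(mi, 1500)[["BiPT"]])
  # cleavage is fast relative to transfer in the reference configuration
  p <- ma$parameters
  expect_gt(p[["kcleave"]] / p[["ktrATF6"]], 10)
})

test_that("ATF6 knockouts act in the documented directions", {
  ref <- build_atf6_branch()
  wfs <- build_atf6_branch(atf6_config(knockout = "wfs1"))
  grid <- c(0, 50, 200, 800)
  b_ref <- vapply(grid, function(u) relax_obs(ref, u)[["BiPT"]], numeric(1))
  b_wfs <- vapply(grid, function(u) relax_obs(wfs, u)[["BiPT"]], numeric(1))
  # WFS1 ineffective: BiP at least as high everywhere, higher under stress
  expect_true(all(b_wfs >= b_ref - 1e-6))
  expect_gt(b_wfs[4], b_ref[4])
  # transfer knockout abolishes cleaved ATF6 and accumulates the membrane
  # receptor, diverting BiP towards it
  tko <- build_atf6_branch(atf6_config(knockout = "transfer"))
  o_ref <- relax_obs(ref, 0); o_tko <- relax_obs(tko, 0)
  expect_lt(o_tko[["ATF6cleaved_pct"]], 1e-6)
  st_ref <- module_relaxed_state(ref, 0)
  st_tko <- module_relaxed_state(tko, 0)
  expect_gt(st_tko[["ATF6"]] + st_tko[["BATF6"]],
            st_ref[["ATF6"]] + st_ref[["BATF6"]])
  expect_gt(st_tko[["BATF6"]], st_ref[["BATF6"]])
  # cleavage knockout: ATF6 leaves the ER but accumulates in the Golgi
  cko <- build_atf6_branch(atf6_config(knockout = "cleavage"))
  st_cko <- module_relaxed_state(cko, 0)
  expect_lt(relax_obs(cko, 0)[["ATF6cleaved_pct"]], 1e-6)
  expect_gt(st_cko[["ATF6g"]], st_ref[["ATF6g"]])
})

test_that("the clamped PERK branch shows its three activity regimes", {
  m <- perk_model()
  run_at <- function(pa) {
    mm <- set_parameters(m, PERKA = pa)
    tr <- integrate_model(mm, t_end = 3000, n_out = 2000)
    n <- length(tr$times)
    list(chop = tr$obs[n, "CHOPlevel"],
         tra = tr$obs[n, "translation"],
         osc = oscillation_metrics(tr, "CHOPlevel")$sustained)
  }
  low <- run_at(0.004)
  mid <- run_at(0.05)
  high <- run_at(1)
  expect_false(low$osc); expect_gt(low$tra, 0.9); expect_lt(low$chop, 0.3)
  expect_true(mid$osc)
  expect_false(high$osc); expect_lt(high$tra, 0.1)
  expect_gt(high$chop, 5 * low$chop)
})

test_that("the apoptosis switch is off without CHOP and on for high CHOP", {
  m <- apop_model()
  ss <- steady_state(m, guess = c(BH3 = 0.2, BAXa = 0))
  expect_lt(ss$state[["BAXa"]], 0.05)
  expect_true(ss$stable)
  tr <- integrate_model(set_parameters(m, CHOP = 2.5), t_end = 1500,
                        n_out = 200)
  expect_gt(tr$state[nrow(tr$state), "BAXa"], 0.5)
})
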