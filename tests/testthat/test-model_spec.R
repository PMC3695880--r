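test_that("the assembled reference network reports its canonical counts", {
  n <- model_counts(full_model())
  expect_identical(unname(n), c(27L, 62L, 82L))
})

test_that("omitting the apoptosis module yields a strict sub-network", {
  m0 <- full_model()
  m1 <- assemble_full_model(apoptosis = NULL)
  n0 <- model_counts(m0); n1 <- model_counts(m1)
  expect_true(all(n1 < n0))
  expect_true(all(species_ids(m1) %in% species_ids(m0)))
  shared <- c("BiP", "UFP", "CHOP", "ATF6p50", "XBP1s")
  expect_true(all(shared %in% species_ids(m1)))
})

test_that("model merging is order-independent and rejects conflicts", {
  a <- build_perk_branch()
  b <- build_apoptosis_module()
  # drop the clamped stand-ins that the other half provides dynamically
  ab <- merge_models(a, b)
  ba <- merge_models(b, a)
  expect_setequal(species_ids(ab), species_ids(ba))
  expect_setequal(vapply(ab$reactions, `[[`, character(1), "id"),
                  vapply(ba$reactions, `[[`, character(1), "id"))
  expect_setequal(names(ab$parameters), names(ba$parameters))
  # conflicting species definitions abort the merge
  clash <- model_spec("clash", list(species_def("eIF2a", "Golgi", 99)),
                      list(), c(dummy = 1))
  expect_error(merge_models(a, clash), "conflicting")
  expect_error(merge_models(a, a), "reaction id collision")
})

test_that("fluxes are non-negative and states stay non-negative", {
  m <- full_model()
  cc <- compile_model(m)
  set.seed(7)
  for (i in 1:50) {
    x <- runif(length(m$species), 0, 10)
    v <- cc$rates(x, m$parameters)
    expect_true(all(v >= 0))
  }
  # random perturbed initial conditions keep the simulated state
  # non-negative (integrator tolerance band)
  x0 <- unstressed_state()
  for (i in 1:100) {
    xr <- pmax(x0 * exp(rnorm(length(x0), 0, 0.5)), 0)
    tr <- integrate_model(m, initial = stats::setNames(xr, names(x0)),
                          t_end = 50, n_out = 60)
    expect_gte(min(tr$state), -1e-9)
  }
})

test_that("conserved totals are flat along trajectories", {
  m <- full_model()
  x0 <- unstressed_state()
  tr <- integrate_model(m, initial = x0,
                        protocol = stress_protocol(15, 200), n_out = 400)
  eif2aT <- tr$state[, "eIF2a"] + tr$state[, "eIF2aP"]
  expect_lt(diff(range(eif2aT)) / mean(eif2aT), 1e-6)
  # the derivative of the conserved total vanishes at arbitrary states
  set.seed(8)
  for (i in 1:20) {
    x <- runif(length(m$species), 0, 5)
    d <- model_rhs(m, x)
    expect_lt(abs(d[["eIF2a"]] + d[["eIF2aP"]]), 1e-10)
  }
})

test_that("knockout flags change only the flagged reaction rates", {
  ref <- build_atf6_branch()
  set.seed(9)
  x <- runif(length(ref$species), 0.1, 3)
  cc_ref <- compile_model(ref)
  v_ref <- cc_ref$rates(x, ref$parameters)
  names(v_ref) <- colnames(cc_ref$stoich)
  cases <- list(transfer = "ATF6_transfer", cleavage = "ATF6_cleave",
                wfs1 = "ATF6_wfs1_deg")
  for (ko in names(cases)) {
    m <- build_atf6_branch(atf6_config(knockout = ko))
    expect_identical(model_counts(m), model_counts(ref))
    cc <- compile_model(m)
    v <- cc$rates(x, m$parameters)
    names(v) <- colnames(cc$stoich)
    expect_identical(unname(v[cases[[ko]]]), 0)
    other <- setdiff(names(v), cases[[ko]])
    expect_equal(v[other], v_ref[other])
  }
})

test_that("rhs flags non-finite rates with the offending reaction", {
  m <- apop_model()
  x <- initial_state(m)
  x["BAXa"] <- NaN
  expect_error(model_rhs(m, x), "BAX")
  expect_error(model_rhs(m, x[1]), "state length")
})

test_that("set_parameters validates names and updates values", {
  m <- apop_model()
  m2 <- set_parameters(m, CHOP = 2, ksBH3 = 0.5)
  expect_identical(unname(m2$parameters[c("CHOP", "ksBH3")]), c(2, 0.5))
  expect_error(set_parameters(m, nosuch = 1), "unknown parameters")
})

test_that("compiled fast paths agree with the rate-law interpreter", {
  set.seed(10)
  for (key in c("full", "perk", "apop")) {
    m <- switch(key, full = full_model(), perk = perk_model(),
                apop = apop_model())
    fp <- uprsim:::fastpath_for(m)
    expect_false(is.null(fp))
    cc <- compile_model(m)
    for (i in 1:10) {
      x <- stats::setNames(runif(length(m$species), 0, 5), species_ids(m))
      t1 <- integrate_model(m, initial = x, t_end = 5, n_out = 20,
                            use_compiled = TRUE)
      t2 <- integrate_model(m, initial = x, t_end = 5, n_out = 20,
                            use_compiled = FALSE)
      expect_equal(t1$state, t2$state, tolerance = 1e-6)
    }
  }
})
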