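test_that("trajectory CSV round trip preserves the series", {
  m <- apop_model()
  tr <- integrate_model(set_parameters(m, CHOP = 1), t_end = 50, n_out = 60)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f, n_species = ncol(tr$state))
  expect_equal(back$times, tr$times)
  expect_equal(unname(back$state[, "BAXa"]), unname(tr$state[, "BAXa"]),
               tolerance = 1e-12)
})

test_that("population CSV and config YAML round trips are faithful", {
  abc <- abc_smc(function(th) th,
                 structure(data.frame(name = c("mu", "omega"),
                                      lower = log(c(0.1, 0.5)),
                                      upper = log(c(10, 2))),
                           class = c("upr_prior", "data.frame")),
                 n_particles = 50, n_generations = 2, seed = 3,
                 epsilon0 = 1e-4,
                 frequency_fun = function(th) {
                   if (th[["mu"]] > 1) th[["omega"]] else 0
                 })
  f <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_population_csv(abc, f, fj)
  back <- read_population_csv(f)
  expect_length(back, 2)
  expect_equal(unname(back[[2]]$particles), unname(abc[[2]]$particles),
               tolerance = 1e-12)
  meta <- jsonlite::read_json(fj)
  expect_identical(meta$seed, 3L)

  cfgf <- tempfile(fileext = ".yaml")
  cfg <- list(variant = "standard", knockout = list("wfs1"),
              overrides = list(mUFPT = 2, ktlBiP = 1.2),
              protocol = list(rates = c(12, 15), durations = 500))
  write_config(cfg, cfgf)
  cfg2 <- read_config(cfgf)
  expect_identical(cfg2$overrides[["ktlBiP"]], 1.2)
  m <- model_from_config(cfg2)
  expect_identical(unname(m$parameters[["kdwATF6"]]), 0)   # wfs1 knockout
  expect_identical(unname(m$parameters[["ktlBiP"]]), 1.2)
})

test_that("SBML round trip preserves counts and simulated dynamics", {
  m <- full_model()
  f <- tempfile(fileext = ".xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  expect_match(xml2::xml_attr(doc, "level"), "2")
  expect_match(xml2::xml_attr(doc, "version"), "4")
  m2 <- import_sbml(f)
  expect_identical(model_counts(m2), model_counts(m))
  x0 <- initial_state(m)
  x0["UFP"] <- 5
  t1 <- integrate_model(m, initial = x0, t_end = 100, n_out = 120,
                        use_compiled = FALSE)
  t2 <- integrate_model(m2, initial = x0, t_end = 100, n_out = 120,
                        use_compiled = FALSE)
  expect_lt(max(abs(t1$state - t2$state) / pmax(abs(t1$state), 1e-8)),
            1e-6)
})

test_that("importing SBML without the structured rate-law annotation is an
           explicit error naming the element", {
  foreign <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" ',
    'version="4"><model id="m"><listOfCompartments>',
    '<compartment id="ER" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="X" compartment="ER" initialConcentration="1"/>',
    '</listOfSpecies><listOfParameters>',
    '<parameter id="k" value="1"/></listOfParameters>',
    '<listOfReactions><reaction id="rx1"><listOfReactants>',
    '<speciesReference species="X" stoichiometry="1"/>',
    '</listOfReactants><kineticLaw>',
    '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>k</ci></math>',
    '</kineticLaw></reaction></listOfReactions></model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(foreign, f)
  expect_error(import_sbml(f), "rx1")
})

test_that("module response curves reproduce the branch orderings", {
  base <- run_response_curve("ire1", ufpt_grid = c(0, 200, 1500),
                             t_eq = 3000)
  ext <- run_response_curve("ire1", ufpt_grid = c(0, 200, 1500),
                            config = ire1_config(extXBP = 1), t_eq = 3000)
  expect_gt(ext$BiPT[3], base$BiPT[3])   # elevated plateau
  rec <- run_response_curve("receptor", ufpt_grid = c(0, 4, 8, 16),
                            t_eq = 2000)
  expect_true(all(diff(rec$RA) >= -1e-8))
})

test_that("scenario runs are deterministic and carry provenance", {
  m <- apop_model()
  t1 <- integrate_model(set_parameters(m, CHOP = 2), t_end = 200,
                        n_out = 100)
  t2 <- integrate_model(set_parameters(m, CHOP = 2), t_end = 200,
                        n_out = 100)
  expect_identical(t1$state, t2$state)
  st <- bax_status(BAXa = 0.01, CHOP = 1)
  expect_false(st$active)
  st2 <- bax_status(BAXa = 0.5, CHOP = 1)
  expect_true(st2$active)
})
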