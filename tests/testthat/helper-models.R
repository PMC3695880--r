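# Shared fixtures: canonical builds are cached per test run (construction is
# cheap, equilibration is not).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

full_model <- function() fixture("full", assemble_full_model)
perk_model <- function() fixture("perk", build_perk_branch)
apop_model <- function() fixture("apop", build_apoptosis_module)

unstressed_state <- function() {
  fixture("x0", function() equilibrated_state(full_model()))
}

scenario_thresholds_cached <- function() {
  fixture("thr", function() uprsim:::scenario_thresholds(full_model()))
}

# relax a module build at a given conserved total UFP and return the final
# observables
module_relaxed_obs <- function(model, ufpt, t_eq = 4000) {
  x0 <- initial_state(model)
  x0["UFP"] <- ufpt
  tr <- integrate_model(model, initial = x0, t_end = t_eq, n_out = 50)
  eval_observables(model, tr$state[nrow(tr$state), ])
}

# brute-force quasi-steady product-formation rate of the explicit
# mass-action scheme E + S <-> C -> E + P (independent oracle for tqssa)
mass_action_qss_rate <- function(kc, Km, St, Et, kon = 5000) {
  koff_plus_kcat <- Km * kon
  kcat <- kc
  koff <- koff_plus_kcat - kcat
  stopifnot(koff >= 0)
  rhs <- function(t, y, p) {
    E <- y[1]; S <- y[2]; C <- y[3]
    v_on <- kon * E * S
    v_off <- koff * C
    v_cat <- kcat * C
    list(c(-v_on + v_off + v_cat, -v_on + v_off, v_on - v_off - v_cat,
           v_cat))
  }
  # integrate to quasi-steady complex: long after binding equilibration
  # (rate ~ kon * (Km + St + Et)) but before appreciable substrate depletion
  t_qss <- 20 / (kon * (Km + St + Et))
  sol <- deSolve::ode(y = c(Et, St, 0, 0), times = c(0, t_qss),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(kcat * sol[nrow(sol), 4])   # C is the fourth column after time
}

module_relaxed_state <- function(model, ufpt, t_eq = 4000) {
  x0 <- initial_state(model)
  x0["UFP"] <- ufpt
  tr <- integrate_model(model, initial = x0, t_end = t_eq, n_out = 50)
  tr$state[nrow(tr$state), ]
}
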