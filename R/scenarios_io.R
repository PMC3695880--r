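#' @title Reproducible scenarios and interfaces
#' @description End-to-end stress scenarios (single presets, stepwise
#'   preconditioning), module-level response curves, and the package's
#'   external interfaces: SBML Level 2 Version 4 export/import, tidy CSV and
#'   JSON writers, and YAML configuration files.
#' @name scenarios_io
NULL

#' BAX activation status against the bistable switch
#'
#' Classifies an activated-BAX level as on/off relative to the midpoint
#' between the two stable branches of the apoptosis switch at the prevailing
#' CHOP level; where the switch is monostable the midpoint is taken between
#' the attractor and the opposite extreme.
#'
#' @param BAXa Activated BAX amount.
#' @param CHOP Prevailing CHOP level.
#' @param config An [apoptosis_config()] (defaults to the reference).
#' @param t_eq Equilibration time for locating the branches.
#' @return List with `active` (logical), `threshold`, `branches` (named
#'   vector `off`, `on`; `NA` where a branch does not exist).
#' @export
bax_status <- function(BAXa, CHOP, config = apoptosis_config(),
                       t_eq = 2000) {
  m <- build_apoptosis_module(config)
  m <- set_parameters(m, CHOP = max(CHOP, 0))
  baxT <- m$parameters[["BAXT"]]
  settle <- function(b0) {
    x0 <- initial_state(m)
    x0["BAXa"] <- b0
    tr <- integrate_model(m, initial = x0, t_end = t_eq, n_out = 50)
    unname(tr$state[nrow(tr$state), "BAXa"])
  }
  lo <- settle(0)
  hi <- settle(baxT)
  on_exists <- hi >= 0.25 * baxT
  off_exists <- lo < 0.25 * baxT
  thr <- if (on_exists && off_exists) {
    (lo + hi) / 2            # bistable: mid-separatrix
  } else if (on_exists) {
    hi / 2                   # monostable on
  } else {
    0.5 * baxT               # monostable off
  }
  branches <- c(off = if (off_exists) lo else NA_real_,
                on = if (on_exists) hi else NA_real_)
  list(active = BAXa > thr, threshold = thr, branches = branches)
}

scenario_thresholds <- function(model, t_end = 1500) {
  asymp <- lapply(c(6, 24), function(v) {
    tr <- integrate_model(model, protocol = stress_protocol(v, t_end),
                          initial = equilibrated_state(model), n_out = 400)
    n <- length(tr$times)
    keep <- seq(floor(0.8 * n), n)
    c(chop = mean(tr$obs[keep, "CHOPlevel"]),
      translation = mean(tr$obs[keep, "translation"]))
  })
  list(chop_mid = mean(c(asymp[[1]]["chop"], asymp[[2]]["chop"])),
       translation_mid = mean(c(asymp[[1]]["translation"],
                                asymp[[2]]["translation"])))
}

#' Pre-equilibrated unstressed state of a model
#'
#' Steady state at zero unfolded-protein influx, used as the initial
#' condition of every scenario (computed, not hard-coded).
#'
#' @param model A `upr_model` with an `mUFPT` parameter.
#' @return Named state vector.
#' @export
equilibrated_state <- function(model) {
  steady_state(model, mUFPT = 0)$state
}

#' Run a stress scenario
#'
#' Simulates the assembled model from its pre-equilibrated unstressed steady
#' state under a constant preset or explicit protocol, and derives the
#' scenario verdicts: the activity-state label (low / intermediate / high),
#' the end-of-run BAX status against the bistable switch, and the
#' first-crossing activation ordering of the PERK-branch components.
#'
#' @param preset `"mild"`, `"moderate"`, `"severe"`, a numeric `mUFPT`
#'   value, or a [stress_protocol()].
#' @param model The assembled model (defaults to the reference
#'   [assemble_full_model()]).
#' @param t_end Run length (atu); defaults to the protocol duration or 1500.
#' @param thresholds Optional precomputed classification thresholds
#'   (`chop_mid`, `translation_mid`); computed from the model's own low/high
#'   stress asymptotes when omitted.
#' @param seed Integer recorded in the provenance (scenarios are
#'   deterministic; the seed only tags the record).
#' @return Object of class `upr_scenario`: `trajectory`, `label`,
#'   `bax` (from [bax_status()]), `timing` (activation order), `protocol`,
#'   `provenance`.
#' @export
run_stress_scenario <- function(preset = "moderate", model = NULL,
                                t_end = NULL, thresholds = NULL, seed = 0) {
  model <- model %||% assemble_full_model()
  protocol <- if (inherits(preset, "upr_protocol")) preset else {
    stress_protocol(preset, durations = t_end %||% 1500)
  }
  t_end <- t_end %||% max(protocol$segments$t_end)
  x0 <- equilibrated_state(model)
  thresholds <- thresholds %||% scenario_thresholds(model)
  tr <- integrate_model(model, initial = x0, protocol = protocol,
                        t_end = t_end)
  om_chop <- oscillation_metrics(tr, "CHOPlevel")
  om_tra <- oscillation_metrics(tr, "translation")
  n <- length(tr$times)
  keep <- seq(floor(0.8 * n), n)
  chop_end <- mean(tr$obs[keep, "CHOPlevel"])
  tra_end <- mean(tr$obs[keep, "translation"])
  label <- if (om_chop$sustained || om_tra$sustained) {
    "intermediate"
  } else if (chop_end <= thresholds$chop_mid &&
             tra_end >= thresholds$translation_mid) {
    "low"
  } else if (chop_end > thresholds$chop_mid &&
             tra_end < thresholds$translation_mid) {
    "high"
  } else "ambiguous"
  bax <- if ("BAXa" %in% colnames(tr$state)) {
    bax_status(tr$state[n, "BAXa"], chop_end)
  } else NULL
  timing <- activation_timing(tr, c("eIF2aP", "ATF4", "CHOP", "GADD34"))
  structure(list(
    trajectory = tr, label = label, bax = bax, timing = timing,
    protocol = protocol,
    diagnostics = list(chop_end = chop_end, translation_end = tra_end,
                       osc_chop = om_chop, osc_translation = om_tra,
                       thresholds = thresholds),
    provenance = scenario_provenance(model, protocol, seed)
  ), class = "upr_scenario")
}

#' @export
print.upr_scenario <- function(x, ...) {
  cat("<upr_scenario> label:", x$label)
  if (!is.null(x$bax)) {
    cat(", BAX:", if (x$bax$active) "active" else "inactive")
  }
  cat("\n")
  invisible(x)
}

#' Run the stepwise preconditioning scenario
#'
#' Administers the stress steps sequentially (default mild, moderate,
#' severe at 500 atu each) from the pre-equilibrated unstressed state and
#' reports the BAX status at the end of each step. Reaching the oscillatory
#' intermediate state from the adaptive low state leaves BAX on the
#' inactive branch of the bistable switch — the protection that direct
#' moderate stress (which passes through the high-activity phase) does not
#' enjoy.
#'
#' @param steps Numeric `mUFPT` step values (default `c(12, 15, 18)`).
#' @param step_duration Duration of each step (atu, default 500).
#' @param model The assembled model (defaults to the reference assembly).
#' @param seed Provenance tag.
#' @return Object of class `upr_scenario` with an additional `per_step`
#'   data frame (`step`, `mUFPT`, `t_end`, `BAXa`, `bax_active`,
#'   `chop_mean`).
#' @export
run_preconditioning <- function(steps = c(12, 15, 18), step_duration = 500,
                                model = NULL, seed = 0) {
  model <- model %||% assemble_full_model()
  protocol <- stress_protocol(steps, durations = step_duration)
  res <- run_stress_scenario(protocol, model = model, seed = seed)
  tr <- res$trajectory
  per_step <- do.call(rbind, lapply(seq_along(steps), function(i) {
    tend <- protocol$segments$t_end[i]
    j <- which.min(abs(tr$times - tend))
    k <- tr$times > protocol$segments$t_start[i] & tr$times <= tend
    chop_mean <- mean(tr$obs[k, "CHOPlevel"])
    st <- bax_status(tr$state[j, "BAXa"], chop_mean)
    data.frame(step = i, mUFPT = steps[i], t_end = tend,
               BAXa = unname(tr$state[j, "BAXa"]),
               bax_active = st$active, chop_mean = chop_mean)
  }))
  rownames(per_step) <- NULL
  res$per_step <- per_step
  res
}

#' Steady-state response curve of an adaptive-response module
#'
#' Sweeps the conserved total unfolded protein of a module-only build and
#' records the relaxed observables at each grid point (each point continues
#' from the previous relaxed state with the UFP total reset).
#'
#' @param module One of `"receptor"`, `"ire1"`, `"atf6"`.
#' @param ufpt_grid Total-UFP grid (acu).
#' @param variant Receptor activation variant (receptor module only).
#' @param knockout ATF6 knockouts (atf6 module only).
#' @param config Optional module config object overriding the default.
#' @param t_eq Relaxation time per grid point (atu).
#' @return Data frame: `UFPT` plus the module's observables
#'   (`RA`/`IRE1A`, `BiPT`, ...).
#' @export
run_response_curve <- function(module = c("receptor", "ire1", "atf6"),
                               ufpt_grid = c(0, 2, 5, 10, 20, 50, 100, 200,
                                             400, 800, 1500),
                               variant = "standard",
                               knockout = character(0), config = NULL,
                               t_eq = 4000) {
  module <- match.arg(module)
  m <- switch(module,
    receptor = {
      ref <- upr_reference_params()
      pars <- receptor_params(kf = ref[["kfIRE1"]], kr = ref[["krIRE1"]],
                              n = ref[["nIRE1"]], extIRE = 0.1,
                              variant = variant)
      if (!is.null(config)) config else build_receptor_module(pars)
    },
    ire1 = build_ire1_branch(config %||% ire1_config()),
    atf6 = build_atf6_branch(config %||% atf6_config(knockout = knockout))
  )
  x <- initial_state(m)
  rows <- lapply(ufpt_grid, function(u) {
    x0 <- x
    x0["UFP"] <- u
    x0["BUFP"] <- 0
    tr <- integrate_model(m, initial = x0, t_end = t_eq, n_out = 50)
    x <<- tr$state[nrow(tr$state), ]
    x[["UFP"]] <- 0   # reset sweep input; next point sets its own total
    obs <- eval_observables(m, tr$state[nrow(tr$state), ])
    as.data.frame(c(list(UFPT_in = u), as.list(obs)))
  })
  do.call(rbind, rows)
}

scenario_provenance <- function(model, protocol, seed) {
  cfg <- list(model = model$name, parameters = as.list(model$parameters),
              protocol = protocol$segments[, c("rate", "duration")])
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  list(config_hash = unname(tools::md5sum(tf)), seed = seed,
       package_version = as.character(utils::packageVersion("uprsim")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

# --- trajectory / diagram / population writers -----------------------------

#' Write a trajectory as tidy CSV
#'
#' Long format: `time, series, value`, species first, then observables.
#'
#' @param traj A `upr_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- function(mat) {
    if (is.null(mat) || ncol(mat) == 0) return(NULL)
    do.call(rbind, lapply(colnames(mat), function(nm) {
      data.frame(time = traj$times, series = nm, value = mat[, nm])
    }))
  }
  out <- rbind(long(traj$state), long(traj$obs))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#' @param path CSV file.
#' @param n_species Number of leading series to treat as species (the
#'   remainder become observables); default: all series are species.
#' @return A `upr_trajectory` (without protocol/solver metadata).
#' @export
read_trajectory_csv <- function(path, n_species = NULL) {
  d <- utils::read.csv(path)
  series <- unique(d$series)
  times <- sort(unique(d$time))
  mat <- sapply(series, function(nm) d$value[d$series == nm])
  n_species <- n_species %||% length(series)
  structure(list(
    times = times,
    state = mat[, seq_len(n_species), drop = FALSE],
    obs = if (n_species < length(series)) {
      mat[, (n_species + 1L):length(series), drop = FALSE]
    } else NULL,
    protocol = NULL, solver = list(), model_name = "imported"
  ), class = "upr_trajectory")
}

#' Write a bifurcation diagram (branch + envelopes) to CSV/JSON
#'
#' @param branch A `upr_branch`.
#' @param model The model continued on.
#' @param path_csv CSV output for the branch table.
#' @param path_json Optional JSON summary (Hopf/fold points) destination.
#' @param hopf,folds Optional precomputed feature lists.
#' @return `path_csv`, invisibly.
#' @export
write_diagram <- function(branch, model, path_csv, path_json = NULL,
                          hopf = NULL, folds = NULL) {
  utils::write.csv(branch_table(branch, model), path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      parameter = attr(branch, "parameter"),
      hopf = lapply(hopf %||% list(), function(h) {
        list(parameter = h$parameter, omega = h$omega)
      }),
      folds = lapply(folds %||% list(), function(f) {
        list(parameter = f$parameter)
      })
    ), path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_csv)
}

#' Write/read ABC-SMC populations
#'
#' CSV: one row per particle (`generation`, `weight`, `frequency`, one
#' column per parameter); JSON side-car with the seed and epsilon schedule.
#'
#' @param abc An `upr_abc` result.
#' @param path_csv CSV destination.
#' @param path_json Optional JSON metadata destination.
#' @return `path_csv`, invisibly.
#' @export
write_population_csv <- function(abc, path_csv, path_json = NULL) {
  rows <- do.call(rbind, lapply(seq_along(abc), function(g) {
    data.frame(generation = g, weight = abc[[g]]$weights,
               frequency = abc[[g]]$frequency, abc[[g]]$particles,
               check.names = FALSE)
  }))
  utils::write.csv(rows, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      seed = attr(abc, "seed"),
      epsilon = vapply(abc, `[[`, numeric(1), "epsilon"),
      acceptance = vapply(abc, `[[`, numeric(1), "acceptance_rate")
    ), path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_csv)
}

#' @rdname write_population_csv
#' @param path_csv CSV file written by `write_population_csv()`.
#' @return `read_population_csv()`: a list of generations in [abc_smc()]
#'   format.
#' @export
read_population_csv <- function(path_csv) {
  d <- utils::read.csv(path_csv, check.names = FALSE)
  lapply(split(d, d$generation), function(g) {
    list(particles = as.matrix(g[, setdiff(names(g),
           c("generation", "weight", "frequency")), drop = FALSE]),
         weights = g$weight, frequency = g$frequency)
  })
}

#' Read/write a scenario configuration file (YAML)
#'
#' One declarative file covering the model variant flags, parameter
#' overrides, stress protocol and analysis settings.
#'
#' @param path YAML file.
#' @return `read_config()`: a list with (any of) `variant`, `knockout`,
#'   `overrides`, `protocol` (`rates`, `durations`), `analysis`.
#' @examples
#' cfg <- read_config(system.file("extdata", "example_config.yaml",
#'                                package = "uprsim"))
#' model_from_config(cfg)
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$overrides)) cfg$overrides <- unlist(cfg$overrides)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build the assembled model described by a configuration
#' @param config A configuration list from [read_config()].
#' @return A `upr_model`.
#' @export
model_from_config <- function(config) {
  assemble_full_model(
    atf6 = atf6_config(knockout = config$knockout %||% character(0)),
    receptor_variant = config$variant %||% "standard",
    overrides = config$overrides %||% numeric(0))
}
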