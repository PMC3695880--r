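#' @title Steady-state continuation and bifurcation analysis
#' @description Natural-parameter continuation of steady-state branches with
#'   a pseudo-arclength fallback at folds, linear stability from
#'   finite-difference Jacobians, Hopf detection by bisection on the real
#'   part of the crossing eigenvalue pair, simulated limit-cycle envelopes,
#'   and two-sweep bistability (hysteresis) detection.
#' @name bifurcation
NULL

# f and Jacobian factory with a scalar parameter override; also accepts a
# plain function f(x, pval) for analytic test systems
make_par_system <- function(model, parameter) {
  if (is.function(model)) {
    return(list(f = model,
                model_at = function(pval) {
                  stop("supply `guess` when continuing a plain function")
                }))
  }
  if (!parameter %in% names(model$parameters)) {
    stop("unknown parameter '", parameter, "'")
  }
  cc <- compile_model(model)
  p0 <- model$parameters
  list(
    f = function(x, pval) {
      p <- p0
      p[[parameter]] <- pval
      as.numeric(cc$stoich %*% cc$rates(x, p))
    },
    model_at = function(pval) {
      set_parameters(model, stats::setNames(pval, parameter))
    }
  )
}

newton_fixed_par <- function(f, x, pval, tol = 1e-10, max_it = 60) {
  g <- function(x) f(x, pval)
  for (it in seq_len(max_it)) {
    fx <- g(x)
    nrm <- sqrt(sum(fx^2))
    if (nrm < tol) return(list(x = x, ok = TRUE))
    J <- jacobian_fd(g, x)
    step <- tryCatch(
      solve(crossprod(J) + 1e-12 * diag(length(x)), -crossprod(J, fx)),
      error = function(e) NULL)
    if (is.null(step)) return(list(x = x, ok = FALSE))
    alpha <- 1
    improved <- FALSE
    while (alpha >= 1e-5) {
      xn <- x + alpha * as.numeric(step)
      if (all(is.finite(xn)) && sqrt(sum(g(xn)^2)) < nrm) {
        x <- xn; improved <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!improved) return(list(x = x, ok = FALSE))
  }
  list(x = x, ok = sqrt(sum(g(x)^2)) < tol)
}

# one pseudo-arclength corrector step: unknowns (x, p), secant tangent tz
newton_arclength <- function(f, z, z_prev, ds, tz, tol = 1e-10,
                             max_it = 40) {
  n <- length(z) - 1L
  G <- function(z) {
    c(f(z[seq_len(n)], z[n + 1L]), sum((z - z_prev) * tz) - ds)
  }
  for (it in seq_len(max_it)) {
    gz <- G(z)
    if (sqrt(sum(gz^2)) < tol) return(list(z = z, ok = TRUE))
    J <- jacobian_fd(G, z)
    step <- tryCatch(solve(J, -gz), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(
        solve(crossprod(J) + 1e-12 * diag(n + 1L), -crossprod(J, gz)),
        error = function(e) NULL)
    }
    if (is.null(step)) return(list(z = z, ok = FALSE))
    z <- z + as.numeric(step)
  }
  list(z = z, ok = sqrt(sum(G(z)^2)) < tol)
}

branch_point <- function(f, x, pval, stab_tol = 1e-8) {
  J <- jacobian_fd(function(xx) f(xx, pval), x)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(parameter = pval, state = x, eigenvalues = ev,
       stable = max(Re(ev)) < stab_tol)
}

#' Continue a steady-state branch over a parameter
#'
#' Natural-parameter continuation with adaptive step size; when the
#' fixed-parameter corrector fails (typically approaching a fold) the
#' continuation switches to pseudo-arclength steps along the secant tangent,
#' so folds are traversed rather than truncated. Each accepted point stores
#' the steady state, its eigenvalues and a stability label.
#'
#' @param model A `upr_model`.
#' @param parameter Name of the swept parameter.
#' @param range Numeric `c(from, to)`.
#' @param guess Starting state at `range[1]`; defaults to the model's
#'   initials (refined by [steady_state()]-style iteration).
#' @param n_steps Target number of steps across the range (controls the
#'   initial parameter step).
#' @param max_points Hard cap on accepted points (fold-back branches can
#'   exceed `n_steps`).
#' @param tol Residual tolerance for each branch point.
#' @param stab_tol Eigenvalue tolerance for the stability label.
#' @return An object of class `upr_branch`: list of points, each with
#'   `parameter`, `state`, `eigenvalues`, `stable`; attribute `incomplete`
#'   is `TRUE` (with a warning) when the branch was lost before reaching the
#'   end of the range.
#' @export
continue_branch <- function(model, parameter, range, guess = NULL,
                            n_steps = 60, max_points = 1200, tol = 1e-10,
                            stab_tol = 1e-8) {
  sys <- make_par_system(model, parameter)
  f <- sys$f
  x0 <- as.numeric(guess %||% steady_state(
    sys$model_at(range[1]), tol = 1e-9)$state)
  st <- newton_fixed_par(f, x0, range[1], tol = tol)
  if (!st$ok) stop("continue_branch: no converged start at range[1]")
  dir <- sign(range[2] - range[1])
  dp0 <- (range[2] - range[1]) / n_steps
  points <- list(branch_point(f, st$x, range[1], stab_tol))
  x <- st$x; pval <- range[1]
  incomplete <- FALSE
  # seed a second point with one natural-parameter step
  seeded <- FALSE
  dp <- dp0
  while (abs(dp) >= abs(dp0) / 256) {
    st <- newton_fixed_par(f, x, pval + dp, tol = tol)
    if (st$ok) {
      points[[2L]] <- branch_point(f, st$x, pval + dp, stab_tol)
      z_prev <- c(x, pval)
      x <- st$x; pval <- pval + dp
      seeded <- TRUE
      break
    }
    dp <- dp / 2
  }
  if (!seeded) {
    warning("continue_branch: could not leave the starting point")
    return(structure(points, class = "upr_branch", parameter = parameter,
                     incomplete = TRUE,
                     model_name = if (is.function(model)) "function"
                                  else model$name))
  }
  # pseudo-arclength marching with secant predictor; traverses folds
  z <- c(x, pval)
  ds <- sqrt(sum((z - z_prev)^2))
  while (length(points) < max_points) {
    lo <- min(range); hi <- max(range)
    if (pval > hi + 1e-12 || pval < lo - 1e-12) break
    tz <- (z - z_prev) / sqrt(sum((z - z_prev)^2))
    # cap the step so that flat branch segments are resolved at the
    # requested parameter resolution, while steep (state-dominated)
    # segments may take correspondingly longer arclength steps
    ds_max <- abs(dp0) / max(abs(tz[length(tz)]), 0.02)
    stepped <- FALSE
    for (tries in 1:10) {
      res <- newton_arclength(f, z + ds * tz, z, ds, tz, tol = tol)
      if (res$ok &&
          sqrt(sum((res$z - z)^2)) < 4 * ds + 1e-12) {
        stepped <- TRUE
        break
      }
      ds <- ds / 2
    }
    if (!stepped) {
      incomplete <- TRUE
      warning("continue_branch: branch lost at ", parameter, " = ",
              signif(pval, 6), "; partial branch returned")
      break
    }
    z_prev <- z
    z <- res$z
    x <- z[seq_along(x)]
    pval <- z[length(z)]
    points[[length(points) + 1L]] <- branch_point(f, x, pval, stab_tol)
    ds <- min(ds * 1.4, ds_max)
  }
  structure(points, class = "upr_branch", parameter = parameter,
            incomplete = incomplete,
            model_name = if (is.function(model)) "function" else model$name)
}

#' @export
print.upr_branch <- function(x, ...) {
  cat("<upr_branch> over ", attr(x, "parameter"), ": ", length(x),
      " points, ", sum(vapply(x, `[[`, logical(1), "stable")),
      " stable\n", sep = "")
  invisible(x)
}

#' Branch summary table
#' @param branch A `upr_branch`.
#' @param model The model the branch was computed on (for species names).
#' @return Data frame with the parameter value, stability, leading
#'   eigenvalue real/imaginary part, and one column per species.
#' @export
branch_table <- function(branch, model) {
  pars <- vapply(branch, `[[`, numeric(1), "parameter")
  stab <- vapply(branch, `[[`, logical(1), "stable")
  lead <- t(vapply(branch, function(b) {
    ev <- b$eigenvalues
    cplx <- ev[abs(Im(ev)) > 1e-8]
    lead <- if (length(cplx)) cplx[which.max(Re(cplx))] else ev[1]
    c(Re(lead), Im(lead))
  }, numeric(2)))
  states <- t(vapply(branch, `[[`, numeric(length(model$species)), "state"))
  colnames(states) <- species_ids(model)
  data.frame(parameter = pars, stable = stab,
             re_lead = lead[, 1], im_lead = lead[, 2], states,
             check.names = FALSE)
}

# maximal real part over complex eigenvalue pairs (NA if none)
max_re_complex <- function(ev, im_tol = 1e-8) {
  cplx <- ev[Im(ev) > im_tol]   # one of each conjugate pair
  if (!length(cplx)) return(NA_real_)
  max(Re(cplx))
}

#' Detect Hopf bifurcations along a branch
#'
#' Scans adjacent branch points for a sign change of the maximal real part
#' over complex-conjugate eigenvalue pairs and refines each crossing by
#' bisection in the parameter (re-solving the steady state at each trial
#' value) until the real part is below `tol`. Returns all crossings; an
#' empty result is valid.
#'
#' @param branch A `upr_branch` from [continue_branch()].
#' @param model The model the branch was computed on.
#' @param tol Bisection tolerance on the real part of the crossing pair.
#' @param im_tol Minimal imaginary part for a pair to count as complex.
#' @return List of Hopf points: `parameter`, `state`, `omega` (imaginary
#'   part at onset, the angular frequency of the nascent cycle).
#' @export
detect_hopf <- function(branch, model, tol = 1e-8, im_tol = 1e-8) {
  parameter <- attr(branch, "parameter")
  sys <- make_par_system(model, parameter)
  f <- sys$f
  res <- list()
  re_at <- function(x, pval) {
    bp <- branch_point(f, x, pval)
    list(re = max_re_complex(bp$eigenvalues, im_tol), bp = bp)
  }
  for (k in seq_len(length(branch) - 1L)) {
    a <- branch[[k]]; b <- branch[[k + 1L]]
    ra <- max_re_complex(a$eigenvalues, im_tol)
    rb <- max_re_complex(b$eigenvalues, im_tol)
    if (is.na(ra) || is.na(rb) || ra * rb > 0) next
    lo <- a$parameter; hi <- b$parameter
    xlo <- a$state; rlo <- ra
    bp_mid <- NULL
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      st <- newton_fixed_par(f, xlo, mid, tol = 1e-11)
      if (!st$ok) break
      rm_ <- re_at(st$x, mid)
      bp_mid <- rm_$bp
      if (is.na(rm_$re)) break
      if (abs(rm_$re) < tol) break
      if (rm_$re * rlo > 0) {
        lo <- mid; xlo <- st$x; rlo <- rm_$re
      } else {
        hi <- mid
      }
    }
    if (is.null(bp_mid)) next
    ev <- bp_mid$eigenvalues
    cplx <- ev[Im(ev) > im_tol]
    omega <- abs(Im(cplx[which.max(Re(cplx))]))
    state <- bp_mid$state
    if (!is.function(model)) {
      state <- stats::setNames(state, species_ids(model))
    }
    res[[length(res) + 1L]] <- list(parameter = bp_mid$parameter,
                                    state = state, omega = omega)
  }
  res
}

#' Detect fold (saddle-node) points along a branch
#'
#' Folds are located as extrema of the parameter along the branch ordering
#' (the signature of pseudo-arclength fold traversal).
#'
#' @param branch A `upr_branch`.
#' @return List of fold points (`parameter`, `state`), possibly empty.
#' @export
detect_folds <- function(branch) {
  pars <- vapply(branch, `[[`, numeric(1), "parameter")
  if (length(pars) < 3) return(list())
  d <- diff(pars)
  idx <- which(d[-length(d)] * d[-1] < 0) + 1L
  # refine each extremum by the vertex of a quadratic in arclength through
  # the three surrounding points
  lapply(idx, function(i) {
    s <- c(0, cumsum(vapply(seq_len(length(branch) - 1L), function(k) {
      sqrt(sum((c(branch[[k + 1L]]$state, pars[k + 1L]) -
                  c(branch[[k]]$state, pars[k]))^2))
    }, numeric(1))))
    ks <- max(1L, i - 1L):min(length(pars), i + 1L)
    pfold <- pars[i]
    if (length(ks) == 3L) {
      fit <- stats::lm.fit(cbind(1, s[ks], s[ks]^2), pars[ks])
      cf <- fit$coefficients
      if (is.finite(cf[3]) && cf[3] != 0) {
        sv <- -cf[2] / (2 * cf[3])
        if (sv >= s[ks[1]] && sv <= s[ks[3]]) {
          pfold <- cf[1] + cf[2] * sv + cf[3] * sv^2
        }
      }
    }
    list(parameter = pfold, state = branch[[i]]$state)
  })
}

#' Limit-cycle min/max envelopes by simulation
#'
#' For each parameter value of a grid (typically spanning the window between
#' two Hopf points), integrates the model for `t_end` atu, discards the
#' transient and records the post-transient minimum and maximum of each
#' requested series. Near a supercritical Hopf point the envelope width
#' shrinks to zero.
#'
#' @param model A `upr_model`.
#' @param parameter Swept parameter name.
#' @param grid Numeric vector of parameter values.
#' @param species Character vector of species/observable names.
#' @param t_end Simulation length per grid point (atu).
#' @param transient_fraction Fraction discarded before taking min/max.
#' @param guess Initial state (defaults to model initials); each grid point
#'   continues from the previous end state.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `parameter`, `series`, `min`, `max`,
#'   `sustained`.
#' @export
limit_cycle_envelope <- function(model, parameter, grid, species,
                                 t_end = 1500, transient_fraction = 0.5,
                                 guess = NULL, rtol = 1e-8, atol = 1e-10) {
  y <- guess %||% initial_state(model)
  rows <- list()
  for (pv in grid) {
    m <- set_parameters(model, stats::setNames(pv, parameter))
    tr <- integrate_model(m, initial = y, t_end = t_end, n_out = 2000,
                          rtol = rtol, atol = atol)
    y <- stats::setNames(tr$state[nrow(tr$state), ], species_ids(model))
    keep <- tr$times >= transient_fraction * t_end
    for (nm in species) {
      s <- trajectory_series(tr, nm)[keep]
      om <- oscillation_metrics(tr, nm,
                                transient_fraction = transient_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pv, series = nm, min = min(s), max = max(s),
        sustained = om$sustained)
    }
  }
  do.call(rbind, rows)
}

#' Detect bistability by quasi-static up/down parameter sweeps
#'
#' Sweeps the parameter up and then down across the range in small
#' increments, re-equilibrating the model at each step from the previous
#' state, and reports the interval(s) where the two sweeps settle on states
#' that differ beyond tolerance. For a hysteretic switch the up-sweep
#' activation threshold exceeds the down-sweep deactivation threshold.
#'
#' @param model A `upr_model`.
#' @param parameter Swept parameter name.
#' @param range Numeric `c(from, to)`.
#' @param n_steps Number of sweep increments (default 100, i.e. 1% of the
#'   range per step).
#' @param t_eq Re-equilibration time per step (atu, default 500).
#' @param species Series used for the state comparison (default: all
#'   species, via Euclidean distance).
#' @param tol Relative difference above which the sweeps count as distinct.
#' @return List with `bistable` (logical), `intervals` (data frame of
#'   `lower`, `upper`), `up`, `down` (sweep tables of parameter and final
#'   state), `up_threshold`, `down_threshold` (first parameter values at
#'   which each sweep jumps branch, `NA` if no jump).
#' @export
detect_bistability <- function(model, parameter, range, n_steps = 100,
                               t_eq = 500, species = NULL, tol = 0.05) {
  grid_up <- seq(range[1], range[2], length.out = n_steps + 1L)
  sweep <- function(grid) {
    y <- initial_state(model)
    states <- matrix(NA_real_, length(grid), length(y))
    colnames(states) <- species_ids(model)
    for (i in seq_along(grid)) {
      m <- set_parameters(model, stats::setNames(grid[i], parameter))
      tr <- integrate_model(m, initial = y, t_end = t_eq, n_out = 60,
                            rtol = 1e-8, atol = 1e-10)
      y <- stats::setNames(tr$state[nrow(tr$state), ], species_ids(model))
      states[i, ] <- y
    }
    states
  }
  up <- sweep(grid_up)
  down <- sweep(rev(grid_up))[rev(seq_along(grid_up)), , drop = FALSE]
  cols <- species %||% colnames(up)
  scale <- pmax(apply(abs(up[, cols, drop = FALSE]), 2, max),
                apply(abs(down[, cols, drop = FALSE]), 2, max), 1e-12)
  reldiff <- vapply(seq_along(grid_up), function(i) {
    max(abs(up[i, cols] - down[i, cols]) / scale)
  }, numeric(1))
  mask <- reldiff > tol
  intervals <- NULL
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    intervals <- data.frame(lower = grid_up[starts[keep]],
                            upper = grid_up[ends[keep]])
  }
  jump_par <- function(states, grid) {
    d <- sqrt(rowSums((diff(states[, cols, drop = FALSE]) /
                         rep(scale, each = nrow(states) - 1L))^2))
    i <- which.max(d)
    if (!length(i) || d[i] < tol) return(NA_real_)
    grid[i + 1L]
  }
  list(bistable = any(mask), intervals = intervals,
       up = cbind(parameter = grid_up, up),
       down = cbind(parameter = grid_up, down),
       up_threshold = jump_par(up, grid_up),
       down_threshold = jump_par(down[rev(seq_along(grid_up)), ,
                                      drop = FALSE], rev(grid_up)))
}

#' Classify the activity state at a stress or input level
#'
#' Simulates the model at the queried parameter value (from its initial /
#' pre-equilibrated state) and classifies the late-time behaviour into the
#' three canonical activity states: `low` (converged, CHOP below the
#' low/high midpoint and translation above its midpoint), `intermediate`
#' (sustained oscillations in CHOP or translation), `high` (converged, CHOP
#' above the midpoint and translation virtually suspended). Reference
#' midpoints default to the means of the CHOP and translation levels
#' attained at the extremes `ref_values` of the swept input (the diagram's
#' own low/high asymptotes); pass `thresholds` to override. An inconsistent
#' signature is labelled `ambiguous` with diagnostics, never silently
#' coerced.
#'
#' @param model A `upr_model` exposing observables `CHOPlevel` and
#'   `translation`.
#' @param parameter Swept input name (`"mUFPT"` for the full model,
#'   `"PERKA"` for the standalone PERK branch).
#' @param value Queried input value.
#' @param ref_values Length-2 vector of asymptotic low/high input values
#'   used to derive default midpoints.
#' @param thresholds Optional list with `chop_mid` and `translation_mid`.
#' @param t_end Simulation length (atu).
#' @param initial Optional starting state (defaults to model initials).
#' @param transient_fraction Transient discard for the oscillation test.
#' @return List with `label` (`"low"`, `"intermediate"`, `"high"` or
#'   `"ambiguous"`), `diagnostics` (end-window CHOP and translation means,
#'   oscillation metrics, thresholds) and the trajectory.
#' @export
classify_activity_state <- function(model, parameter, value,
                                    ref_values = NULL, thresholds = NULL,
                                    t_end = 1500, initial = NULL,
                                    transient_fraction = 0.5) {
  need <- c("CHOPlevel", "translation")
  if (!all(need %in% names(model$observables))) {
    stop("classify_activity_state: model must expose CHOPlevel and ",
         "translation observables")
  }
  if (is.null(thresholds)) {
    if (is.null(ref_values)) {
      ref_values <- switch(parameter,
                           mUFPT = c(6, 24), PERKA = c(0.002, 0.45),
                           stop("classify_activity_state: supply ref_values ",
                                "or thresholds for parameter '", parameter,
                                "'"))
    }
    asymp <- lapply(ref_values, function(v) {
      m <- set_parameters(model, stats::setNames(v, parameter))
      tr <- integrate_model(m, initial = initial, t_end = t_end,
                            n_out = 500)
      n <- length(tr$times)
      keep <- seq(floor(0.8 * n), n)
      c(chop = mean(tr$obs[keep, "CHOPlevel"]),
        translation = mean(tr$obs[keep, "translation"]))
    })
    thresholds <- list(
      chop_mid = mean(c(asymp[[1]]["chop"], asymp[[2]]["chop"])),
      translation_mid = mean(c(asymp[[1]]["translation"],
                               asymp[[2]]["translation"])))
  }
  m <- set_parameters(model, stats::setNames(value, parameter))
  tr <- integrate_model(m, initial = initial, t_end = t_end, n_out = 2000)
  om_chop <- oscillation_metrics(tr, "CHOPlevel",
                                 transient_fraction = transient_fraction)
  om_tra <- oscillation_metrics(tr, "translation",
                                transient_fraction = transient_fraction)
  n <- length(tr$times)
  keep <- seq(floor(0.8 * n), n)
  chop_end <- mean(tr$obs[keep, "CHOPlevel"])
  tra_end <- mean(tr$obs[keep, "translation"])
  diag <- list(chop_end = chop_end, translation_end = tra_end,
               osc_chop = om_chop, osc_translation = om_tra,
               thresholds = thresholds)
  label <- if (om_chop$sustained || om_tra$sustained) {
    "intermediate"
  } else if (chop_end <= thresholds$chop_mid &&
             tra_end >= thresholds$translation_mid) {
    "low"
  } else if (chop_end > thresholds$chop_mid &&
             tra_end < thresholds$translation_mid) {
    "high"
  } else {
    "ambiguous"
  }
  list(label = label, diagnostics = diag, trajectory = tr)
}
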