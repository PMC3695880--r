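#' Piecewise-constant stress protocol
#'
#' A stress protocol is an ordered list of segments, each holding the
#' unfolded-protein accumulation rate `mUFPT` (acu/atu) constant for a given
#' duration (atu). The named presets are constant-rate protocols at the
#' mild/moderate/severe reference stress levels mUFPT = 12, 15, 18.
#'
#' @param rates Numeric vector of segment `mUFPT` values (`>= 0`), or one of
#'   `"mild"`, `"moderate"`, `"severe"`.
#' @param durations Numeric vector of segment durations (atu, `> 0`),
#'   recycled against `rates`.
#' @return An object of class `upr_protocol` with a `segments` data frame.
#' @examples
#' stress_protocol("moderate", durations = 300)
#' stress_protocol(c(12, 15, 18), durations = 500)  # stepwise escalation
#' @export
stress_protocol <- function(rates, durations = 500) {
  if (is.character(rates)) {
    rates <- switch(match.arg(rates, c("mild", "moderate", "severe")),
                    mild = 12, moderate = 15, severe = 18)
  }
  if (any(rates < 0)) stop("stress_protocol: rates must be >= 0")
  if (any(durations <= 0)) stop("stress_protocol: durations must be > 0")
  seg <- data.frame(rate = rates,
                    duration = rep_len(durations, length(rates)))
  seg$t_end <- cumsum(seg$duration)
  seg$t_start <- seg$t_end - seg$duration
  structure(list(segments = seg), class = "upr_protocol")
}

#' @export
print.upr_protocol <- function(x, ...) {
  cat("<upr_protocol> ", nrow(x$segments), " segment(s), total ",
      max(x$segments$t_end), " atu\n", sep = "")
  print(x$segments[, c("t_start", "t_end", "rate")], row.names = FALSE)
  invisible(x)
}

#' Protocol rate at a given time
#' @param protocol A [stress_protocol()] (or `NULL` for no stress input).
#' @param t Time (atu); times beyond the last segment hold its rate.
#' @return `mUFPT` value at `t`.
#' @export
protocol_rate <- function(protocol, t) {
  if (is.null(protocol)) return(0)
  seg <- protocol$segments
  i <- findInterval(t, seg$t_start, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  seg$rate[i]
}

#' Evaluate the model right-hand side
#'
#' Evaluates all reaction rate laws at a state and returns the state
#' derivative; the protocol (if any) overrides the `mUFPT` parameter at time
#' `t`. A non-finite rate aborts with a diagnostic naming the offending
#' reaction.
#'
#' @param model A `upr_model`.
#' @param state Named (or ordered) numeric state vector matching the species
#'   count.
#' @param t Time (atu), used only to look up the protocol rate.
#' @param protocol A [stress_protocol()] or `NULL`.
#' @param compiled Optional cached result of [compile_model()].
#' @return Named numeric vector of time derivatives.
#' @export
model_rhs <- function(model, state, t = 0, protocol = NULL,
                      compiled = NULL) {
  cc <- compiled %||% compile_model(model)
  if (length(state) != length(model$species)) {
    stop("model_rhs: state length ", length(state), " != species count ",
         length(model$species))
  }
  p <- model$parameters
  if (!is.null(protocol) && "mUFPT" %in% names(p)) {
    p[["mUFPT"]] <- protocol_rate(protocol, t)
  }
  v <- cc$rates(as.numeric(state), p)
  if (any(!is.finite(v))) {
    bad <- colnames(cc$stoich)[which(!is.finite(v))]
    stop("model_rhs: non-finite rate in reaction(s): ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(as.numeric(cc$stoich %*% v), species_ids(model))
}

# deSolve-style rhs closure (fast inner loop; no per-call validation)
make_desolve_rhs <- function(model, compiled) {
  stoich <- compiled$stoich
  rates <- compiled$rates
  function(t, y, parms) {
    list(as.numeric(stoich %*% rates(y, parms)))
  }
}

#' Integrate the model under a stress protocol
#'
#' Stiff-capable integration (deSolve `lsoda`) with event-free piecewise
#' restarts at protocol segment boundaries and dense output on a uniform
#' grid. Small negative excursions from the integrator are clamped at the
#' reported output (tolerance `-1e-9`).
#'
#' @param model A `upr_model`.
#' @param initial Named initial state; defaults to the model's declared
#'   initial amounts.
#' @param protocol A [stress_protocol()] or `NULL` (autonomous run using the
#'   model's own `mUFPT` parameter, if present).
#' @param t_end Final time (atu, `> 0`); defaults to the protocol's total
#'   duration.
#' @param n_out Number of uniformly spaced output points (>= 2000 by
#'   default).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param method deSolve method (default `"lsoda"`).
#' @return An object of class `upr_trajectory`: `times`, `state` (time x
#'   species matrix), `obs` (time x observables), `protocol`, `solver`
#'   metadata.
#' @export
integrate_model <- function(model, initial = NULL, protocol = NULL,
                            t_end = NULL, n_out = 2000, rtol = 1e-8,
                            atol = 1e-10, method = "lsoda",
                            use_compiled = TRUE) {
  fp <- if (use_compiled) fastpath_for(model) else NULL
  cc <- if (is.null(fp)) compile_model(model) else NULL
  y0 <- initial %||% initial_state(model)
  if (is.null(t_end)) {
    if (is.null(protocol)) stop("integrate_model: t_end required without a protocol")
    t_end <- max(protocol$segments$t_end)
  }
  if (t_end <= 0) stop("integrate_model: t_end must be > 0")
  times <- seq(0, t_end, length.out = max(n_out, 2))
  rhs <- if (is.null(fp)) make_desolve_rhs(model, cc) else NULL
  pars <- if (is.null(fp)) model$parameters else fp$parms
  # segment boundaries within [0, t_end] are integration restarts
  bounds <- 0
  if (!is.null(protocol)) {
    bounds <- sort(unique(c(0, protocol$segments$t_start[
      protocol$segments$t_start < t_end])))
  }
  bounds <- c(bounds, t_end)
  out <- matrix(NA_real_, length(times), length(y0))
  colnames(out) <- species_ids(model)
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    p <- pars
    if (!is.null(protocol) && "mUFPT" %in% names(p)) {
      p[["mUFPT"]] <- protocol_rate(protocol, (t0 + t1) / 2)
    }
    idx <- which(times > t0 & times <= t1)
    seg_times <- unique(c(t0, times[idx], t1))
    sol <- if (is.null(fp)) {
      deSolve::ode(y = y, times = seg_times, func = rhs, parms = p,
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 50000)
    } else {
      deSolve::ode(y = y, times = seg_times, func = fp$func,
                   initfunc = fp$initfunc, dllname = "uprsim", parms = p,
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 50000)
    }
    if (attr(sol, "istate")[1L] < 0 || max(sol[, 1]) < t1 - 1e-8) {
      stop("integrate_model: integration failed at t = ",
           signif(max(sol[, 1]), 6), " atu")
    }
    if (length(idx)) {
      out[idx, ] <- sol[match(times[idx], sol[, 1]), -1, drop = FALSE]
    }
    y <- sol[nrow(sol), -1]
  }
  if (min(out, na.rm = TRUE) < -1e-6) {
    warning("integrate_model: negative concentrations beyond tolerance")
  }
  out[out < 0 & out > -1e-6] <- 0
  traj <- structure(list(
    times = times, state = out,
    obs = eval_observables(model, out),
    protocol = protocol,
    solver = list(method = method, rtol = rtol, atol = atol, n_out = n_out),
    model_name = model$name
  ), class = "upr_trajectory")
  traj
}

#' @export
print.upr_trajectory <- function(x, ...) {
  cat("<upr_trajectory> ", x$model_name, ": ", length(x$times),
      " points over ", max(x$times), " atu, ", ncol(x$state), " species\n",
      sep = "")
  invisible(x)
}

#' Extract a series (species or observable) from a trajectory
#' @param traj A `upr_trajectory`.
#' @param name Species or observable name.
#' @return Numeric vector aligned with `traj$times`.
#' @export
trajectory_series <- function(traj, name) {
  if (name %in% colnames(traj$state)) return(traj$state[, name])
  if (!is.null(traj$obs) && name %in% colnames(traj$obs)) {
    return(traj$obs[, name])
  }
  stop("trajectory_series: no species or observable named '", name, "'")
}

# central finite-difference Jacobian of f at x
jacobian_fd <- function(f, x, rel_step = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), 1e-3)
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Find a steady state of the model
#'
#' Damped Gauss-Newton root finding on the right-hand side (tolerant of the
#' singular Jacobians that arise from conservation relations), falling back
#' to long-time integration restarts when the iteration stalls. Stability is
#' assessed from the eigenvalues of the finite-difference Jacobian: the point
#' is flagged stable when every eigenvalue real part is below the tolerance
#' (neutral directions from conservation relations count as stable).
#'
#' @param model A `upr_model`.
#' @param mUFPT Optional stress rate; if given, overrides the model's
#'   `mUFPT` parameter.
#' @param guess Initial state guess; defaults to the declared initials.
#' @param tol Residual norm target (default `1e-10`).
#' @param stab_tol Eigenvalue real-part tolerance for the stability flag.
#' @param max_rounds Newton/integration alternation rounds before giving up.
#' @return List with `state` (named vector), `residual`, `stable` (logical),
#'   `eigenvalues` (complex vector, sorted by decreasing real part).
#' @export
steady_state <- function(model, mUFPT = NULL, guess = NULL, tol = 1e-10,
                         stab_tol = 1e-8, max_rounds = 6) {
  if (!is.null(mUFPT)) {
    if (!"mUFPT" %in% names(model$parameters)) {
      stop("steady_state: model has no mUFPT parameter")
    }
    model <- set_parameters(model, mUFPT = mUFPT)
  }
  cc <- compile_model(model)
  p <- model$parameters
  f <- function(x) as.numeric(cc$stoich %*% cc$rates(x, p))
  x <- as.numeric(guess %||% initial_state(model))
  scale <- max(1, max(abs(x)))
  newton <- function(x) {
    for (it in 1:80) {
      fx <- f(x)
      if (sqrt(sum(fx^2)) < tol) return(list(x = x, ok = TRUE))
      J <- jacobian_fd(f, x)
      lambda <- 1e-10
      step <- tryCatch(
        solve(crossprod(J) + lambda * diag(length(x)), -crossprod(J, fx)),
        error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      alpha <- 1
      repeat {
        xn <- x + alpha * as.numeric(step)
        xn[xn < 0 & xn > -1e-12 * scale] <- 0
        if (all(xn >= 0) && all(is.finite(xn)) &&
            sqrt(sum(f(xn)^2)) < sqrt(sum(fx^2)) * (1 - 1e-4 * alpha)) {
          x <- xn
          break
        }
        alpha <- alpha / 2
        if (alpha < 1e-6) return(list(x = x, ok = FALSE))
      }
    }
    list(x = x, ok = sqrt(sum(f(x)^2)) < tol)
  }
  ok <- FALSE
  for (round in seq_len(max_rounds)) {
    res <- newton(x)
    x <- res$x
    if (res$ok) { ok <- TRUE; break }
    # relax towards an attractor, then retry the root finder
    tr <- integrate_model(model,
                          initial = stats::setNames(pmax(x, 0),
                                                    species_ids(model)),
                          t_end = 500 * round, n_out = 50, rtol = 1e-8,
                          atol = 1e-10)
    x <- as.numeric(tr$state[nrow(tr$state), ])
  }
  if (!ok) {
    stop("steady_state: no convergence (residual ",
         signif(sqrt(sum(f(x)^2)), 3), ")")
  }
  J <- jacobian_fd(f, x)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(state = stats::setNames(x, species_ids(model)),
       residual = sqrt(sum(f(x)^2)),
       stable = max(Re(ev)) < stab_tol,
       eigenvalues = ev)
}

# --- reduced ATF4/GADD34 delay model ---------------------------------------

#' Reduced two-variable ATF4/GADD34 delay model
#'
#' A minimal skeleton of the PERK-branch negative feedback used to isolate
#' the origin of the intermediate-state oscillations. The fast eIF2alpha
#' phosphorylation cycle is taken at quasi-steady state, giving the
#' phosphorylated fraction `p = PERKA / (PERKA + kg * (GADD34 + CReP))`;
#' ATF4 translation switches on when `p` exceeds the attenuation midpoint
#' (Hill response), and GADD34 induction follows ATF4 with a discrete delay
#' `tau` standing in for the intervening genetic steps:
#'
#' \deqn{A'(t) = k_{sA}\, H(p(t)) - k_{dA} A(t)}
#' \deqn{G'(t) = k_{sG}\, \frac{A(t-\tau)}{K_{mG} + A(t-\tau)} - k_{dG} G(t)}
#'
#' At `tau = 0` the two-variable feedback relaxes monotonically (no
#' sustained oscillation); a sufficient delay destabilises the intermediate
#' state into a limit cycle whose period grows with `tau`.
#'
#' @param PERKA Clamped active-PERK input level.
#' @param tau Delay (atu, `>= 0`) between ATF4 activation and GADD34
#'   expression.
#' @param pars Named overrides of the kinetic constants
#'   `ksA, kdA, kATF4, nh, kg, CReP, ksG, KmG, kdG`.
#' @return An object of class `upr_delay_model`.
#' @export
reduced_delay_model <- function(PERKA = 2, tau = 6, pars = numeric(0)) {
  if (tau < 0) stop("reduced_delay_model: tau must be >= 0")
  p <- c(ksA = 0.2, kdA = 0.25, kATF4 = 0.9, nh = 20, kg = 1.75,
         CReP = 0.05, ksG = 0.45, KmG = 0.45, kdG = 0.3)
  unknown <- setdiff(names(pars), names(p))
  if (length(unknown)) {
    stop("reduced_delay_model: unknown parameters: ",
         paste(unknown, collapse = ", "))
  }
  p[names(pars)] <- pars
  structure(list(PERKA = PERKA, tau = tau, pars = p),
            class = "upr_delay_model")
}

#' Integrate the reduced delay model
#'
#' Delay-differential integration via deSolve's interpolated-history solver
#' (`dede`); at `tau = 0` the same path reduces exactly to the ODE limit.
#'
#' @param model A [reduced_delay_model()].
#' @param history Constant history state `c(ATF4, GADD34)` on `[-tau, 0]`,
#'   or a function of time returning that vector.
#' @param t_end Final time (atu).
#' @param n_out Output grid size.
#' @return A `upr_trajectory` with state columns `ATF4`, `GADD34` and
#'   observable `phospho_frac`.
#' @export
integrate_dde <- function(model, history = c(ATF4 = 0, GADD34 = 0),
                          t_end = 500, n_out = 2000) {
  stopifnot(inherits(model, "upr_delay_model"))
  p <- model$pars
  P <- model$PERKA
  tau <- model$tau
  hfun <- if (is.function(history)) history else function(t) unname(history)
  pfrac <- function(G) P / (P + p[["kg"]] * (G + p[["CReP"]]))
  hill <- function(x) {
    r <- (x / p[["kATF4"]])^p[["nh"]]
    r / (1 + r)
  }
  deriv <- function(t, y, parms) {
    Alag <- if (tau == 0) y[1] else {
      if (t > tau) deSolve::lagvalue(t - tau, 1) else hfun(t - tau)[1]
    }
    dA <- p[["ksA"]] * hill(pfrac(y[2])) - p[["kdA"]] * y[1]
    dG <- p[["ksG"]] * Alag / (p[["KmG"]] + Alag) - p[["kdG"]] * y[2]
    list(c(dA, dG))
  }
  times <- seq(0, t_end, length.out = n_out)
  y0 <- hfun(0)
  sol <- if (tau == 0) {
    deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = 1e-8, atol = 1e-10)
  } else {
    deSolve::dede(y = y0, times = times, func = deriv, parms = NULL,
                  rtol = 1e-8, atol = 1e-10)
  }
  state <- sol[, -1, drop = FALSE]
  colnames(state) <- c("ATF4", "GADD34")
  structure(list(
    times = sol[, 1], state = state,
    obs = cbind(phospho_frac = pfrac(state[, "GADD34"])),
    protocol = NULL,
    solver = list(method = if (tau == 0) "lsoda" else "dede",
                  rtol = 1e-8, atol = 1e-10, tau = tau),
    model_name = "reduced_delay"
  ), class = "upr_trajectory")
}

#' Integrate the linear test delay equation x'(t) = -x(t - tau)
#'
#' The classical scalar benchmark for delay-induced oscillation: solutions
#' decay monotonically for small delay, decay with oscillation beyond
#' `tau = 1/e`, and the oscillation becomes self-sustaining (neutral) at
#' `tau = pi/2`, growing beyond it. Used to validate the delay-integration
#' machinery against the characteristic-equation root.
#'
#' @param tau Delay (`>= 0`).
#' @param x0 Constant history value on `[-tau, 0]`.
#' @param t_end Final time.
#' @param n_out Output grid size.
#' @return A `upr_trajectory` with single state column `x`.
#' @export
integrate_linear_dde <- function(tau, x0 = 1, t_end = 100, n_out = 2000) {
  if (tau < 0) stop("integrate_linear_dde: tau must be >= 0")
  deriv <- function(t, y, parms) {
    xlag <- if (tau == 0) y[1] else {
      if (t > tau) deSolve::lagvalue(t - tau, 1) else x0
    }
    list(-xlag)
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- if (tau == 0) {
    deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = 1e-10, atol = 1e-12)
  } else {
    deSolve::dede(y = x0, times = times, func = deriv, parms = NULL,
                  rtol = 1e-10, atol = 1e-12)
  }
  state <- sol[, -1, drop = FALSE]
  colnames(state) <- "x"
  structure(list(times = sol[, 1], state = state, obs = NULL,
                 protocol = NULL,
                 solver = list(method = "dede", tau = tau),
                 model_name = "linear_dde"),
            class = "upr_trajectory")
}

# --- trajectory metrics ----------------------------------------------------

#' Oscillation metrics of a trajectory series
#'
#' Discards the initial transient, locates interior maxima and minima, and
#' reports the oscillation frequency ((number of maxima - 1) / time between
#' the first and last maximum), the relative peak-to-trough amplitude, and
#' whether the oscillation is sustained: relative amplitude above
#' `amp_threshold` *and* the last peak-to-trough amplitude at least
#' `decay_ratio` of the first (non-decaying). Constant or converging series
#' report frequency 0.
#'
#' @param traj A `upr_trajectory`.
#' @param species Species or observable name.
#' @param transient_fraction Fraction of the window discarded as transient
#'   (default 0.5).
#' @param amp_threshold Relative amplitude below which the series counts as
#'   non-oscillating (default 0.01 of the series mean).
#' @param decay_ratio Minimum last/first amplitude ratio for a sustained
#'   oscillation (default 0.95).
#' @param min_points Minimum number of post-transient samples required.
#' @return List `frequency` (1/atu), `amplitude` (relative), `sustained`
#'   (logical), `n_peaks`.
#' @export
oscillation_metrics <- function(traj, species, transient_fraction = 0.5,
                                amp_threshold = 0.01, decay_ratio = 0.95,
                                min_points = 50) {
  y <- trajectory_series(traj, species)
  t <- traj$times
  keep <- t >= t[1] + transient_fraction * (t[length(t)] - t[1])
  y <- y[keep]; t <- t[keep]
  if (length(y) < min_points) {
    stop("oscillation_metrics: post-transient window too short (",
         length(y), " points); increase t_end or n_out")
  }
  scale <- mean(abs(y))
  if (scale == 0) scale <- 1
  rel_amp <- (max(y) - min(y)) / scale
  flat <- list(frequency = 0, amplitude = rel_amp, sustained = FALSE,
               n_peaks = 0L)
  if (rel_amp <= amp_threshold) return(flat)
  d <- diff(y)
  # interior maxima/minima by slope sign change (plateaus collapse to one)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(flat)
  runs <- s[nz]
  flips <- which(diff(runs) != 0)
  if (!length(flips)) return(flat)
  idx <- nz[flips] + 1L
  kind <- ifelse(runs[flips] > 0, "max", "min")
  peaks <- idx[kind == "max"]
  troughs <- idx[kind == "min"]
  if (length(peaks) < 2) return(flat)
  freq <- (length(peaks) - 1) / (t[peaks[length(peaks)]] - t[peaks[1]])
  # peak-to-following-trough amplitudes for the decay check
  amp_of <- function(pk) {
    nxt <- troughs[troughs > pk]
    if (!length(nxt)) return(NA_real_)
    y[pk] - y[nxt[1]]
  }
  a_first <- amp_of(peaks[1])
  a_last <- amp_of(peaks[max(1, length(peaks) - 1)])
  decaying <- !is.na(a_first) && !is.na(a_last) && a_first > 0 &&
    (a_last / a_first) < decay_ratio
  sustained <- rel_amp > amp_threshold && !decaying && length(peaks) >= 3
  list(frequency = freq, amplitude = rel_amp, sustained = sustained,
       n_peaks = length(peaks))
}

#' Renormalise trajectory series to 0-100% of their range
#'
#' Each selected series is rescaled so its minimum over the window maps to 0
#' and its maximum to 100, allowing partial and total activation levels of
#' different components to be compared on one axis. A constant series maps
#' to 0 everywhere (declared convention).
#'
#' @param traj A `upr_trajectory`.
#' @param species Character vector of species/observable names (non-empty).
#' @param window Optional time window `c(t0, t1)` over which min/max are
#'   taken (default: full trajectory).
#' @return List with `times` and `scaled` (time x series matrix in
#'   `[0, 100]`).
#' @export
renormalize_trajectory <- function(traj, species, window = NULL) {
  if (!length(species)) stop("renormalize_trajectory: empty species selection")
  t <- traj$times
  keep <- if (is.null(window)) rep(TRUE, length(t)) else
    (t >= window[1] & t <= window[2])
  out <- sapply(species, function(nm) {
    y <- trajectory_series(traj, nm)[keep]
    r <- range(y)
    if (diff(r) == 0) rep(0, length(y)) else (y - r[1]) / diff(r) * 100
  })
  list(times = t[keep], scaled = as.matrix(out))
}

#' First-crossing activation times of renormalised series
#'
#' Renormalises each series to 0-100% and returns the first time each
#' crosses the threshold (linear interpolation between samples). Series that
#' never cross are reported as `NA` (absent), not an error. The *ordering*
#' of the returned times is the object of interest, e.g. translation
#' attenuation preceding the rise of folding capacity.
#'
#' @param traj A `upr_trajectory`.
#' @param species Character vector of species/observable names.
#' @param threshold Crossing threshold in percent of each series' range
#'   (default 50).
#' @param window Optional time window passed to [renormalize_trajectory()].
#' @return Named numeric vector of first-crossing times (atu), `NA` where
#'   the series never reaches the threshold.
#' @export
activation_timing <- function(traj, species, threshold = 50, window = NULL) {
  rn <- renormalize_trajectory(traj, species, window = window)
  t <- rn$times
  vapply(species, function(nm) {
    y <- rn$scaled[, nm]
    above <- which(y >= threshold)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1L) return(t[1])
    # linear interpolation of the crossing
    t[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }, numeric(1))
}
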