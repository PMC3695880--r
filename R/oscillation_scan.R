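#' @title ABC-SMC mapping of the oscillatory parameter region
#' @description Sequential approximate Bayesian computation over the PERK
#'   branch parameters with the oscillation frequency as the summary and a
#'   Heaviside step acceptance: a particle is accepted when its simulated
#'   oscillation frequency `f` reaches the generation's threshold epsilon.
#'   Raising epsilon every generation concentrates the final population on
#'   the parameter region supporting high-frequency oscillations.
#' @name oscillation_scan
NULL

#' Heaviside acceptance on oscillation frequency
#'
#' The distance measure of the oscillation scan: `1` (accept) when
#' `f >= eps`, else `0`. The boundary `f = eps` accepts.
#'
#' @param f Measured oscillation frequency (1/atu, `>= 0`).
#' @param eps Acceptance threshold (1/atu, `>= 0`).
#' @return `1` or `0` (vectorised over `f`).
#' @export
heaviside_distance <- function(f, eps) {
  if (any(f < 0) || any(eps < 0)) {
    stop("heaviside_distance: f and eps must be >= 0")
  }
  as.numeric(f >= eps)
}

#' Prior specification for the oscillation scan
#'
#' Independent log-uniform priors spanning `span`-fold below to above each
#' reference value — the default prior family for positive kinetic
#' parameters.
#'
#' @param names Character vector of scanned parameter names (must exist in
#'   the scanned model's parameter vector).
#' @param reference Named numeric vector of reference values (defaults to
#'   the PERK-branch reference configuration).
#' @param span Fold-range of each log-uniform prior (default 10: from
#'   ref/10 to ref*10).
#' @return An object of class `upr_prior`: data frame with `name`, `lower`,
#'   `upper` (natural-log bounds).
#' @export
prior_spec <- function(names, reference = NULL, span = 10) {
  if (is.null(reference)) {
    ref <- build_perk_branch()$parameters
    reference <- ref[names]
  }
  if (any(is.na(reference)) || any(reference <= 0)) {
    stop("prior_spec: reference values must be positive and available for ",
         "all scanned parameters")
  }
  structure(data.frame(name = names,
                       lower = log(reference / span),
                       upper = log(reference * span),
                       row.names = NULL),
            class = c("upr_prior", "data.frame"))
}

sample_prior <- function(prior, n) {
  m <- matrix(stats::runif(n * nrow(prior), rep(prior$lower, each = n),
                           rep(prior$upper, each = n)),
              nrow = n, dimnames = list(NULL, prior$name))
  exp(m)
}

prior_log_density <- function(prior, theta_log) {
  # uniform in log space: constant inside the box, -Inf outside
  inside <- all(theta_log >= prior$lower & theta_log <= prior$upper)
  if (inside) -sum(log(prior$upper - prior$lower)) else -Inf
}

#' Oscillation frequency of a parameterised model
#'
#' Simulates the model and measures the oscillation frequency of a series
#' with [oscillation_metrics()]; non-sustained oscillations score 0.
#'
#' @param model A `upr_model`.
#' @param species Series used for the frequency measurement.
#' @param t_end Simulation length (atu).
#' @param transient_fraction Transient discard fraction.
#' @param rtol,atol Integrator tolerances (scan default is looser than the
#'   scenario default; the frequency summary is insensitive at this level).
#' @return Frequency (1/atu), 0 for non-oscillating parameterisations.
#' @export
oscillation_frequency <- function(model, species = "CHOPlevel",
                                  t_end = 1500, transient_fraction = 0.5,
                                  rtol = 1e-5, atol = 1e-8) {
  tr <- tryCatch(
    integrate_model(model, t_end = t_end, n_out = 800, rtol = rtol,
                    atol = atol),
    error = function(e) NULL)
  if (is.null(tr)) return(0)
  om <- tryCatch(
    oscillation_metrics(tr, species, transient_fraction = transient_fraction),
    error = function(e) NULL)
  if (is.null(om) || !om$sustained) return(0)
  om$frequency
}

#' ABC-SMC scan of the oscillatory parameter region
#'
#' Sequential Monte Carlo with the Heaviside frequency acceptance. Each
#' generation resamples the previous population proportionally to its
#' weights, perturbs the particles in log-parameter space with a Gaussian
#' kernel (covariance = 2x the weighted covariance of the previous
#' generation), simulates the model, and accepts particles whose frequency
#' meets the generation's threshold. Importance weights follow the standard
#' SMC correction (prior density over the kernel-weighted mixture). The
#' epsilon schedule may be fixed, or adapted as the `adapt_quantile` of the
#' previous generation's accepted frequencies (strictly increasing
#' enforced).
#'
#' @param model_builder Function taking a named parameter vector and
#'   returning a `upr_model` (e.g. a wrapper around [build_perk_branch()]).
#' @param prior A [prior_spec()].
#' @param n_particles Particles per generation (`>= 50`).
#' @param n_generations Number of generations when `epsilon` is adaptive.
#' @param epsilon Optional fixed, strictly increasing threshold schedule
#'   (1/atu); overrides `n_generations`.
#' @param epsilon0 First-generation acceptance threshold (1/atu) used when
#'   the schedule is adaptive; a small positive value restricts the scan to
#'   oscillatory parameterisations from the start.
#' @param adapt_quantile Quantile of the previous generation's frequencies
#'   used as the next threshold (default 0.6).
#' @param seed Integer seed; the scan is fully reproducible given the seed.
#' @param frequency_fun Function mapping a model to a frequency (default
#'   [oscillation_frequency()]); replaceable for cheap test systems.
#' @param min_acceptance Acceptance-rate floor; generations below it abort
#'   the scan, returning completed generations with a warning.
#' @param max_attempts_factor Cap on proposal attempts per generation, as a
#'   multiple of `n_particles / min_acceptance`.
#' @return Object of class `upr_abc`: list of generations, each with
#'   `particles` (matrix), `weights`, `frequency`, `epsilon`,
#'   `acceptance_rate`.
#' @export
abc_smc <- function(model_builder, prior, n_particles = 500,
                    n_generations = 5, epsilon = NULL, epsilon0 = 0.005,
                    adapt_quantile = 0.6, seed = 1,
                    frequency_fun = oscillation_frequency,
                    min_acceptance = 1e-4, max_attempts_factor = 2) {
  if (n_particles < 50) stop("abc_smc: n_particles must be >= 50")
  if (!is.null(epsilon)) {
    if (any(diff(epsilon) <= 0)) {
      stop("abc_smc: epsilon schedule must be strictly increasing")
    }
    n_generations <- length(epsilon)
  }
  set.seed(seed)
  d <- nrow(prior)
  gens <- list()
  prev <- NULL
  eps_prev <- -Inf
  for (g in seq_len(n_generations)) {
    eps_g <- if (!is.null(epsilon)) epsilon[g] else if (is.null(prev)) epsilon0 else {
      e <- stats::quantile(prev$frequency, adapt_quantile, names = FALSE)
      max(e, eps_prev + 1e-9)   # strictly increasing
    }
    if (!is.null(prev)) {
      wcov <- stats::cov.wt(log(prev$particles), wt = prev$weights,
                            method = "ML")$cov
      # regularisation scaled to the prior box so that degenerate
      # (point-mass-like) priors keep proposals inside their support
      kcov <- 2 * wcov + diag((1e-9 * (prior$upper - prior$lower))^2 +
                                1e-300, d)
      kchol <- chol(kcov)
    }
    acc <- matrix(NA_real_, n_particles, d,
                  dimnames = list(NULL, prior$name))
    fs <- numeric(n_particles)
    wts <- numeric(n_particles)
    n_acc <- 0L
    attempts <- 0L
    max_attempts <- ceiling(max_attempts_factor * n_particles /
                              min_acceptance)
    while (n_acc < n_particles && attempts < max_attempts) {
      attempts <- attempts + 1L
      if (is.null(prev)) {
        theta_log <- log(sample_prior(prior, 1)[1, ])
      } else {
        i <- sample.int(n_particles, 1, prob = prev$weights)
        theta_log <- log(prev$particles[i, ]) +
          as.numeric(stats::rnorm(d) %*% kchol)
        if (!is.finite(prior_log_density(prior, theta_log))) next
      }
      theta <- exp(theta_log)
      f <- frequency_fun(model_builder(theta))
      if (heaviside_distance(f, eps_g) != 1) next
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- theta
      fs[n_acc] <- f
      wts[n_acc] <- if (is.null(prev)) 1 else {
        # standard SMC importance correction (uniform log-prior numerator)
        lognum <- prior_log_density(prior, theta_log)
        mix <- sum(vapply(seq_len(n_particles), function(j) {
          z <- backsolve(kchol, theta_log - log(prev$particles[j, ]),
                         transpose = TRUE)
          prev$weights[j] * exp(-0.5 * sum(z^2))
        }, numeric(1)))
        exp(lognum) / max(mix, 1e-300)
      }
      # check the acceptance floor early, after a probing burst
      if (attempts >= 200 && n_acc / attempts < min_acceptance) break
    }
    rate <- n_acc / attempts
    if (n_acc < n_particles) {
      warning("abc_smc: acceptance rate ", signif(rate, 3),
              " below floor at generation ", g,
              "; returning completed generations")
      break
    }
    wts <- wts / sum(wts)
    prev <- list(particles = acc, weights = wts, frequency = fs,
                 epsilon = eps_g, acceptance_rate = rate)
    gens[[g]] <- prev
    eps_prev <- eps_g
  }
  structure(gens, class = "upr_abc", seed = seed)
}

#' @export
print.upr_abc <- function(x, ...) {
  cat("<upr_abc> ", length(x), " generation(s)\n", sep = "")
  for (g in seq_along(x)) {
    cat(sprintf("  gen %d: eps = %.5f, acceptance = %.3f, median f = %.5f\n",
                g, x[[g]]$epsilon, x[[g]]$acceptance_rate,
                stats::median(x[[g]]$frequency)))
  }
  invisible(x)
}

#' Weighted quantile
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param probs Quantile probabilities.
#' @return Weighted quantiles (type-4-like interpolation on the weighted
#'   CDF).
#' @export
weighted_quantile <- function(x, w, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

#' Marginal summaries of an ABC population
#'
#' Per-parameter weighted quantiles and pairwise weighted rank correlations
#' of the log-parameters; the correlation signs carry the co-occurrence
#' structure of the oscillatory region (e.g. high Hill cooperativity of ATF4
#' activation pairing with a low activation threshold).
#'
#' @param population One generation of an [abc_smc()] result.
#' @param probs Quantile probabilities.
#' @return List with `quantiles` (parameters x probs matrix) and
#'   `rank_correlation` (parameters x parameters matrix; `NA` with a warning
#'   attribute where a parameter is degenerate).
#' @export
marginal_summaries <- function(population,
                               probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  th <- population$particles
  w <- population$weights
  qs <- t(apply(th, 2, weighted_quantile, w = w, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  d <- ncol(th)
  rc <- matrix(NA_real_, d, d, dimnames = list(colnames(th), colnames(th)))
  degenerate <- apply(th, 2, function(v) stats::sd(v) == 0)
  # weighted rank correlation via weighted resampling-free approximation:
  # rank-transform, then weighted Pearson on the ranks
  rk <- apply(th, 2, rank)
  wm <- function(v) sum(w * v)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (degenerate[i] || degenerate[j]) next
      xi <- rk[, i] - wm(rk[, i]); xj <- rk[, j] - wm(rk[, j])
      rc[i, j] <- wm(xi * xj) / sqrt(wm(xi^2) * wm(xj^2))
    }
  }
  list(quantiles = qs, rank_correlation = rc,
       degenerate = names(which(degenerate)))
}

#' Population-based sensitivity scores of the oscillation frequency
#'
#' Weighted rank-regression sensitivity: the per-particle frequencies and
#' log-parameters are rank-transformed and the frequency ranks are regressed
#' on the standardised parameter ranks with the particle weights. The
#' absolute standardised coefficients are comparable across parameters; a
#' parameter with degenerate variance scores 0 and is flagged.
#'
#' @param population One generation of an [abc_smc()] result (with stored
#'   per-particle frequencies).
#' @param output Per-particle output values; defaults to the stored
#'   oscillation frequencies.
#' @return List with `scores` (named, normalised to max 1), `coefficients`
#'   (raw standardised rank-regression coefficients) and `degenerate`
#'   (flagged parameter names).
#' @export
sensitivity_matrix <- function(population, output = NULL) {
  th <- population$particles
  w <- population$weights
  f <- output %||% population$frequency
  keep <- apply(th, 2, function(v) stats::sd(v) > 0)
  X <- apply(log(th[, keep, drop = FALSE]), 2, rank)
  X <- scale(X)
  y <- rank(f)
  y <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, X), y, w)
  coefs <- fit$coefficients[-1]
  scores <- stats::setNames(numeric(ncol(th)), colnames(th))
  scores[names(coefs)] <- abs(coefs)
  if (max(scores) > 0) scores <- scores / max(scores)
  list(scores = scores, coefficients = coefs,
       degenerate = colnames(th)[!keep])
}

#' Build a PERK-branch model from scanned parameter values
#'
#' Convenience builder for [abc_smc()]: applies a named vector of parameter
#' overrides (the scanned subset, typically
#' `nh, kATF4, eIF2aT, CReP, extCHOP, kphos, kdephos, kmChop, kmAtff,
#' PERKA`) to the reference PERK-branch model.
#'
#' @param theta Named numeric vector of parameter values.
#' @return A `upr_model`.
#' @export
perk_scan_builder <- function(theta) {
  m <- build_perk_branch()
  m <- set_parameters(m, theta)
  # eIF2a initial tracks the (scanned) total
  i <- match("eIF2a", species_ids(m))
  m$species[[i]]$initial <- unname(m$parameters[["eIF2aT"]])
  m
}
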