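#' Extended (total-QSSA) Michaelis-Menten product-formation rate
#'
#' Classical Michaelis-Menten kinetics assumes the free-enzyme pool is
#' constant and substrate is in excess. During receptor activation and XBP1
#' mRNA splicing both the enzyme (active receptor complexes) and the
#' substrate (mRNA) pools are small and variable, so the rate law is derived
#' instead under the total quasi-steady-state approximation, which tracks the
#' *total* substrate and enzyme amounts:
#'
#' \deqn{v = \tfrac{1}{2} k_c \left[ S_t + E_t + K_m -
#'       \sqrt{(S_t + E_t + K_m)^2 - 4 S_t E_t} \right]}
#'
#' The law is symmetric in \eqn{S_t} and \eqn{E_t}, bounded by
#' \eqn{k_c \min(S_t, E_t)}, and reduces to the classical form
#' \eqn{k_c E_t S_t / (K_m + S_t)} when \eqn{E_t \ll S_t + K_m}.
#'
#' @param kc Maximal catalytic rate (acu/atu per unit of saturated enzyme),
#'   `kc >= 0`.
#' @param Km Half-saturation substrate amount (acu), `Km >= 0`.
#' @param St Total substrate amount (acu), `St >= 0`.
#' @param Et Total enzyme amount (acu), `Et >= 0`.
#' @return Product formation rate (acu/atu), a single non-negative number.
#' @examples
#' tqssa_rate(kc = 1, Km = 1, St = 100, Et = 1)   # ~ classical MM regime
#' tqssa_rate(kc = 1, Km = 0, St = 1,   Et = 1)   # full saturation: 1
#' @export
tqssa_rate <- function(kc, Km, St, Et) {
  stopifnot(length(kc) == 1L, length(Km) == 1L, length(St) == 1L,
            length(Et) == 1L)
  if (kc < 0 || Km < 0) stop("tqssa_rate: kc and Km must be non-negative")
  if (St < 0 || Et < 0) stop("tqssa_rate: St and Et must be non-negative")
  s <- St + Et + Km
  disc <- s * s - 4 * St * Et
  # (St+Et+Km)^2 >= 4*St*Et always holds for Km >= 0; round-off can push the
  # discriminant marginally below zero at Km = 0, St = Et.
  if (disc < 0) {
    if (disc < -1e-12 * max(1, s * s)) {
      stop("tqssa_rate: negative discriminant for valid inputs")
    }
    disc <- 0
  }
  0.5 * kc * (s - sqrt(disc))
}

#' Competitive multi-regulator transcription rate
#'
#' Rate of mRNA synthesis from a single (or low-copy) gene whose promoter is
#' shared competitively by several transcription regulators. Each regulator
#' `i` occupies the promoter with weight \eqn{[TF]_i / K_{m,i}}; occupied
#' activator states produce at \eqn{k_{c,i}}, repressor-occupied and free
#' states are silent:
#'
#' \deqn{v = \frac{\sum_i k_{c,i} [TF]_i / K_{m,i}}
#'            {1 + \sum_j [TF]_j / K_{m,j}}}
#'
#' where the numerator sum runs over activators (`kc > 0`) and the
#' denominator over *all* regulators. A pure repressor is a term with
#' `kc = 0`. Constitutive (basal) expression is modelled explicitly as an
#' activator of fixed unit occupancy weight (see [regulator_term()]).
#'
#' @param regulators A list of regulator terms created by
#'   [regulator_term()]. May be empty, in which case the rate is 0.
#' @return mRNA synthesis rate (acu/atu), bounded above by `max(kc_i)`.
#' @seealso [regulator_term()]
#' @examples
#' act <- regulator_term(concentration = 2, kc = 2, Km = 2)  # half-saturated
#' rep <- regulator_term(concentration = 2, kc = 0, Km = 2)  # pure repressor
#' regulation_rate(list(act))        # 1
#' regulation_rate(list(act, rep))   # 2/3
#' @export
regulation_rate <- function(regulators) {
  if (length(regulators) == 0L) return(0)
  num <- 0
  den <- 1
  for (r in regulators) {
    if (!inherits(r, "upr_regulator_term")) {
      r <- do.call(regulator_term, as.list(r))
    }
    w <- r$concentration / r$Km
    num <- num + r$kc * w
    den <- den + w
  }
  num / den
}

#' Construct a transcription-regulator term
#'
#' @param concentration Regulator concentration `[TF]` (acu, `>= 0`).
#' @param kc Maximal transcription activation rate contributed by this
#'   regulator (acu/atu); 0 for a pure repressor.
#' @param Km Relative affinity (acu, `> 0`); smaller values mean stronger
#'   promoter occupancy per unit regulator.
#' @return An object of class `upr_regulator_term`.
#' @export
regulator_term <- function(concentration, kc, Km) {
  if (concentration < 0) stop("regulator_term: concentration must be >= 0")
  if (kc < 0) stop("regulator_term: kc must be >= 0")
  if (Km <= 0) stop("regulator_term: Km must be > 0")
  structure(list(concentration = concentration, kc = kc, Km = Km),
            class = "upr_regulator_term")
}

#' Hill parameter set
#'
#' @param K Midpoint (acu, `> 0`): input at which the response is 1/2.
#' @param h Hill coefficient (dimensionless, `> 0`).
#' @param direction `"activating"` or `"repressing"`.
#' @return An object of class `upr_hill_params`.
#' @export
hill_params <- function(K, h, direction = c("activating", "repressing")) {
  direction <- match.arg(direction)
  if (K <= 0) stop("hill_params: K must be > 0")
  if (h <= 0) stop("hill_params: h must be > 0")
  structure(list(K = K, h = h, direction = direction),
            class = "upr_hill_params")
}

#' Normalised Hill response
#'
#' Dimensionless sigmoidal response in `[0, 1]`; activating:
#' \eqn{x^h/(K^h + x^h)}, repressing: \eqn{K^h/(K^h + x^h)}. The value at
#' `x = K` is exactly 1/2 for either direction. Scaling by rate constants is
#' left to the call site so that units stay in one place.
#'
#' @param x Input amount (acu, `>= 0`).
#' @param params A [hill_params()] object.
#' @return A number in `[0, 1]`.
#' @export
hill_response <- function(x, params) {
  stopifnot(inherits(params, "upr_hill_params"))
  if (any(x < 0)) stop("hill_response: x must be >= 0")
  # compute on the ratio to avoid overflow for large x^h
  r <- (x / params$K)^params$h
  act <- ifelse(is.infinite(r), 1, r / (1 + r))
  if (params$direction == "activating") act else 1 - act
}

#' Receptor kinetic parameter set
#'
#' Parameters of the generic stress-receptor activation module shared by
#' IRE1alpha, PERK and ATF6. Activation is the cooperative assembly of `n`
#' receptor monomers into an active (autophosphorylated) complex; the
#' complex dissociates back to monomers without an external phosphatase.
#' Two alternative hypotheses for direct unfolded-protein (UFP) involvement
#' are available as variants: `direct_ufp` makes the activation flux
#' proportional to UFP, `ufp_stabilised` divides the deactivation flux by
#' `1 + extIRE * UFP`.
#'
#' @param kf Association/activation rate constant (`>= 0`).
#' @param kr Dissociation/deactivation rate constant (`>= 0`).
#' @param n Stoichiometry of the activated complex (positive integer).
#' @param extIRE Strength of UFP stabilisation of the active complex
#'   (per acu, `>= 0`); used only by the `ufp_stabilised` variant.
#' @param variant One of `"standard"`, `"direct_ufp"`, `"ufp_stabilised"`.
#' @return An object of class `upr_receptor_params`.
#' @export
receptor_params <- function(kf, kr, n, extIRE = 0,
                            variant = c("standard", "direct_ufp",
                                        "ufp_stabilised")) {
  variant <- match.arg(variant)
  if (kf < 0 || kr < 0 || extIRE < 0) {
    stop("receptor_params: kf, kr, extIRE must be >= 0")
  }
  if (n < 1 || n != round(n)) {
    stop("receptor_params: n must be a positive integer")
  }
  structure(list(kf = kf, kr = kr, n = as.integer(n), extIRE = extIRE,
                 variant = variant),
            class = "upr_receptor_params")
}

#' Receptor activation and deactivation fluxes
#'
#' Evaluates the activation flux `vact` and deactivation flux `vdeact` of the
#' generic receptor module for the chosen variant:
#' standard: \eqn{v_{act} = k_f R^n}, \eqn{v_{deact} = k_r R_{act}};
#' direct UFP activation: \eqn{v_{act} = k_f \, UFP \, R^n};
#' UFP stabilisation: \eqn{v_{deact} = k_r R_{act} / (1 + extIRE \, UFP)}.
#'
#' @param params A [receptor_params()] object.
#' @param R Inactive receptor monomer amount (acu, `>= 0`).
#' @param Ract Active complex amount (acu, `>= 0`).
#' @param UFP Free unfolded protein amount (acu, `>= 0`); ignored by the
#'   standard variant.
#' @return Named numeric vector `c(vact =, vdeact =)`, both `>= 0`.
#' @export
receptor_fluxes <- function(params, R, Ract, UFP = 0) {
  stopifnot(inherits(params, "upr_receptor_params"))
  if (R < 0 || Ract < 0 || UFP < 0) {
    stop("receptor_fluxes: R, Ract, UFP must be >= 0")
  }
  vact <- switch(params$variant,
    standard       = params$kf * R^params$n,
    direct_ufp     = params$kf * UFP * R^params$n,
    ufp_stabilised = params$kf * R^params$n,
    stop("receptor_fluxes: unknown variant '", params$variant, "'")
  )
  vdeact <- switch(params$variant,
    ufp_stabilised = params$kr * Ract / (1 + params$extIRE * UFP),
    params$kr * Ract
  )
  c(vact = vact, vdeact = vdeact)
}
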