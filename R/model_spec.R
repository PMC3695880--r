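#' @title Model specification containers
#' @description Lightweight S3 containers for a reaction-network model:
#'   species (with compartments and initial amounts), reaction channels with
#'   symbolic rate laws, a named parameter vector, and named observable
#'   expressions. Rate laws reference species and parameters by *name*; a
#'   name is resolved against the species list first and the parameter list
#'   second, so the same law works whether e.g. CHOP is a dynamic species
#'   (full model) or a clamped input (module-only build).
#' @name model_spec
NULL

upr_compartments <- c("ER", "nucleus", "Golgi", "cytoplasm")

#' Define a species
#'
#' @param id Unique symbolic name.
#' @param compartment One of `"ER"`, `"nucleus"`, `"Golgi"`, `"cytoplasm"`.
#' @param initial Initial amount (acu, `>= 0`).
#' @param role Free-form annotation (e.g. `"receptor"`, `"chaperone"`,
#'   `"mRNA"`, `"TF"`, `"apoptotic"`).
#' @return A `upr_species` list.
#' @export
species_def <- function(id, compartment, initial = 0, role = "") {
  if (!compartment %in% upr_compartments) {
    stop("species_def: unknown compartment '", compartment, "'")
  }
  if (initial < 0) stop("species_def: initial must be >= 0")
  structure(list(id = id, compartment = compartment,
                 initial = initial, role = role),
            class = "upr_species")
}

#' Define a reaction channel
#'
#' @param id Unique reaction identifier.
#' @param reactants Named integer vector of reactant stoichiometries (may be
#'   empty for synthesis reactions).
#' @param products Named integer vector of product stoichiometries (may be
#'   empty for degradation reactions).
#' @param law A rate law created by one of the `law_*()` constructors.
#' @return A `upr_reaction` list.
#' @export
reaction_def <- function(id, reactants = numeric(0), products = numeric(0),
                         law) {
  if (length(reactants) && (is.null(names(reactants)) ||
      any(reactants <= 0) || any(reactants != round(reactants)))) {
    stop("reaction_def: reactant stoichiometries must be named positive integers")
  }
  if (length(products) && (is.null(names(products)) ||
      any(products <= 0) || any(products != round(products)))) {
    stop("reaction_def: product stoichiometries must be named positive integers")
  }
  stopifnot(inherits(law, "upr_law"))
  structure(list(id = id, reactants = reactants, products = products,
                 law = law),
            class = "upr_reaction")
}

new_law <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "upr_law")
}

#' Rate-law constructors
#'
#' Symbolic rate laws for [reaction_def()]. All arguments are *names* of
#' parameters (resolved in the model's parameter vector) or of species
#' (resolved in the state); numeric literals are also accepted where a name
#' is expected and are used verbatim.
#'
#' * `law_const(k)`: zero-order rate `k` (synthesis / constant influx).
#' * `law_mass_action(k, modifiers)`: `k * prod(reactant^stoich)`, optionally
#'   multiplied linearly by each modifier symbol (e.g. direct UFP involvement
#'   in receptor activation).
#' * `law_stabilised_decay(k, ext, ufp)`: `k * reactant / (1 + ext * ufp)`,
#'   the UFP-stabilisation variant of receptor deactivation.
#' * `law_tqssa(kc, Km, enzyme, enz_mult)`: total-QSSA Michaelis-Menten rate
#'   ([tqssa_rate()]) with the single reactant as total substrate and
#'   `enz_mult * enzyme` as total enzyme (e.g. 2 catalytic domains per
#'   IRE1alpha quadromer).
#' * `law_regulation(terms)`: competitive multi-regulator transcription rate
#'   ([regulation_rate()]); `terms` is a list of `reg_term()` entries.
#' * `law_mm(kc, Km, enzyme, enz_mult, inhibitor, inh_K)`: classical
#'   Michaelis-Menten `kc * E * S/(Km + S)` on the single reactant, with an
#'   optional non-competitive inhibitory factor `1/(1 + I/inh_K)`.
#' * `law_atf4_translation(ks, K, h, eif2a)`: ATF4 synthesis as a repressing
#'   Hill response of the active eIF2alpha level,
#'   `ks * K^h/(K^h + eIF2a^h)`: translation switches on when active
#'   eIF2alpha falls below the midpoint `K`.
#' * `law_bax_activation(k, total, activator)`: `k * act * (total - X)` where
#'   `X` is the product species (activated BAX) and `total` its conserved
#'   total.
#' * `law_bax_auto(k, total, J)`: autocatalytic BAX recruitment
#'   `k * (total - X) * X^2/(J^2 + X^2)`.
#' * `law_bax_inactivation(krev, kbcl, bcl2T, K, h, chop)`: re-translocation
#'   `(krev + kbcl * Bcl2(chop)) * X` with CHOP-repressed Bcl-2 level
#'   `Bcl2 = bcl2T * K^h/(K^h + chop^h)`.
#'
#' @param k,kc,Km,ks,K,h,ext,ufp,enzyme,enz_mult,inhibitor,inh_K,total,
#'   activator,J,krev,kbcl,bcl2T,chop,eif2a Symbol names (character) or
#'   numeric literals; see individual law descriptions.
#' @param modifiers Character vector of symbols multiplying the rate
#'   linearly (may be empty).
#' @param terms List of `reg_term()` entries.
#' @return An object of class `upr_law`.
#' @name rate_law_constructors
NULL

#' @rdname rate_law_constructors
#' @export
law_const <- function(k) new_law("const", k = k)

#' @rdname rate_law_constructors
#' @export
law_mass_action <- function(k, modifiers = character(0)) {
  new_law("mass_action", k = k, modifiers = modifiers)
}

#' @rdname rate_law_constructors
#' @export
law_stabilised_decay <- function(k, ext, ufp) {
  new_law("stab_decay", k = k, ext = ext, ufp = ufp)
}

#' @rdname rate_law_constructors
#' @export
law_tqssa <- function(kc, Km, enzyme, enz_mult = 1) {
  new_law("tqssa", kc = kc, Km = Km, enzyme = enzyme, enz_mult = enz_mult)
}

#' @rdname rate_law_constructors
#' @export
law_regulation <- function(terms) new_law("regulation", terms = terms)

#' Transcription-regulator term of a [law_regulation()] rate law
#'
#' @param ref Symbol (species or parameter name) giving the regulator
#'   concentration, or a numeric literal; use `ref = 1` with `Km = 1` for a
#'   constitutive activator of unit occupancy weight.
#' @param kc Maximal activation rate (symbol or numeric; 0 for a pure
#'   repressor).
#' @param Km Relative affinity (symbol or numeric, `> 0`).
#' @return A `upr_reg_term` list.
#' @export
reg_term <- function(ref, kc, Km = 1) {
  structure(list(ref = ref, kc = kc, Km = Km), class = "upr_reg_term")
}

#' @rdname rate_law_constructors
#' @export
law_mm <- function(kc, Km, enzyme, enz_mult = 1, inhibitor = NULL,
                   inh_K = NULL) {
  new_law("mm", kc = kc, Km = Km, enzyme = enzyme, enz_mult = enz_mult,
          inhibitor = inhibitor, inh_K = inh_K)
}

#' @rdname rate_law_constructors
#' @export
law_atf4_translation <- function(ks, K, h, eif2a) {
  new_law("atf4_translation", ks = ks, K = K, h = h, eif2a = eif2a)
}

#' @rdname rate_law_constructors
#' @export
law_bax_activation <- function(k, total, activator) {
  new_law("bax_activation", k = k, total = total, activator = activator)
}

#' @rdname rate_law_constructors
#' @export
law_bax_auto <- function(k, total, J) {
  new_law("bax_auto", k = k, total = total, J = J)
}

#' @rdname rate_law_constructors
#' @export
law_bax_inactivation <- function(krev, kbcl, bcl2T, K, h, chop) {
  new_law("bax_inactivation", krev = krev, kbcl = kbcl, bcl2T = bcl2T,
          K = K, h = h, chop = chop)
}

#' Assemble a model specification
#'
#' @param name Model name.
#' @param species List of [species_def()] entries; ids must be unique.
#' @param reactions List of [reaction_def()] entries; every species symbol
#'   used in stoichiometries must be declared.
#' @param parameters Named numeric vector of parameter values.
#' @param observables Named list of character expressions over species and
#'   parameter names (e.g. `list(BiPT = "BiP + BUFP + BIRE1")`).
#' @return An object of class `upr_model`.
#' @export
model_spec <- function(name, species, reactions, parameters,
                       observables = list()) {
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("model_spec: duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) {
    stop("model_spec: duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("model_spec: parameters must be a fully named numeric vector")
  }
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)), ids)
    if (length(unknown)) {
      stop("model_spec: reaction '", r$id, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
  }
  m <- structure(list(name = name, species = species, reactions = reactions,
                      parameters = parameters, observables = observables),
                 class = "upr_model")
  # resolve all law symbols now so configuration errors surface early
  compile_model(m)
  m
}

#' Model introspection counts
#'
#' @param model A `upr_model`.
#' @return Named integer vector `c(species =, reactions =, parameters =)`.
#' @export
model_counts <- function(model) {
  stopifnot(inherits(model, "upr_model"))
  c(species = length(model$species),
    reactions = length(model$reactions),
    parameters = length(model$parameters))
}

#' @export
print.upr_model <- function(x, ...) {
  n <- model_counts(x)
  cat("<upr_model> ", x$name, ": ", n["species"], " species, ",
      n["reactions"], " reactions, ", n["parameters"], " parameters\n",
      sep = "")
  invisible(x)
}

#' Species ids of a model
#' @param model A `upr_model`.
#' @return Character vector of species ids, in declaration order.
#' @export
species_ids <- function(model) {
  vapply(model$species, function(s) s$id, character(1))
}

#' Initial state vector of a model
#' @param model A `upr_model`.
#' @return Named numeric vector of declared initial amounts.
#' @export
initial_state <- function(model) {
  x <- vapply(model$species, function(s) s$initial, numeric(1))
  names(x) <- species_ids(model)
  x
}

# --- symbol resolution and law compilation ---------------------------------

# A resolved symbol is a function of (state, pars); compile-time we store
# (where, index): where = 0 literal, 1 species, 2 parameter.
resolve_symbol <- function(sym, sids, pnames, context) {
  if (is.null(sym)) return(NULL)
  if (is.numeric(sym)) return(list(where = 0L, value = as.numeric(sym)))
  i <- match(sym, sids)
  if (!is.na(i)) return(list(where = 1L, index = i))
  j <- match(sym, pnames)
  if (!is.na(j)) return(list(where = 2L, index = j))
  stop("unknown symbol '", sym, "' in ", context,
       " (not a species or parameter)")
}

sym_value <- function(rs, x, p) {
  if (rs$where == 0L) rs$value else if (rs$where == 1L) x[[rs$index]]
  else p[[rs$index]]
}

compile_law <- function(law, reaction, sids, pnames) {
  ctx <- paste0("reaction '", reaction$id, "'")
  rv <- function(sym) resolve_symbol(sym, sids, pnames, ctx)
  ridx <- match(names(reaction$reactants), sids)
  rsto <- unname(reaction$reactants)
  switch(law$type,
    const = {
      k <- rv(law$k)
      function(x, p) sym_value(k, x, p)
    },
    mass_action = {
      k <- rv(law$k)
      mods <- lapply(law$modifiers, rv)
      function(x, p) {
        v <- sym_value(k, x, p)
        if (length(ridx)) v <- v * prod(x[ridx]^rsto)
        for (m in mods) v <- v * sym_value(m, x, p)
        v
      }
    },
    stab_decay = {
      if (length(ridx) != 1L) stop("stab_decay law needs one reactant in ", ctx)
      k <- rv(law$k); ext <- rv(law$ext); ufp <- rv(law$ufp)
      function(x, p) {
        sym_value(k, x, p) * x[[ridx]] /
          (1 + sym_value(ext, x, p) * sym_value(ufp, x, p))
      }
    },
    tqssa = {
      if (length(ridx) != 1L) stop("tqssa law needs one reactant in ", ctx)
      kc <- rv(law$kc); Km <- rv(law$Km)
      enz <- rv(law$enzyme); mult <- rv(law$enz_mult)
      function(x, p) {
        tqssa_rate(sym_value(kc, x, p), sym_value(Km, x, p),
                   St = max(x[[ridx]], 0),
                   Et = max(sym_value(mult, x, p) * sym_value(enz, x, p), 0))
      }
    },
    regulation = {
      terms <- lapply(law$terms, function(tm) {
        stopifnot(inherits(tm, "upr_reg_term"))
        list(ref = rv(tm$ref), kc = rv(tm$kc), Km = rv(tm$Km))
      })
      function(x, p) {
        num <- 0; den <- 1
        for (tm in terms) {
          w <- max(sym_value(tm$ref, x, p), 0) / sym_value(tm$Km, x, p)
          num <- num + sym_value(tm$kc, x, p) * w
          den <- den + w
        }
        num / den
      }
    },
    mm = {
      if (length(ridx) != 1L) stop("mm law needs one reactant in ", ctx)
      kc <- rv(law$kc); Km <- rv(law$Km)
      enz <- rv(law$enzyme); mult <- rv(law$enz_mult)
      inh <- rv(law$inhibitor); inhK <- rv(law$inh_K)
      function(x, p) {
        s <- max(x[[ridx]], 0)
        v <- sym_value(kc, x, p) * sym_value(mult, x, p) *
          sym_value(enz, x, p) * s / (sym_value(Km, x, p) + s)
        if (!is.null(inh)) {
          v <- v / (1 + max(sym_value(inh, x, p), 0) / sym_value(inhK, x, p))
        }
        v
      }
    },
    atf4_translation = {
      ks <- rv(law$ks); K <- rv(law$K); h <- rv(law$h)
      e <- rv(law$eif2a)
      function(x, p) {
        # repressing Hill of the active eIF2alpha level: translation of ATF4
        # switches on as active eIF2alpha falls below the midpoint K
        r <- (max(sym_value(e, x, p), 0) / sym_value(K, x, p)) ^
          sym_value(h, x, p)
        sym_value(ks, x, p) / (1 + r)
      }
    },
    bax_activation = {
      k <- rv(law$k); tot <- rv(law$total); act <- rv(law$activator)
      xi <- match(names(reaction$products), sids)[1]
      function(x, p) {
        sym_value(k, x, p) * max(sym_value(act, x, p), 0) *
          max(sym_value(tot, x, p) - x[[xi]], 0)
      }
    },
    bax_auto = {
      k <- rv(law$k); tot <- rv(law$total); J <- rv(law$J)
      xi <- match(names(reaction$products), sids)[1]
      function(x, p) {
        b <- max(x[[xi]], 0)
        sym_value(k, x, p) * max(sym_value(tot, x, p) - b, 0) *
          b^2 / (sym_value(J, x, p)^2 + b^2)
      }
    },
    bax_inactivation = {
      if (length(ridx) != 1L) stop("bax_inactivation needs one reactant in ", ctx)
      krev <- rv(law$krev); kbcl <- rv(law$kbcl); b2 <- rv(law$bcl2T)
      K <- rv(law$K); h <- rv(law$h); chop <- rv(law$chop)
      function(x, p) {
        Kh <- sym_value(K, x, p)^sym_value(h, x, p)
        bcl2 <- sym_value(b2, x, p) * Kh /
          (Kh + max(sym_value(chop, x, p), 0)^sym_value(h, x, p))
        (sym_value(krev, x, p) + sym_value(kbcl, x, p) * bcl2) * x[[ridx]]
      }
    },
    stop("unknown rate-law type '", law$type, "' in ", ctx)
  )
}

#' Compile a model into a fast derivative evaluator
#'
#' Resolves all rate-law symbols to state/parameter indices, builds the
#' stoichiometry matrix, and returns an evaluator environment used by
#' [model_rhs()], [integrate_model()] and the analysis layers. Called
#' automatically (and cached) where needed; exposed for inspection.
#'
#' @param model A `upr_model`.
#' @return A list with elements `stoich` (species x reactions matrix),
#'   `rate_fns` (list of functions of `(state, pars)`), `rates(state, pars)`
#'   returning the 62-vector (or however many) of reaction rates, and
#'   `deriv(state, pars)` returning the state derivative.
#' @export
compile_model <- function(model) {
  stopifnot(inherits(model, "upr_model"))
  sids <- species_ids(model)
  pnames <- names(model$parameters)
  ns <- length(sids)
  nr <- length(model$reactions)
  stoich <- matrix(0, ns, nr, dimnames = list(sids,
    vapply(model$reactions, function(r) r$id, character(1))))
  rate_fns <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    if (length(r$reactants)) {
      stoich[names(r$reactants), j] <- stoich[names(r$reactants), j] -
        unname(r$reactants)
    }
    if (length(r$products)) {
      stoich[names(r$products), j] <- stoich[names(r$products), j] +
        unname(r$products)
    }
    rate_fns[[j]] <- compile_law(r$law, r, sids, pnames)
  }
  rates <- function(x, p) {
    v <- numeric(nr)
    for (j in seq_len(nr)) v[j] <- rate_fns[[j]](x, p)
    v
  }
  list(stoich = stoich, rate_fns = rate_fns, rates = rates,
       deriv = function(x, p) as.numeric(stoich %*% rates(x, p)))
}

#' Evaluate all observable expressions of a model
#'
#' @param model A `upr_model`.
#' @param state Named state vector, or a matrix with species columns
#'   (one row per time point).
#' @return Named numeric vector (or matrix) of observable values.
#' @export
eval_observables <- function(model, state) {
  obs <- model$observables
  if (length(obs) == 0L) {
    return(if (is.matrix(state)) matrix(0, nrow(state), 0) else numeric(0))
  }
  env_from <- function(x) {
    e <- as.list(c(x, model$parameters[setdiff(names(model$parameters),
                                               names(x))]))
    list2env(e)
  }
  if (is.matrix(state)) {
    out <- matrix(NA_real_, nrow(state), length(obs),
                  dimnames = list(NULL, names(obs)))
    exprs <- lapply(obs, function(s) parse(text = s)[[1]])
    pars <- as.list(model$parameters)
    for (i in seq_len(nrow(state))) {
      e <- list2env(c(as.list(state[i, ]), pars))
      for (k in seq_along(exprs)) out[i, k] <- eval(exprs[[k]], e)
    }
    out
  } else {
    e <- env_from(state)
    vapply(obs, function(s) eval(parse(text = s)[[1]], e), numeric(1))
  }
}

#' Merge two models by shared species ids
#'
#' Species present in both models must have identical compartment and
#' initial amount; shared parameters must have equal values; reaction ids
#' must not collide. Used by the branch composers to build the full network.
#'
#' @param a,b `upr_model` objects.
#' @param name Name of the merged model.
#' @return A merged `upr_model`.
#' @export
merge_models <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  ida <- species_ids(a)
  sp <- a$species
  for (s in b$species) {
    i <- match(s$id, ida)
    if (is.na(i)) {
      sp <- c(sp, list(s))
      ida <- c(ida, s$id)
    } else {
      old <- sp[[i]]
      if (!identical(old$compartment, s$compartment) ||
          !isTRUE(all.equal(old$initial, s$initial))) {
        stop("merge_models: conflicting definitions for species '", s$id, "'")
      }
    }
  }
  shared <- intersect(names(a$parameters), names(b$parameters))
  bad <- shared[abs(a$parameters[shared] - b$parameters[shared]) >
                  1e-12 * pmax(1, abs(a$parameters[shared]))]
  if (length(bad)) {
    stop("merge_models: conflicting values for parameters: ",
         paste(bad, collapse = ", "))
  }
  rida <- vapply(a$reactions, function(r) r$id, character(1))
  ridb <- vapply(b$reactions, function(r) r$id, character(1))
  if (length(intersect(rida, ridb))) {
    stop("merge_models: reaction id collision: ",
         paste(intersect(rida, ridb), collapse = ", "))
  }
  pars <- c(a$parameters, b$parameters[setdiff(names(b$parameters), shared)])
  obs <- c(a$observables, b$observables[setdiff(names(b$observables),
                                                names(a$observables))])
  model_spec(name, sp, c(a$reactions, b$reactions), pars, obs)
}

#' Difference between two models' networks
#'
#' Reports reaction ids present in only one model and shared reactions whose
#' rate laws differ; used to verify that knockout/variant flags touch only
#' the flagged reactions.
#'
#' @param a,b `upr_model` objects.
#' @return List with `only_a`, `only_b`, `changed` (character vectors of
#'   reaction ids) and `species_only_a`, `species_only_b`.
#' @export
model_diff <- function(a, b) {
  rida <- vapply(a$reactions, function(r) r$id, character(1))
  ridb <- vapply(b$reactions, function(r) r$id, character(1))
  shared <- intersect(rida, ridb)
  changed <- character(0)
  for (id in shared) {
    ra <- a$reactions[[match(id, rida)]]
    rb <- b$reactions[[match(id, ridb)]]
    if (!isTRUE(all.equal(ra[c("reactants", "products", "law")],
                          rb[c("reactants", "products", "law")]))) {
      changed <- c(changed, id)
    }
  }
  list(only_a = setdiff(rida, ridb), only_b = setdiff(ridb, rida),
       changed = changed,
       species_only_a = setdiff(species_ids(a), species_ids(b)),
       species_only_b = setdiff(species_ids(b), species_ids(a)))
}

#' Replace parameter values in a model
#'
#' @param model A `upr_model`.
#' @param ... Named parameter values, or a single named vector/list.
#' @return The model with updated parameter values.
#' @export
set_parameters <- function(model, ...) {
  upd <- list(...)
  if (length(upd) == 1L && is.null(names(upd)) ||
      (length(upd) == 1L && (is.list(upd[[1]]) ||
        (is.numeric(upd[[1]]) && length(upd[[1]]) > 1L &&
         !is.null(names(upd[[1]])))))) {
    upd <- as.list(upd[[1]])
  }
  upd <- unlist(upd)
  unknown <- setdiff(names(upd), names(model$parameters))
  if (length(unknown)) {
    stop("set_parameters: unknown parameters: ",
         paste(unknown, collapse = ", "))
  }
  model$parameters[names(upd)] <- upd
  model
}
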