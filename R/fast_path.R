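# Compiled-rhs fast path. The canonical builds (full assembly, standalone
# PERK branch, standalone apoptosis switch) have fixed network structure;
# their derivatives are mirrored in src/upr_rhs.c and used by the integrator
# whenever the model's species order and parameter set match the compiled
# layout. Structural edits (different oligomer stoichiometry, added
# reactions) silently fall back to the generic interpreter; equality of the
# two paths is asserted in the test suite.

fastpath_layouts <- function() {
  list(
    full = list(
      func = "upr_deriv_full", initfunc = "upr_init_full",
      par_names = c(names(upr_reference_params()), "extIREp", "vflag"),
      species = c("UFP", "BiP", "BUFP", "IRE1", "BIRE1", "IRE1a",
                  "PERK", "BPERK", "PERKa", "ATF6", "BATF6", "ATF6g",
                  "ATF6p50", "WFS1", "mXBP1", "mXBP1s", "XBP1s", "mBiP",
                  "eIF2a", "eIF2aP", "ATF4", "mCHOP", "CHOP", "mGADD34",
                  "GADD34", "BH3", "BAXa"),
      check = function(model) {
        isTRUE(model$parameters[["nIRE1"]] == 4) &&
          isTRUE(model$parameters[["nPERK"]] == 4)
      }),
    perk = list(
      func = "upr_deriv_perk", initfunc = "upr_init_perk",
      par_names = c("PERKA", "kphos", "Kmphos", "kmChop", "kdephos",
                    "Kmdephos", "CReP", "eIF2aT", "ksATF4", "kATF4", "nh",
                    "kdATF4", "kc0CHOP", "kcA4CHOP", "kmAtff", "kcA6CHOP",
                    "KmA6CHOP", "kcXsCHOP", "KmXsCHOP", "extCHOP",
                    "ktlCHOP", "kdCHOP", "kcChopG", "KmChopG", "ktlG",
                    "kdG", "kdmRNA", "ATF6p50", "XBP1s"),
      species = c("eIF2a", "eIF2aP", "ATF4", "mCHOP", "CHOP", "mGADD34",
                  "GADD34"),
      check = function(model) TRUE),
    apop = list(
      func = "upr_deriv_apop", initfunc = "upr_init_apop",
      par_names = c("CHOP", "ksBH3", "kcBH3", "KmBH3", "kdBH3", "BAXT",
                    "kactBAX", "kautoBAX", "JBAX", "krevBAX", "kbclBAX",
                    "Bcl2T", "KbclCHOP", "hbcl"),
      species = c("BH3", "BAXa"),
      check = function(model) TRUE)
  )
}

# returns list(func, initfunc, parms) or NULL when the model does not match
fastpath_for <- function(model) {
  key <- attr(model, "fastpath")
  if (is.null(key)) return(NULL)
  lay <- fastpath_layouts()[[key]]
  if (is.null(lay)) return(NULL)
  if (!identical(species_ids(model), lay$species)) return(NULL)
  p <- model$parameters
  known <- lay$par_names %in% c(names(p), "extIREp", "vflag")
  if (!all(known)) return(NULL)
  if (!lay$check(model)) return(NULL)
  v <- stats::setNames(numeric(length(lay$par_names)), lay$par_names)
  avail <- intersect(lay$par_names, names(p))
  v[avail] <- p[avail]
  if ("vflag" %in% lay$par_names) {
    v[["vflag"]] <- attr(model, "vflag") %||% 0
  }
  list(func = lay$func, initfunc = lay$initfunc, parms = v)
}
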