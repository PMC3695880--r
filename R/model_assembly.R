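#' @title UPR model assembly
#' @description Builders for the four UPR submodules (generic receptor
#'   activation, IRE1alpha branch, ATF6 branch, PERK/translation-attenuation
#'   branch), the condensed BAX/BAK/BH3 apoptosis switch, and the complete
#'   integrated network. Module-only builds clamp their upstream input as a
#'   parameter (e.g. `PERKA` for the PERK branch, `CHOP` for the apoptosis
#'   switch), so the same rate-law definitions serve both the standalone and
#'   the assembled forms.
#' @name model_assembly
NULL

# small helpers -------------------------------------------------------------

rx_syn <- function(id, sp, k) {
  reaction_def(id, products = stats::setNames(1, sp), law = law_const(k))
}
rx_deg <- function(id, sp, k) {
  reaction_def(id, reactants = stats::setNames(1, sp), law = law_mass_action(k))
}
rx_conv <- function(id, from, to, k) {
  reaction_def(id, reactants = stats::setNames(1, from),
               products = stats::setNames(1, to), law = law_mass_action(k))
}
rx_translate <- function(id, mrna, prot, k) {
  reaction_def(id, reactants = stats::setNames(1, mrna),
               products = stats::setNames(c(1, 1), c(mrna, prot)),
               law = law_mass_action(k))
}

#' Reference parameter set of the integrated UPR model
#'
#' The package's reference parameterisation (82 parameters) of the complete
#' network, in arbitrary concentration/time units (acu/atu). The values are
#' the package's own calibration, chosen so that the assembled model
#' reproduces the documented qualitative behaviour of the system: a steep,
#' lag-phased receptor response; a 3-4 fold adaptive BiP gain of the
#' IRE1alpha branch; a translation-attenuation midpoint at a 90% decrease of
#' active eIF2alpha; a pair of Hopf bifurcations on the PERK branch
#' enclosing an oscillatory window; a bistable, hysteretic BAX switch driven
#' by CHOP; and the low/intermediate/high activity states at stress rates
#' mUFPT = 12, 15 and 18. Protein-protein interactions are fast relative to
#' the genetic regulatory steps by construction (magnitude separation of the
#' rate constants).
#'
#' @return Named numeric vector of length 82.
#' @export
upr_reference_params <- function() {
  c(
    # --- stress input and BiP/UFP handling (ER) ---
    mUFPT    = 0,      # unfolded-protein accumulation rate (acu/atu); stress input
    kdUFP    = 0.05,   # free UFP dilution/turnover
    kdBUFP   = 0.10,   # BiP:UFP complex turnover
    kfB      = 10,     # shared BiP association rate (receptors and UFP)
    krbUFP   = 1,      # BiP:UFP dissociation
    kdBiP    = 0.05,   # free BiP degradation
    # --- IRE1alpha receptor ---
    krbIRE1  = 1,      # BiP:IRE1 dissociation
    kfIRE1   = 50,     # IRE1 oligomerisation/activation (monomer^4)
    krIRE1   = 1,      # IRE1a complex dissociation
    nIRE1    = 4,      # monomers per active IRE1alpha complex
    vsR      = 0.20,   # shared receptor synthesis rate
    kdR      = 0.10,   # shared receptor degradation rate
    # --- PERK receptor ---
    krbPERK  = 0.13,   # BiP binds PERK tightly (less sensitive than IRE1)
    kfPERK   = 6,      # PERK oligomerisation/activation (monomer^4)
    krPERK   = 1,
    nPERK    = 4,      # monomers per active PERK complex
    # --- ATF6 branch ---
    krbATF6  = 1,
    kdwATF6  = 1,      # WFS1-enhanced ATF6 degradation (per acu WFS1)
    ktrATF6  = 0.10,   # ER -> Golgi transfer of unbound ATF6
    kcleave  = 5,      # Golgi cleavage to ATF6p50 (>> ktrATF6)
    kdATF6g  = 0.10,   # Golgi ATF6 turnover
    kdATF6p50 = 0.10,  # cleaved ATF6p50 turnover
    kc0WFS1  = 0.01,   # constitutive WFS1 expression
    kcA6WFS1 = 0.20,   # ATF6p50 -> WFS1 activation
    KmA6WFS1 = 0.30,
    kdWFS1   = 0.10,
    # --- XBP1 / BiP genetics ---
    kc0XBP1  = 0.14,   # constitutive mXBP1 transcription
    kcA6XBP1 = 0.15,   # ATF6p50 -> mXBP1
    KmA6XBP1 = 0.30,
    extXBP   = 0,      # external drive on mXBP1 (acu)
    kdmRNA   = 0.20,   # shared mRNA turnover (mXBP1, mBiP, mCHOP, mGADD34)
    kcspl    = 2,      # XBP1 splicing catalytic rate per active domain
    Kmspl    = 0.50,   # splicing affinity
    ncat     = 2,      # catalytic domains per IRE1alpha quadromer
    kdmXBP1s = 0.10,   # spliced mRNA turnover
    ktlXBP1  = 0.50,   # XBP1s translation
    kdXBP1s  = 0.10,
    kc0BiP   = 0.33,   # constitutive mBiP transcription
    kcXsBiP  = 1.6,    # XBP1s -> mBiP
    KmXsBiP  = 0.50,
    kcA6BiP  = 2.2,    # ATF6p50 -> mBiP
    KmA6BiP  = 0.50,
    extBiP   = 0,      # external drive on mBiP (acu)
    ktlBiP   = 1.5,    # BiP translation
    # --- eIF2alpha cycle / PERK genetics ---
    kphos    = 22,     # eIF2a phosphorylation by active PERK
    Kmphos   = 0.05,   # (zero-order regime: Km << eIF2aT)
    kmChop   = 2,      # CHOP-mediated attenuation of phosphorylation
    kdephos  = 2,      # dephosphorylation by GADD34/CReP
    Kmdephos = 0.05,
    CReP     = 0.05,   # constitutive phosphatase level (acu)
    eIF2aT   = 1,      # total eIF2alpha (conserved)
    ksATF4   = 0.20,   # maximal ATF4 synthesis
    kATF4    = 0.10,   # ATF4-activation midpoint: active eIF2a level (= 10% of the pool)
    nh       = 10,     # ATF4-activation Hill coefficient
    kdATF4   = 0.20,
    kc0CHOP  = 0.004,  # basal mCHOP transcription
    kcA4CHOP = 0.50,   # ATF4 -> mCHOP
    kmAtff   = 0.30,   # potency of CHOP activation by ATF4 (affinity)
    kcA6CHOP = 0.05,   # ATF6p50 -> mCHOP (also scales the extCHOP drive)
    KmA6CHOP = 2,
    kcXsCHOP = 0.05,   # XBP1s -> mCHOP
    KmXsCHOP = 5,
    extCHOP  = 0,      # external drive on mCHOP (acu)
    ktlCHOP  = 0.20,
    kdCHOP   = 0.10,
    kcChopG  = 0.40,   # CHOP -> mGADD34
    KmChopG  = 1,
    ktlG     = 0.20,
    kdG      = 0.15,
    # --- condensed BAX/BAK/BH3 switch ---
    ksBH3    = 0.02,   # basal BH3 (Bim) synthesis
    kcBH3    = 0.09,   # CHOP-activated BH3 synthesis (saturating)
    KmBH3    = 1.05,
    kdBH3    = 0.10,
    BAXT     = 1,      # conserved total BAX
    kactBAX  = 0.0055, # BH3-driven BAX activation
    kautoBAX = 0.22,   # autocatalytic BAX recruitment
    JBAX     = 0.45,
    krevBAX  = 0.02,   # spontaneous re-translocation
    kbclBAX  = 0.15,   # Bcl-2 mediated deactivation
    Bcl2T    = 1,      # unrepressed Bcl-2 level
    KbclCHOP = 1.4,    # CHOP repression of Bcl-2: midpoint
    hbcl     = 4       # CHOP repression of Bcl-2: Hill coefficient
  )
}

# collect all character symbols referenced by a set of reactions / observables
used_symbols <- function(reactions, observables = list()) {
  syms <- character(0)
  grab <- function(v) if (is.character(v)) syms <<- c(syms, v)
  for (r in reactions) {
    for (f in r$law) {
      if (inherits(f, "upr_reg_term")) {
        grab(f$ref); grab(f$kc); grab(f$Km)
      } else if (is.list(f)) {
        for (tm in f) if (inherits(tm, "upr_reg_term")) {
          grab(tm$ref); grab(tm$kc); grab(tm$Km)
        }
      } else grab(f)
    }
  }
  for (o in observables) {
    syms <- c(syms, all.vars(parse(text = o)[[1]]))
  }
  unique(syms)
}

# subset the reference parameter vector to the symbols a model actually uses,
# with `extra` supplying clamped inputs and stand-ins absent from the
# reference vector
subset_params <- function(reactions, observables, extra = numeric(0),
                          base = upr_reference_params()) {
  syms <- used_symbols(reactions, observables)
  base[names(extra)] <- NA_real_  # extras shadow the base vector
  keep <- base[intersect(names(base), syms)]
  out <- c(keep[!is.na(keep)], extra)
  out[intersect(unique(c(names(keep), names(extra))), names(out))]
}

# --- network pieces (full-model reaction ids and parameter names) ----------

piece_core_stress <- function(bip_init = 5) {
  list(
    species = list(
      species_def("UFP",  "ER", 0, "unfolded protein"),
      species_def("BiP",  "ER", bip_init, "chaperone"),
      species_def("BUFP", "ER", 0, "chaperone complex")
    ),
    reactions = list(
      rx_syn("ufp_influx", "UFP", "mUFPT"),
      reaction_def("bip_ufp_on", reactants = c(BiP = 1, UFP = 1),
                   products = c(BUFP = 1), law = law_mass_action("kfB")),
      reaction_def("bip_ufp_off", reactants = c(BUFP = 1),
                   products = c(BiP = 1, UFP = 1),
                   law = law_mass_action("krbUFP")),
      rx_deg("ufp_deg", "UFP", "kdUFP"),
      rx_deg("bufp_deg", "BUFP", "kdBUFP"),
      rx_deg("bip_deg", "BiP", "kdBiP")
    )
  )
}

# core-stress variant for module-only builds: no UFP influx/dilution (total
# UFP is the conserved sweep input) but BiP still turns over everywhere, so
# the complex releases its UFP while the chaperone is degraded
module_core_stress <- function(bip_init = 5) {
  core <- piece_core_stress(bip_init)
  core$reactions <- core$reactions[
    !vapply(core$reactions, function(r)
      r$id %in% c("ufp_influx", "ufp_deg", "bufp_deg"), logical(1))]
  core$reactions <- c(core$reactions, list(
    reaction_def("bufp_bip_deg", reactants = c(BUFP = 1),
                 products = c(UFP = 1), law = law_mass_action("kdBUFP"))
  ))
  core
}

# generic receptor reactions for one receptor instance
piece_receptor <- function(id, krb, kf, kr, n, turnover = TRUE,
                           variant = "standard", extIRE = "extIREp",
                           init = 1) {
  R <- id; BR <- paste0("B", id); RA <- paste0(id, "a")
  act_law <- if (variant == "direct_ufp") {
    law_mass_action(kf, modifiers = "UFP")
  } else {
    law_mass_action(kf)
  }
  deact_law <- if (variant == "ufp_stabilised") {
    law_stabilised_decay(kr, ext = extIRE, ufp = "UFP")
  } else {
    law_mass_action(kr)
  }
  rxns <- list(
    reaction_def(paste0(id, "_bip_on"),
                 reactants = stats::setNames(c(1, 1), c("BiP", R)),
                 products = stats::setNames(1, BR),
                 law = law_mass_action("kfB")),
    reaction_def(paste0(id, "_bip_off"),
                 reactants = stats::setNames(1, BR),
                 products = stats::setNames(c(1, 1), c("BiP", R)),
                 law = law_mass_action(krb)),
    reaction_def(paste0(id, "_activation"),
                 reactants = stats::setNames(n, R),
                 products = stats::setNames(1, RA), law = act_law),
    reaction_def(paste0(id, "_deactivation"),
                 reactants = stats::setNames(1, RA),
                 products = stats::setNames(n, R), law = deact_law)
  )
  if (turnover) {
    rxns <- c(rxns, list(
      rx_syn(paste0(id, "_syn"), R, "vsR"),
      rx_deg(paste0(id, "_deg"), R, "kdR"),
      rx_deg(paste0(id, "a_deg"), RA, "kdR"),
      reaction_def(paste0("b", tolower(id), "_deg"),
                   reactants = stats::setNames(1, BR),
                   products = c(BiP = 1), law = law_mass_action("kdR"))
    ))
  }
  list(
    species = list(
      species_def(R, "ER", init, "receptor"),
      species_def(BR, "ER", 0, "chaperone complex"),
      species_def(RA, "ER", 0, "active receptor complex")
    ),
    reactions = rxns
  )
}

piece_atf6_branch <- function(turnover = TRUE) {
  base <- piece_receptor("ATF6", "krbATF6", 0, 0, 1, turnover = FALSE)
  # ATF6 does not oligomerise: drop the generic activation pair, the unbound
  # monomer is instead transferred to the Golgi and cleaved there.
  base$species <- base$species[1:2]   # ATF6, BATF6 (no ATF6a complex)
  base$reactions <- base$reactions[1:2]
  extra_species <- list(
    species_def("ATF6g",   "Golgi",   0, "receptor"),
    species_def("ATF6p50", "nucleus", 0, "TF"),
    species_def("WFS1",    "nucleus", 0.05, "negative regulator")
  )
  extra_rxns <- list(
    rx_syn("ATF6_syn", "ATF6", "vsR"),
    rx_deg("ATF6_deg", "ATF6", "kdR"),
    reaction_def("ATF6_wfs1_deg", reactants = c(ATF6 = 1),
                 law = law_mass_action("kdwATF6", modifiers = "WFS1")),
    rx_conv("ATF6_transfer", "ATF6", "ATF6g", "ktrATF6"),
    rx_conv("ATF6_cleave", "ATF6g", "ATF6p50", "kcleave"),
    rx_deg("ATF6g_deg", "ATF6g", "kdATF6g"),
    rx_deg("ATF6p50_deg", "ATF6p50", "kdATF6p50"),
    reaction_def("WFS1_syn", products = c(WFS1 = 1),
                 law = law_regulation(list(
                   reg_term(1, "kc0WFS1", 1),
                   reg_term("ATF6p50", "kcA6WFS1", "KmA6WFS1")))),
    rx_deg("WFS1_deg", "WFS1", "kdWFS1"),
    reaction_def("batf6_deg", reactants = c(BATF6 = 1), products = c(BiP = 1),
                 law = law_mass_action("kdR"))
  )
  list(species = c(base$species, extra_species),
       reactions = c(base$reactions, extra_rxns))
}

piece_xbp1_bip <- function() {
  list(
    species = list(
      species_def("mXBP1",  "cytoplasm", 0.25, "mRNA"),
      species_def("mXBP1s", "cytoplasm", 0, "mRNA"),
      species_def("XBP1s",  "nucleus",   0, "TF"),
      species_def("mBiP",   "cytoplasm", 0.75, "mRNA")
    ),
    reactions = list(
      reaction_def("mXBP1_syn", products = c(mXBP1 = 1),
                   law = law_regulation(list(
                     reg_term(1, "kc0XBP1", 1),
                     reg_term("ATF6p50", "kcA6XBP1", "KmA6XBP1"),
                     reg_term("extXBP", "kcA6XBP1", "KmA6XBP1")))),
      rx_deg("mXBP1_deg", "mXBP1", "kdmRNA"),
      reaction_def("xbp1_splicing", reactants = c(mXBP1 = 1),
                   products = c(mXBP1s = 1),
                   law = law_tqssa("kcspl", "Kmspl", enzyme = "IRE1a",
                                   enz_mult = "ncat")),
      rx_deg("mXBP1s_deg", "mXBP1s", "kdmXBP1s"),
      rx_translate("XBP1s_translation", "mXBP1s", "XBP1s", "ktlXBP1"),
      rx_deg("XBP1s_deg", "XBP1s", "kdXBP1s"),
      reaction_def("mBiP_syn", products = c(mBiP = 1),
                   law = law_regulation(list(
                     reg_term(1, "kc0BiP", 1),
                     reg_term("XBP1s", "kcXsBiP", "KmXsBiP"),
                     reg_term("ATF6p50", "kcA6BiP", "KmA6BiP"),
                     reg_term("extBiP", "kcXsBiP", "KmXsBiP")))),
      rx_deg("mBiP_deg", "mBiP", "kdmRNA"),
      rx_translate("BiP_translation", "mBiP", "BiP", "ktlBiP")
    )
  )
}

piece_perk_genetics <- function(enzyme = "PERKa", enz_mult = "nPERK") {
  list(
    species = list(
      species_def("eIF2a",   "cytoplasm", 1, "initiation factor"),
      species_def("eIF2aP",  "cytoplasm", 0, "initiation factor"),
      species_def("ATF4",    "nucleus",   0, "TF"),
      species_def("mCHOP",   "cytoplasm", 0, "mRNA"),
      species_def("CHOP",    "nucleus",   0, "TF"),
      species_def("mGADD34", "cytoplasm", 0, "mRNA"),
      species_def("GADD34",  "nucleus",   0, "phosphatase")
    ),
    reactions = list(
      reaction_def("eif2a_phos", reactants = c(eIF2a = 1),
                   products = c(eIF2aP = 1),
                   law = law_mm("kphos", "Kmphos", enzyme = enzyme,
                                enz_mult = enz_mult, inhibitor = "CHOP",
                                inh_K = "kmChop")),
      reaction_def("eif2a_dephos_g", reactants = c(eIF2aP = 1),
                   products = c(eIF2a = 1),
                   law = law_mm("kdephos", "Kmdephos", enzyme = "GADD34")),
      reaction_def("eif2a_dephos_crep", reactants = c(eIF2aP = 1),
                   products = c(eIF2a = 1),
                   law = law_mm("kdephos", "Kmdephos", enzyme = "CReP")),
      reaction_def("ATF4_syn", products = c(ATF4 = 1),
                   law = law_atf4_translation("ksATF4", "kATF4", "nh",
                                              "eIF2a")),
      rx_deg("ATF4_deg", "ATF4", "kdATF4"),
      reaction_def("mCHOP_syn", products = c(mCHOP = 1),
                   law = law_regulation(list(
                     reg_term(1, "kc0CHOP", 1),
                     reg_term("ATF4", "kcA4CHOP", "kmAtff"),
                     reg_term("ATF6p50", "kcA6CHOP", "KmA6CHOP"),
                     reg_term("XBP1s", "kcXsCHOP", "KmXsCHOP"),
                     reg_term("extCHOP", "kcA6CHOP", "KmA6CHOP")))),
      rx_deg("mCHOP_deg", "mCHOP", "kdmRNA"),
      rx_translate("CHOP_translation", "mCHOP", "CHOP", "ktlCHOP"),
      rx_deg("CHOP_deg", "CHOP", "kdCHOP"),
      reaction_def("mGADD34_syn", products = c(mGADD34 = 1),
                   law = law_regulation(list(
                     reg_term("CHOP", "kcChopG", "KmChopG")))),
      rx_deg("mGADD34_deg", "mGADD34", "kdmRNA"),
      rx_translate("GADD34_translation", "mGADD34", "GADD34", "ktlG"),
      rx_deg("GADD34_deg", "GADD34", "kdG")
    )
  )
}

piece_apoptosis <- function() {
  list(
    species = list(
      species_def("BH3",  "cytoplasm", 0, "apoptotic"),
      species_def("BAXa", "cytoplasm", 0, "apoptotic")
    ),
    reactions = list(
      rx_syn("BH3_syn_basal", "BH3", "ksBH3"),
      reaction_def("BH3_syn_chop", products = c(BH3 = 1),
                   law = law_regulation(list(
                     reg_term("CHOP", "kcBH3", "KmBH3")))),
      rx_deg("BH3_deg", "BH3", "kdBH3"),
      reaction_def("BAX_activation", products = c(BAXa = 1),
                   law = law_bax_activation("kactBAX", "BAXT", "BH3")),
      reaction_def("BAX_auto", products = c(BAXa = 1),
                   law = law_bax_auto("kautoBAX", "BAXT", "JBAX")),
      reaction_def("BAX_inactivation", reactants = c(BAXa = 1),
                   law = law_bax_inactivation("krevBAX", "kbclBAX", "Bcl2T",
                                              "KbclCHOP", "hbcl",
                                              chop = "CHOP"))
    )
  )
}

piece_model <- function(name, pieces, extra = numeric(0),
                        observables = list(), base = upr_reference_params()) {
  species <- do.call(c, lapply(pieces, `[[`, "species"))
  reactions <- do.call(c, lapply(pieces, `[[`, "reactions"))
  pars <- subset_params(reactions, observables, extra = extra, base = base)
  model_spec(name, species, reactions, pars, observables)
}

# --- configuration objects -------------------------------------------------

#' IRE1alpha branch configuration
#'
#' @param receptor A [receptor_params()] object for IRE1alpha; its `n` is
#'   the oligomer size (monomers per active complex).
#' @param cat_domains Catalytic domains per active complex (positive
#'   integer; each domain contributes enzyme capacity to XBP1 splicing).
#' @param kc_splice,Km_splice XBP1-splicing kinetics ([tqssa_rate()] form).
#' @param extXBP,extBiP External (ATF6-like) drives on XBP1 / BiP
#'   transcription, in acu of an equivalent activator.
#' @param overrides Named numeric vector of reference-parameter overrides.
#' @return An `upr_ire1_config` list.
#' @export
ire1_config <- function(receptor = NULL, cat_domains = 2,
                        kc_splice = NULL, Km_splice = NULL,
                        extXBP = 0, extBiP = 0, overrides = numeric(0)) {
  ref <- upr_reference_params()
  if (is.null(receptor)) {
    receptor <- receptor_params(kf = ref[["kfIRE1"]], kr = ref[["krIRE1"]],
                                n = ref[["nIRE1"]])
  }
  if (cat_domains < 1 || cat_domains != round(cat_domains)) {
    stop("ire1_config: cat_domains must be a positive integer")
  }
  structure(list(receptor = receptor, cat_domains = as.integer(cat_domains),
                 kc_splice = kc_splice %||% ref[["kcspl"]],
                 Km_splice = Km_splice %||% ref[["Kmspl"]],
                 extXBP = extXBP, extBiP = extBiP, overrides = overrides),
            class = "upr_ire1_config")
}

#' ATF6 branch configuration
#'
#' @param k_cleave Golgi cleavage rate constant; must stay well above the
#'   ER-to-Golgi transfer rate (ratio > 10 in the reference configuration,
#'   separating fast proteolysis from slow membrane remodelling).
#' @param k_transfer ER-to-Golgi transfer rate of unbound ATF6 (linear).
#' @param knockout Character vector among `"transfer"`, `"cleavage"`,
#'   `"wfs1"`; a knockout forces the corresponding reaction rate to zero and
#'   changes nothing else.
#' @param overrides Named numeric vector of reference-parameter overrides.
#' @return An `upr_atf6_config` list.
#' @export
atf6_config <- function(k_cleave = NULL, k_transfer = NULL,
                        knockout = character(0), overrides = numeric(0)) {
  ref <- upr_reference_params()
  k_cleave <- k_cleave %||% ref[["kcleave"]]
  k_transfer <- k_transfer %||% ref[["ktrATF6"]]
  bad <- setdiff(knockout, c("transfer", "cleavage", "wfs1"))
  if (length(bad)) stop("atf6_config: unknown knockout: ",
                        paste(bad, collapse = ", "))
  if (!length(knockout) && k_transfer > 0 && k_cleave / k_transfer <= 10) {
    stop("atf6_config: k_cleave must exceed 10 * k_transfer in the ",
         "reference configuration")
  }
  structure(list(k_cleave = k_cleave, k_transfer = k_transfer,
                 knockout = knockout, overrides = overrides),
            class = "upr_atf6_config")
}

#' PERK branch configuration
#'
#' @param receptor A [receptor_params()] object for PERK.
#' @param PERKA Clamped active-PERK level (acu) for the standalone branch
#'   build; in the full assembly active PERK is dynamic and this value is
#'   unused.
#' @param attenuation_midpoint Fractional decrease of active eIF2alpha at
#'   which ATF4 translation is half-activated; in `(0, 1)`.
#' @param nh ATF4-activation Hill coefficient (`>= 1`).
#' @param extCHOP External (ATF6/XBP1-equivalent) drive on CHOP
#'   transcription (acu).
#' @param overrides Named numeric vector of reference-parameter overrides
#'   (e.g. `c(kphos = , kdephos = , CReP = , kmChop = , kmAtff = ,
#'   eIF2aT = )`).
#' @return An `upr_perk_config` list.
#' @export
perk_config <- function(receptor = NULL, PERKA = 1,
                        attenuation_midpoint = NULL, nh = NULL,
                        extCHOP = NULL, overrides = numeric(0)) {
  ref <- upr_reference_params()
  if (is.null(receptor)) {
    receptor <- receptor_params(kf = ref[["kfPERK"]], kr = ref[["krPERK"]],
                                n = ref[["nPERK"]])
  }
  attenuation_midpoint <- attenuation_midpoint %||% 0.9
  nh <- nh %||% ref[["nh"]]
  if (attenuation_midpoint <= 0 || attenuation_midpoint >= 1) {
    stop("perk_config: attenuation_midpoint must lie in (0, 1)")
  }
  if (nh < 1) stop("perk_config: nh must be >= 1")
  structure(list(receptor = receptor, PERKA = PERKA,
                 attenuation_midpoint = attenuation_midpoint, nh = nh,
                 extCHOP = extCHOP %||% ref[["extCHOP"]],
                 overrides = overrides),
            class = "upr_perk_config")
}

#' Apoptosis (condensed BAX/BAK/BH3 switch) configuration
#'
#' The condensed mitochondrial outer-membrane switch: BH3-only activator
#' (Bim) synthesis driven by CHOP, autocatalytic BAX recruitment, and Bcl-2
#' mediated deactivation with CHOP repressing Bcl-2 through a Hill term.
#' CHOP replaces the original model's generic "Stress" input.
#'
#' @param CHOP Clamped CHOP level (acu) for the standalone module build.
#' @param overrides Named numeric vector of reference-parameter overrides
#'   (the `ksBH3 ... hbcl` block of [upr_reference_params()]).
#' @return An `upr_apoptosis_config` list.
#' @export
apoptosis_config <- function(CHOP = 0, overrides = numeric(0)) {
  structure(list(CHOP = CHOP, overrides = overrides),
            class = "upr_apoptosis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_overrides <- function(model, overrides) {
  if (length(overrides)) {
    overrides <- overrides[names(overrides) %in% names(model$parameters)]
    if (length(overrides)) model <- set_parameters(model, overrides)
  }
  model
}

# --- public builders -------------------------------------------------------

#' Build the generic receptor activation module
#'
#' A single stress receptor competing with unfolded protein (UFP) for BiP:
#' BiP sequesters the inactive monomer; free monomers assemble cooperatively
#' into the active complex, which reverts spontaneously. No synthesis or
#' degradation is present, so receptor, BiP and UFP totals are conserved and
#' the module's steady-state response can be swept against total UFP.
#'
#' @param params A [receptor_params()] object (activation variant included).
#' @param bip_total,receptor_total Initial (conserved) BiP and receptor
#'   monomer totals (acu).
#' @param ufp_total Initial (conserved) total UFP (acu); sweep this for
#'   response curves.
#' @param krb BiP:receptor dissociation rate constant.
#' @param kfB,krbUFP BiP association rate (shared with UFP binding) and
#'   BiP:UFP dissociation rate.
#' @return A `upr_model` with species `Receptor`, `ReceptorA`, `BiP`,
#'   `BReceptor`, `UFP`, `BUFP`, and observables `RA` (phosphorylated
#'   receptor, `n * ReceptorA`), `UFPT` and `BiPT`.
#' @export
build_receptor_module <- function(params = NULL, bip_total = 5,
                                  receptor_total = 1, ufp_total = 0,
                                  krb = 1, kfB = 10, krbUFP = 1) {
  ref <- upr_reference_params()
  if (is.null(params)) {
    params <- receptor_params(kf = ref[["kfIRE1"]], kr = ref[["krIRE1"]],
                              n = ref[["nIRE1"]])
  }
  stopifnot(inherits(params, "upr_receptor_params"))
  rec <- piece_receptor("Receptor", "krbR", "kfR", "krR", params$n,
                        turnover = FALSE, variant = params$variant,
                        extIRE = "extIREp", init = receptor_total)
  sp <- c(list(
    species_def("UFP", "ER", ufp_total, "unfolded protein"),
    species_def("BiP", "ER", bip_total, "chaperone"),
    species_def("BUFP", "ER", 0, "chaperone complex")
  ), rec$species)
  rxns <- c(list(
    reaction_def("bip_ufp_on", reactants = c(BiP = 1, UFP = 1),
                 products = c(BUFP = 1), law = law_mass_action("kfB")),
    reaction_def("bip_ufp_off", reactants = c(BUFP = 1),
                 products = c(BiP = 1, UFP = 1),
                 law = law_mass_action("krbUFP"))
  ), rec$reactions)
  pars <- c(kfB = kfB, krbUFP = krbUFP, krbR = krb, kfR = params$kf,
            krR = params$kr, nR = as.numeric(params$n),
            extIREp = params$extIRE)
  obs <- list(RA = "nR * Receptora",
              UFPT = "UFP + BUFP",
              BiPT = "BiP + BUFP + BReceptor")
  model_spec("receptor_module", sp, rxns, pars, obs)
}

#' Build the IRE1alpha branch (adaptive response) model
#'
#' The IRE1alpha receptor module plus its genetic cascade: active IRE1alpha
#' complexes splice XBP1 mRNA through the total-QSSA rate law (enzyme
#' capacity = active complexes x catalytic domains), spliced XBP1 protein
#' activates BiP transcription competitively, and newly translated BiP feeds
#' back on receptor sequestration. Receptor turnover is disabled in this
#' module-only build (receptor total conserved); UFP is a conserved sweep
#' input. External drives `extXBP` and `extBiP` enter the respective
#' transcription laws as additional activator terms.
#'
#' @param config An [ire1_config()].
#' @return A `upr_model` with observables `IRE1A`, `UFPT`, `BiPT`.
#' @export
build_ire1_branch <- function(config = ire1_config()) {
  stopifnot(inherits(config, "upr_ire1_config"))
  rec <- piece_receptor("IRE1", "krbIRE1", "kfIRE1", "krIRE1",
                        config$receptor$n, turnover = FALSE,
                        variant = config$receptor$variant)
  core <- module_core_stress()
  obs <- list(IRE1A = "nIRE1 * IRE1a",
              UFPT = "UFP + BUFP",
              BiPT = "BiP + BUFP + BIRE1",
              XBP1s = "XBP1s")
  m <- piece_model("ire1_branch", list(core, rec, piece_xbp1_bip()),
                   extra = c(ATF6p50 = 0,
                             extXBP = config$extXBP, extBiP = config$extBiP,
                             kfIRE1 = config$receptor$kf,
                             krIRE1 = config$receptor$kr,
                             nIRE1 = as.numeric(config$receptor$n),
                             ncat = as.numeric(config$cat_domains),
                             kcspl = config$kc_splice,
                             Kmspl = config$Km_splice),
                   observables = obs)
  apply_overrides(m, config$overrides)
}

#' Build the adaptive-response model with the ATF6 branch
#'
#' Extends the IRE1alpha branch with the three-compartment ATF6 flow:
#' BiP-sequestered ATF6 on the ER membrane, linear transfer of the unbound
#' monomer to the Golgi, fast cleavage to the transcription factor ATF6p50,
#' and the WFS1 negative-feedback loop (ATF6p50 induces WFS1, which enhances
#' ER-membrane ATF6 degradation). ATF6p50 contributes activator terms to
#' XBP1, BiP and CHOP transcription with gene-specific weights. ATF6 is
#' synthesised and degraded (it must be replenished after cleavage); the
#' IRE1alpha receptor total remains conserved.
#'
#' @param config An [atf6_config()].
#' @param ire1 An [ire1_config()] for the embedded IRE1alpha branch.
#' @return A `upr_model` with observables `IRE1A`, `UFPT`, `BiPT`,
#'   `ATF6cleaved_pct`.
#' @export
build_atf6_branch <- function(config = atf6_config(), ire1 = ire1_config()) {
  stopifnot(inherits(config, "upr_atf6_config"))
  rec <- piece_receptor("IRE1", "krbIRE1", "kfIRE1", "krIRE1",
                        ire1$receptor$n, turnover = FALSE,
                        variant = ire1$receptor$variant)
  core <- module_core_stress()
  obs <- list(IRE1A = "nIRE1 * IRE1a",
              UFPT = "UFP + BUFP",
              BiPT = "BiP + BUFP + BIRE1 + BATF6",
              ATF6cleaved_pct =
                "100 * ATF6p50 / (ATF6 + BATF6 + ATF6g + ATF6p50)")
  extra <- c(extXBP = ire1$extXBP, extBiP = ire1$extBiP,
             ncat = as.numeric(ire1$cat_domains),
             ktrATF6 = config$k_transfer, kcleave = config$k_cleave)
  m <- piece_model("atf6_branch",
                   list(core, rec, piece_atf6_branch(), piece_xbp1_bip()),
                   extra = extra, observables = obs)
  m <- apply_knockouts(m, config$knockout)
  apply_overrides(m, config$overrides)
}

apply_knockouts <- function(model, knockout) {
  if ("transfer" %in% knockout) model <- set_parameters(model, ktrATF6 = 0)
  if ("cleavage" %in% knockout) model <- set_parameters(model, kcleave = 0)
  if ("wfs1" %in% knockout) model <- set_parameters(model, kdwATF6 = 0)
  model
}

#' Build the standalone PERK branch (translation attenuation) model
#'
#' The eIF2alpha phosphorylation cycle driven by a *clamped* active-PERK
#' level `PERKA` (the bifurcation parameter of the branch), with
#' Michaelis-Menten (zero-order regime) phosphorylation and GADD34/CReP
#' dephosphorylation, ATF4 translation activated by the fractional decrease
#' of active eIF2alpha through a Hill response (midpoint
#' `attenuation_midpoint`, coefficient `nh`), and the genetic cascade
#' ATF4 -> CHOP -> GADD34 closing the delayed negative feedback. CHOP also
#' attenuates the phosphorylation rate (constant `kmChop`). `extCHOP` enters
#' CHOP transcription as an external activator term.
#'
#' @param config A [perk_config()].
#' @return A `upr_model` with observables `translation`
#'   (`eIF2a / eIF2aT`, the relative translation rate) and `CHOP`.
#' @export
build_perk_branch <- function(config = perk_config()) {
  stopifnot(inherits(config, "upr_perk_config"))
  gen <- piece_perk_genetics(enzyme = "PERKA", enz_mult = 1)
  obs <- list(translation = "eIF2a / eIF2aT", CHOPlevel = "CHOP",
              phospho_frac = "eIF2aP / eIF2aT")
  ref <- upr_reference_params()
  m <- piece_model("perk_branch", list(gen),
                   extra = c(PERKA = config$PERKA,
                             ATF6p50 = 0, XBP1s = 0,
                             extCHOP = config$extCHOP,
                             kATF4 = (1 - config$attenuation_midpoint) *
                               ref[["eIF2aT"]],
                             nh = config$nh),
                   observables = obs)
  # eIF2a starts from the total (all active)
  i <- match("eIF2a", species_ids(m))
  m$species[[i]]$initial <- unname(m$parameters[["eIF2aT"]])
  m <- apply_overrides(m, config$overrides)
  attr(m, "fastpath") <- "perk"
  m
}

#' Build the standalone condensed BAX/BAK/BH3 apoptosis module
#'
#' @param config An [apoptosis_config()]; `config$CHOP` is the clamped
#'   input replacing the original switch's "Stress" parameter.
#' @return A `upr_model` with species `BH3`, `BAXa` and observable `BAXa`.
#' @export
build_apoptosis_module <- function(config = apoptosis_config()) {
  stopifnot(inherits(config, "upr_apoptosis_config"))
  m <- piece_model("apoptosis_module", list(piece_apoptosis()),
                   extra = c(CHOP = config$CHOP),
                   observables = list(BAXactive = "BAXa"))
  m <- apply_overrides(m, config$overrides)
  attr(m, "fastpath") <- "apop"
  m
}

#' Assemble the complete integrated UPR model
#'
#' Composes the stress-input core, the three receptor branches, the
#' XBP1/BiP genetic cascade, the PERK translation-attenuation cascade and
#' (optionally) the apoptosis switch into the single reference network:
#' 27 species, 62 reaction channels, 82 parameters. Shared species (BiP,
#' UFP, CHOP, ATF6p50, XBP1s) are merged by id. Unfolded protein enters at
#' the constant protocol rate `mUFPT` and is never cleared by UPR-dependent
#' folding (unmitigated-stress assumption); only slow dilution balances the
#' influx.
#'
#' @param ire1 An [ire1_config()].
#' @param atf6 An [atf6_config()] (knockouts apply to the assembly).
#' @param perk A [perk_config()] (its clamped `PERKA` is ignored: active
#'   PERK is dynamic here, entering the phosphorylation law as
#'   `nPERK * PERKa`).
#' @param apoptosis An [apoptosis_config()] or `NULL` to omit the module.
#' @param receptor_variant Activation variant applied to the IRE1alpha and
#'   PERK receptors: `"standard"`, `"direct_ufp"` or `"ufp_stabilised"`.
#' @param overrides Named numeric vector of parameter overrides applied
#'   last.
#' @return A `upr_model` named `"upr_full"` with observables `UFPT`, `BiPT`,
#'   `IRE1A`, `PERKA`, `ATF6cleaved_pct`, `translation`, `CHOPlevel`,
#'   `BAXactive`.
#' @export
assemble_full_model <- function(ire1 = ire1_config(), atf6 = atf6_config(),
                                perk = perk_config(),
                                apoptosis = apoptosis_config(),
                                receptor_variant = "standard",
                                overrides = numeric(0)) {
  pieces <- list(
    piece_core_stress(),
    piece_receptor("IRE1", "krbIRE1", "kfIRE1", "krIRE1", ire1$receptor$n,
                   turnover = TRUE, variant = receptor_variant,
                   extIRE = "extIREp"),
    piece_receptor("PERK", "krbPERK", "kfPERK", "krPERK", perk$receptor$n,
                   turnover = TRUE, variant = receptor_variant,
                   extIRE = "extIREp"),
    piece_atf6_branch(),
    piece_xbp1_bip(),
    piece_perk_genetics(enzyme = "PERKa", enz_mult = "nPERK")
  )
  if (!is.null(apoptosis)) pieces <- c(pieces, list(piece_apoptosis()))
  obs <- list(
    UFPT = "UFP + BUFP",
    BiPT = "BiP + BUFP + BIRE1 + BPERK + BATF6",
    IRE1A = "nIRE1 * IRE1a",
    PERKA = "nPERK * PERKa",
    ATF6cleaved_pct = "100 * ATF6p50 / (ATF6 + BATF6 + ATF6g + ATF6p50)",
    translation = "eIF2a / eIF2aT",
    CHOPlevel = "CHOP",
    BAXactive = if (!is.null(apoptosis)) "BAXa" else "0"
  )
  extra <- c(
    nIRE1 = as.numeric(ire1$receptor$n), nPERK = as.numeric(perk$receptor$n),
    ncat = as.numeric(ire1$cat_domains),
    kATF4 = (1 - perk$attenuation_midpoint) *
      upr_reference_params()[["eIF2aT"]],
    nh = perk$nh,
    extCHOP = perk$extCHOP, extXBP = ire1$extXBP, extBiP = ire1$extBiP,
    ktrATF6 = atf6$k_transfer, kcleave = atf6$k_cleave
  )
  if (receptor_variant == "ufp_stabilised") extra <- c(extra, extIREp = 0.1)
  m <- piece_model("upr_full", pieces, extra = extra, observables = obs)
  i <- match("eIF2a", species_ids(m))
  m$species[[i]]$initial <- unname(m$parameters[["eIF2aT"]])
  m <- apply_knockouts(m, atf6$knockout)
  m <- apply_overrides(m, atf6$overrides)
  m <- apply_overrides(m, ire1$overrides)
  m <- apply_overrides(m, perk$overrides)
  if (!is.null(apoptosis)) m <- apply_overrides(m, apoptosis$overrides)
  m <- apply_overrides(m, overrides)
  if (!is.null(apoptosis)) {
    attr(m, "fastpath") <- "full"
    attr(m, "vflag") <- match(receptor_variant,
                              c("standard", "direct_ufp",
                                "ufp_stabilised")) - 1L
  }
  m
}
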