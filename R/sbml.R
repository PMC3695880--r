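#' @title SBML Level 2 Version 4 interchange
#' @description Serialises a model specification to SBML L2V4 (the
#'   deposition format of the reference model) and reads such documents
#'   back. Kinetic laws are emitted both as genuine MathML (for third-party
#'   interoperability) and as a structured annotation in the package's
#'   namespace; the importer reconstructs the rate laws from the annotation
#'   and raises an explicit error, naming the element, for documents that
#'   lack it or use constructs outside the package's rate-law registry.
#' @name sbml
NULL

upr_sbml_ns <- "https://uprsim.r-pkg/annotation"

# render a law as an infix expression string over species/parameter symbols
law_to_expr <- function(law, reaction) {
  sym <- function(v) if (is.numeric(v)) format(v, digits = 17) else v
  r1 <- function() names(reaction$reactants)[1]
  switch(law$type,
    const = sym(law$k),
    mass_action = {
      parts <- sym(law$k)
      if (length(reaction$reactants)) {
        parts <- c(parts, vapply(seq_along(reaction$reactants), function(i) {
          s <- reaction$reactants[i]
          if (s == 1) names(s) else paste0(names(s), "^", s)
        }, character(1)))
      }
      parts <- c(parts, vapply(law$modifiers, identity, character(1)))
      paste(parts, collapse = " * ")
    },
    stab_decay = sprintf("%s * %s / (1 + %s * %s)", sym(law$k), r1(),
                         sym(law$ext), sym(law$ufp)),
    tqssa = {
      S <- r1()
      E <- sprintf("(%s * %s)", sym(law$enz_mult), sym(law$enzyme))
      tot <- sprintf("(%s + %s + %s)", S, E, sym(law$Km))
      sprintf("0.5 * %s * (%s - sqrt(%s^2 - 4 * %s * %s))",
              sym(law$kc), tot, tot, S, E)
    },
    regulation = {
      num <- character(0); den <- "1"
      for (tm in law$terms) {
        w <- sprintf("(%s / %s)", sym(tm$ref), sym(tm$Km))
        num <- c(num, sprintf("%s * %s", sym(tm$kc), w))
        den <- c(den, w)
      }
      if (!length(num)) return("0")
      sprintf("(%s) / (%s)", paste(num, collapse = " + "),
              paste(den, collapse = " + "))
    },
    mm = {
      S <- r1()
      base <- sprintf("%s * %s * %s * %s / (%s + %s)", sym(law$kc),
                      sym(law$enz_mult), sym(law$enzyme), S, sym(law$Km), S)
      if (!is.null(law$inhibitor)) {
        base <- sprintf("%s / (1 + %s / %s)", base, sym(law$inhibitor),
                        sym(law$inh_K))
      }
      base
    },
    atf4_translation = {
      r <- sprintf("(%s / %s)^%s", sym(law$eif2a), sym(law$K), sym(law$h))
      sprintf("%s / (1 + %s)", sym(law$ks), r)
    },
    bax_activation = {
      X <- names(reaction$products)[1]
      sprintf("%s * %s * (%s - %s)", sym(law$k), sym(law$activator),
              sym(law$total), X)
    },
    bax_auto = {
      X <- names(reaction$products)[1]
      sprintf("%s * (%s - %s) * %s^2 / (%s^2 + %s^2)", sym(law$k),
              sym(law$total), X, X, sym(law$J), X)
    },
    bax_inactivation = {
      X <- names(reaction$reactants)[1]
      bcl <- sprintf("%s * %s^%s / (%s^%s + %s^%s)", sym(law$bcl2T),
                     sym(law$K), sym(law$h), sym(law$K), sym(law$h),
                     sym(law$chop), sym(law$h))
      sprintf("(%s + %s * %s) * %s", sym(law$krev), sym(law$kbcl), bcl, X)
    },
    stop("law_to_expr: unsupported law type '", law$type, "'")
  )
}

# R expression -> Content MathML nodes (supports + - * / ^ sqrt and symbols)
expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  }
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(expr_to_mathml(args[[1]]))
    opname <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                     "/" = "divide", "^" = "power", "sqrt" = "root",
                     stop("expr_to_mathml: unsupported operator '", op, "'"))
    inner <- paste(vapply(args, expr_to_mathml, character(1)),
                   collapse = "\n")
    return(paste0("<apply>\n<", opname, "/>\n", inner, "\n</apply>"))
  }
  stop("expr_to_mathml: unsupported expression element")
}

serialise_law <- function(law) {
  out <- unclass(law)
  out <- out[!vapply(out, is.null, logical(1))]
  if (identical(law$type, "regulation")) {
    out$terms <- lapply(law$terms, unclass)
  }
  out
}

deserialise_law <- function(x) {
  known <- c("const", "mass_action", "stab_decay", "tqssa", "regulation",
             "mm", "atf4_translation", "bax_activation", "bax_auto",
             "bax_inactivation")
  if (is.null(x$type) || !x$type %in% known) {
    stop("SBML import: unsupported rate-law type '", x$type %||% "<none>",
         "'")
  }
  # empty JSON containers stand for absent optional fields
  x[vapply(x, function(v) is.list(v) && !length(v), logical(1))] <- NULL
  if (identical(x$type, "regulation")) {
    x$terms <- lapply(x$terms, function(tm) {
      structure(tm[c("ref", "kc", "Km")], class = "upr_reg_term")
    })
  }
  if (identical(x$type, "mass_action") && is.null(x$modifiers)) {
    x$modifiers <- character(0)
  }
  structure(x, class = "upr_law")
}

#' Export a model to SBML Level 2 Version 4
#'
#' @param model A `upr_model`.
#' @param path Destination file; when `NULL` the `xml2` document is
#'   returned instead.
#' @return The path (invisibly) or an `xml_document`.
#' @export
export_sbml <- function(model, path = NULL) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  comp_xml <- paste(sprintf(
    '<compartment id="%s" size="1"/>', upr_compartments), collapse = "\n")
  sp_xml <- paste(vapply(model$species, function(s) {
    sprintf(paste0('<species id="%s" name="%s" compartment="%s" ',
                   'initialConcentration="%s"/>'),
            s$id, esc(s$role), s$compartment,
            format(s$initial, digits = 17))
  }, character(1)), collapse = "\n")
  par_xml <- paste(vapply(seq_along(model$parameters), function(i) {
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            names(model$parameters)[i],
            format(model$parameters[[i]], digits = 17))
  }, character(1)), collapse = "\n")
  rx_xml <- paste(vapply(model$reactions, function(r) {
    refs <- function(v) paste(vapply(seq_along(v), function(i) {
      sprintf('<speciesReference species="%s" stoichiometry="%s"/>',
              names(v)[i], format(v[[i]]))
    }, character(1)), collapse = "\n")
    expr <- law_to_expr(r$law, r)
    math <- expr_to_mathml(parse(text = expr)[[1]])
    ann <- jsonlite::toJSON(serialise_law(r$law), auto_unbox = TRUE,
                            digits = NA)
    paste0(
      '<reaction id="', r$id, '" reversible="false">\n',
      '<annotation><uprsim:law xmlns:uprsim="', upr_sbml_ns, '">',
      esc(as.character(ann)), '</uprsim:law></annotation>\n',
      if (length(r$reactants)) {
        paste0("<listOfReactants>\n", refs(r$reactants),
               "\n</listOfReactants>\n")
      } else "",
      if (length(r$products)) {
        paste0("<listOfProducts>\n", refs(r$products),
               "\n</listOfProducts>\n")
      } else "",
      '<kineticLaw>\n',
      '<math xmlns="http://www.w3.org/1998/Math/MathML">\n', math,
      '\n</math>\n</kineticLaw>\n</reaction>')
  }, character(1)), collapse = "\n")
  obs_ann <- jsonlite::toJSON(model$observables, auto_unbox = TRUE)
  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" ',
    'version="4">\n',
    '<model id="', gsub("[^A-Za-z0-9_]", "_", model$name), '" name="',
    esc(model$name), '">\n',
    '<annotation><uprsim:observables xmlns:uprsim="', upr_sbml_ns, '">',
    esc(as.character(obs_ann)), '</uprsim:observables></annotation>\n',
    "<listOfCompartments>\n", comp_xml, "\n</listOfCompartments>\n",
    "<listOfSpecies>\n", sp_xml, "\n</listOfSpecies>\n",
    "<listOfParameters>\n", par_xml, "\n</listOfParameters>\n",
    "<listOfReactions>\n", rx_xml, "\n</listOfReactions>\n",
    "</model>\n</sbml>\n")
  doc <- xml2::read_xml(doc_str)
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML Level 2 Version 4
#'
#' Reads documents produced by [export_sbml()]. Kinetic laws are
#' reconstructed from the package's structured annotation; a reaction
#' without it (e.g. third-party SBML with free-form MathML) raises an error
#' naming the reaction.
#'
#' @param path SBML file, or an `xml_document`.
#' @return A `upr_model`.
#' @export
import_sbml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level2/version4", u = upr_sbml_ns)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("SBML import: no <model> element (is this SBML L2V4?)")
  }
  name <- xml2::xml_attr(mdl, "name") %||% xml2::xml_attr(mdl, "id")
  species <- lapply(xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species",
                                       ns), function(nd) {
    species_def(xml2::xml_attr(nd, "id"), xml2::xml_attr(nd, "compartment"),
                as.numeric(xml2::xml_attr(nd, "initialConcentration")),
                role = xml2::xml_attr(nd, "name") %||% "")
  })
  pnodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parameters <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  reactions <- lapply(
    xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns),
    function(nd) {
      id <- xml2::xml_attr(nd, "id")
      ann <- xml2::xml_find_first(nd, ".//u:law", ns)
      if (inherits(ann, "xml_missing")) {
        stop("SBML import: reaction '", id, "' carries no structured ",
             "rate-law annotation; only documents written by export_sbml() ",
             "are supported")
      }
      law <- deserialise_law(jsonlite::fromJSON(xml2::xml_text(ann),
                                                simplifyVector = FALSE))
      sref <- function(xp) {
        nds <- xml2::xml_find_all(nd, xp, ns)
        if (!length(nds)) return(numeric(0))
        stats::setNames(as.numeric(xml2::xml_attr(nds, "stoichiometry")),
                        xml2::xml_attr(nds, "species"))
      }
      reaction_def(id, reactants = sref(".//s:listOfReactants/s:speciesReference"),
                   products = sref(".//s:listOfProducts/s:speciesReference"),
                   law = law)
    })
  obs_ann <- xml2::xml_find_first(mdl, "./s:annotation/u:observables", ns)
  observables <- if (!inherits(obs_ann, "xml_missing")) {
    lapply(jsonlite::fromJSON(xml2::xml_text(obs_ann),
                              simplifyVector = FALSE), as.character)
  } else list()
  model_spec(name %||% "imported", species, reactions, parameters,
             observables)
}
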