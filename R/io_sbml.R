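# SBML Level 3 core subset reader/writer.
#
# Supported subset: compartments, species with integer initialAmount
# (hasOnlySubstanceUnits semantics), parameters, and irreversible
# mass-action reactions whose kinetic law is a single constant times a
# product of reactant species (powers allowed). Reversible reactions are
# split into two irreversible halves at load. FBA submodels use the flux
# balance constraints (FBC) idiom: bounds as parameters referenced from
# reaction attributes, plus an objective list. Species participating in an
# FBA steady state (internal metabolites) are marked with
# boundaryCondition="false"; pool-exchange species carry "true", following
# the constraint-based convention that boundary metabolites are exempt
# from the steady-state balance. Everything outside the subset (events,
# rate/assignment/algebraic rules, constraints, initial assignments,
# function definitions) is rejected with an error naming the construct —
# never silently ignored.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.WC_ANN_NS <- "http://wcsim.r-pkg.example/annotation"

#' Write a submodel as standalone SBML
#'
#' The written document round-trips through [read_submodel_sbml()] exactly:
#' ids, stoichiometries, rate constants, bounds and objective are
#' preserved. Numeric rate constants are written as `constant="true"`
#' parameters; parameter-name rate constants (retunable by Boolean rules)
#' are written as `constant="false"` parameters and read back as
#' references. The submodel's formalism is recorded as a model annotation
#' (core SBML has no formalism attribute); the composition manifest
#' remains authoritative for it.
#'
#' @param submodel A [wc_submodel()] (SSA, ODE, or FBA).
#' @param compartments List of [wc_compartment()] covering the submodel's
#'   species.
#' @param path Optional file path; when given the document is written there.
#' @return The `xml2::xml_document`, invisibly when `path` is given.
#' @export
write_submodel_sbml <- function(submodel, compartments, path = NULL) {
  if (identical(submodel$formalism, "BOOLEAN")) {
    stop("Boolean submodels live in the composition manifest, not SBML", call. = FALSE)
  }
  doc <- xml2::xml_new_root("sbml",
    "xmlns" = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = submodel$id, "fbc:strict" = "false")

  ann <- xml2::xml_add_child(model, "annotation")
  frm <- xml2::xml_add_child(ann, "formalism", xmlns = .WC_ANN_NS)
  xml2::xml_set_text(frm, submodel$formalism)

  used_comps <- unique(vapply(submodel$species, function(s) s$compartment, character(1)))
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in compartments) {
    if (!(cmp$id %in% used_comps) && length(used_comps)) next
    xml2::xml_add_child(loc, "compartment", id = cmp$id, name = cmp$name,
                        size = format(cmp$volume, digits = 17),
                        spatialDimensions = "3", constant = "true")
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  internal <- if (!is.null(submodel$fba)) submodel$fba$internal else character(0)
  for (sp in submodel$species) {
    xml2::xml_add_child(los, "species", id = sp$id, name = sp$name,
                        compartment = sp$compartment,
                        initialAmount = format(sp$initial_count, digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = if (sp$id %in% internal) "false" else "true",
                        constant = "false")
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (r in submodel$reactions) {
    k <- r$rate_constant
    if (is.character(k)) {
      xml2::xml_add_child(lop, "parameter", id = k, constant = "false")
    } else {
      xml2::xml_add_child(lop, "parameter", id = paste0("k_", r$id),
                          value = format(k, digits = 17), constant = "true")
    }
  }
  if (!is.null(submodel$fba)) {
    for (r in submodel$reactions) {
      lb <- submodel$fba$lower[r$id]
      ub <- submodel$fba$upper[r$id]
      if (!is.na(lb)) {
        xml2::xml_add_child(lop, "parameter", id = paste0("lb_", r$id),
                            value = format(unname(lb), digits = 17), constant = "true")
      }
      if (!is.na(ub)) {
        xml2::xml_add_child(lop, "parameter", id = paste0("ub_", r$id),
                            value = format(unname(ub), digits = 17), constant = "true")
      }
    }
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in submodel$reactions) {
    attrs <- list(id = r$id, reversible = "false", fast = "false")
    if (!is.null(submodel$fba)) {
      if (!is.na(submodel$fba$lower[r$id])) {
        attrs[["fbc:lowerFluxBound"]] <- paste0("lb_", r$id)
      }
      if (!is.na(submodel$fba$upper[r$id])) {
        attrs[["fbc:upperFluxBound"]] <- paste0("ub_", r$id)
      }
    }
    rxn <- do.call(xml2::xml_add_child, c(list(lor, "reaction"), attrs))
    .write_species_refs(rxn, "listOfReactants", r$reactants)
    .write_species_refs(rxn, "listOfProducts", r$products)
    if (is.null(submodel$fba)) {
      kl <- xml2::xml_add_child(rxn, "kineticLaw")
      math <- xml2::xml_add_child(kl, "math", xmlns = .MATHML_NS)
      kid <- if (is.character(r$rate_constant)) r$rate_constant else paste0("k_", r$id)
      .write_mass_action_math(math, kid, r$reactants)
    }
  }

  if (!is.null(submodel$fba) && length(submodel$fba$objective)) {
    loo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    for (rid in names(submodel$fba$objective)) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" = format(submodel$fba$objective[[rid]],
                                                     digits = 17))
    }
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

.write_species_refs <- function(rxn, list_name, stoich) {
  if (length(stoich) == 0L) return(invisible(NULL))
  lst <- xml2::xml_add_child(rxn, list_name)
  for (sp in names(stoich)) {
    xml2::xml_add_child(lst, "speciesReference", species = sp,
                        stoichiometry = format(stoich[[sp]], digits = 17),
                        constant = "true")
  }
}

.write_mass_action_math <- function(math, param_id, reactants) {
  if (length(reactants) == 0L) {
    ci <- xml2::xml_add_child(math, "ci")
    xml2::xml_set_text(ci, param_id)
    return(invisible(NULL))
  }
  ap <- xml2::xml_add_child(math, "apply")
  xml2::xml_add_child(ap, "times")
  ci <- xml2::xml_add_child(ap, "ci")
  xml2::xml_set_text(ci, param_id)
  for (sp in names(reactants)) {
    s <- reactants[[sp]]
    if (s == 1) {
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci, sp)
    } else {
      pw <- xml2::xml_add_child(ap, "apply")
      xml2::xml_add_child(pw, "power")
      ci <- xml2::xml_add_child(pw, "ci")
      xml2::xml_set_text(ci, sp)
      cn <- xml2::xml_add_child(pw, "cn", type = "integer")
      xml2::xml_set_text(cn, format(s))
    }
  }
  invisible(NULL)
}

#' Read a submodel from the SBML subset
#'
#' @param x A file path or an `xml2::xml_document`.
#' @param formalism Formalism to tag the submodel with; defaults to the
#'   document's annotation when present, else `"SSA"`. FBA submodels pick
#'   up FBC bounds and objective.
#' @param id Submodel id; defaults to the SBML model id.
#' @return A list of class `wc_sbml_submodel`: `submodel`
#'   ([wc_submodel()]) and `compartments` (list of [wc_compartment()]).
#' @export
read_submodel_sbml <- function(x, formalism = NULL, id = NULL) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS, m = .MATHML_NS)
  model <- xml2::xml_find_first(root, "./s:model", ns)
  if (inherits(model, "xml_missing")) stop("no <model> element found", call. = FALSE)

  .reject_unsupported(model, ns)

  if (is.null(id)) id <- xml2::xml_attr(model, "id")
  if (is.na(id) || !nzchar(id)) id <- "submodel"
  if (is.null(formalism)) {
    ann <- xml2::xml_find_first(model, ".//*[local-name() = 'formalism']")
    formalism <- if (!inherits(ann, "xml_missing")) xml2::xml_text(ann) else "SSA"
  }
  formalism <- match.arg(formalism, setdiff(WC_FORMALISMS, "BOOLEAN"))

  compartments <- lapply(xml2::xml_find_all(model, "./s:listOfCompartments/s:compartment", ns),
    function(nd) {
      size <- xml2::xml_attr(nd, "size")
      wc_compartment(xml2::xml_attr(nd, "id"),
                     name = xml2::xml_attr(nd, "name") %|na|% xml2::xml_attr(nd, "id"),
                     volume = if (is.na(size)) 1e-15 else as.numeric(size))
    })

  internal <- character(0)
  species <- lapply(xml2::xml_find_all(model, "./s:listOfSpecies/s:species", ns),
    function(nd) {
      sid <- xml2::xml_attr(nd, "id")
      bc <- xml2::xml_attr(nd, "boundaryCondition")
      if (identical(bc, "false")) internal <<- c(internal, sid)
      amt <- xml2::xml_attr(nd, "initialAmount")
      wc_species(sid,
                 name = xml2::xml_attr(nd, "name") %|na|% sid,
                 compartment = xml2::xml_attr(nd, "compartment"),
                 initial_count = if (is.na(amt)) 0 else as.numeric(amt))
    })

  params <- list()
  for (nd in xml2::xml_find_all(model, "./s:listOfParameters/s:parameter", ns)) {
    pid <- xml2::xml_attr(nd, "id")
    val <- xml2::xml_attr(nd, "value")
    params[[pid]] <- list(value = if (is.na(val)) NA_real_ else as.numeric(val),
                          constant = !identical(xml2::xml_attr(nd, "constant"), "false"))
  }

  species_ids <- vapply(species, function(s) s$id, character(1))
  reactions <- list()
  lower <- numeric(0)
  upper <- numeric(0)
  for (nd in xml2::xml_find_all(model, "./s:listOfReactions/s:reaction", ns)) {
    parsed <- .parse_reaction(nd, ns, params, species_ids, is_fba = formalism == "FBA")
    for (r in parsed$reactions) reactions[[length(reactions) + 1L]] <- r
    lower <- c(lower, parsed$lower)
    upper <- c(upper, parsed$upper)
  }

  fba <- NULL
  if (formalism == "FBA") {
    objective <- numeric(0)
    for (nd in xml2::xml_find_all(model,
        "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)) {
      objective[xml2::xml_attr(nd, "fbc:reaction", ns = ns)] <-
        as.numeric(xml2::xml_attr(nd, "fbc:coefficient", ns = ns))
    }
    fba <- list(lower = lower, upper = upper, objective = objective,
                internal = internal)
  }

  structure(list(submodel = wc_submodel(id, formalism, species = species,
                                        reactions = reactions, fba = fba),
                 compartments = compartments),
            class = "wc_sbml_submodel")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

.UNSUPPORTED <- c(listOfEvents = "event", listOfRules = "rule",
                  listOfConstraints = "constraint",
                  listOfInitialAssignments = "initialAssignment",
                  listOfFunctionDefinitions = "functionDefinition")

.reject_unsupported <- function(model, ns) {
  for (lst in names(.UNSUPPORTED)) {
    nd <- xml2::xml_find_first(model, paste0("./s:", lst), ns)
    if (!inherits(nd, "xml_missing")) {
      child <- xml2::xml_find_first(nd, "./*")
      cid <- if (!inherits(child, "xml_missing")) xml2::xml_attr(child, "id") else NA
      stop("unsupported SBML construct <", .UNSUPPORTED[[lst]], ">",
           if (!is.na(cid)) paste0(" (id '", cid, "')"),
           ": outside the supported Level 3 core subset", call. = FALSE)
    }
  }
}

.parse_species_refs <- function(rxn, list_name, ns) {
  out <- numeric(0)
  for (nd in xml2::xml_find_all(rxn, paste0("./s:", list_name, "/s:speciesReference"), ns)) {
    st <- xml2::xml_attr(nd, "stoichiometry")
    out[xml2::xml_attr(nd, "species")] <- if (is.na(st)) 1 else as.numeric(st)
  }
  out
}

.parse_reaction <- function(nd, ns, params, species_ids, is_fba = FALSE) {
  rid <- xml2::xml_attr(nd, "id")
  reversible <- identical(xml2::xml_attr(nd, "reversible"), "true")
  reactants <- .parse_species_refs(nd, "listOfReactants", ns)
  products <- .parse_species_refs(nd, "listOfProducts", ns)

  kl <- xml2::xml_find_first(nd, "./s:kineticLaw", ns)
  rate <- 0
  if (!inherits(kl, "xml_missing")) {
    if (!inherits(xml2::xml_find_first(kl, ".//m:csymbol", ns), "xml_missing")) {
      stop("reaction '", rid, "': csymbol (e.g. delay) is outside the supported subset",
           call. = FALSE)
    }
    rate <- .parse_mass_action(kl, ns, params, species_ids, rid)
  }

  lower <- numeric(0)
  upper <- numeric(0)
  if (is_fba) {
    lbp <- xml2::xml_attr(nd, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(nd, "fbc:upperFluxBound", ns = ns)
    if (!is.na(lbp)) lower[rid] <- params[[lbp]]$value
    if (!is.na(ubp)) upper[rid] <- params[[ubp]]$value
  }

  if (reversible) {
    fwd <- wc_reaction(paste0(rid, "_fwd"), reactants, products, rate)
    rev <- wc_reaction(paste0(rid, "_rev"), products, reactants, rate)
    return(list(reactions = list(fwd, rev), lower = lower, upper = upper))
  }
  list(reactions = list(wc_reaction(rid, reactants, products, rate)),
       lower = lower, upper = upper)
}

# Accepts: <ci>param</ci>, <cn>value</cn>, or
# <apply><times/> constant-ci and species factors (ci or power) </apply>.
.parse_mass_action <- function(kl, ns, params, species_ids, rid) {
  math <- xml2::xml_find_first(kl, "./m:math", ns)
  if (inherits(math, "xml_missing")) {
    stop("reaction '", rid, "': kineticLaw has no MathML body", call. = FALSE)
  }
  body <- xml2::xml_find_first(math, "./*")
  law_text <- function() gsub("\\s+", " ", xml2::xml_text(math))
  name <- xml2::xml_name(body)

  lookup_const <- function(pid) {
    p <- params[[pid]]
    if (is.null(p)) {
      stop("reaction '", rid, "': kinetic law references unknown parameter '",
           pid, "'", call. = FALSE)
    }
    if (!p$constant || is.na(p$value)) pid else p$value
  }

  if (name == "ci") return(lookup_const(xml2::xml_text(body)))
  if (name == "cn") return(as.numeric(xml2::xml_text(body)))
  if (name != "apply") {
    stop("reaction '", rid, "': non-mass-action kinetic law: ", law_text(), call. = FALSE)
  }
  kids <- xml2::xml_find_all(body, "./*")
  if (xml2::xml_name(kids[[1]]) != "times") {
    stop("reaction '", rid, "': non-mass-action kinetic law: ", law_text(), call. = FALSE)
  }
  const <- NULL
  for (k in kids[-1]) {
    kn <- xml2::xml_name(k)
    if (kn == "ci") {
      txt <- xml2::xml_text(k)
      if (txt %in% species_ids) next
      if (!is.null(const)) {
        stop("reaction '", rid, "': kinetic law has multiple constants: ",
             law_text(), call. = FALSE)
      }
      const <- lookup_const(txt)
    } else if (kn == "cn") {
      if (!is.null(const)) {
        stop("reaction '", rid, "': kinetic law has multiple constants: ",
             law_text(), call. = FALSE)
      }
      const <- as.numeric(xml2::xml_text(k))
    } else if (kn == "apply") {
      op <- xml2::xml_name(xml2::xml_find_first(k, "./*"))
      base <- xml2::xml_text(xml2::xml_find_first(k, "./m:ci", ns))
      if (op != "power" || !(base %in% species_ids)) {
        stop("reaction '", rid, "': non-mass-action kinetic law: ", law_text(),
             call. = FALSE)
      }
    } else {
      stop("reaction '", rid, "': non-mass-action kinetic law: ", law_text(),
           call. = FALSE)
    }
  }
  if (is.null(const)) {
    stop("reaction '", rid, "': kinetic law has no rate constant: ", law_text(),
         call. = FALSE)
  }
  const
}
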