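#' Define a compartment
#'
#' Compartments are the physical containers (e.g. extracellular space,
#' membrane, cytosol) that species live in. Volumes are carried in liters so
#' concentration-based engines can convert from molecule counts if needed;
#' the simulator itself works on counts throughout.
#'
#' @param id Compartment identifier, unique within a model.
#' @param name Human-readable name. Defaults to `id`.
#' @param volume Compartment volume in liters; must be positive.
#' @return An object of class `wc_compartment`.
#' @export
wc_compartment <- function(id, name = id, volume = 1e-15) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0) {
    stop("compartment '", id, "': volume must be a positive finite number", call. = FALSE)
  }
  structure(list(id = id, name = name, volume = as.numeric(volume)),
            class = "wc_compartment")
}

#' Define a molecular species
#'
#' Species hold non-negative integer molecule counts. After composition into
#' a whole-cell model, species ids are global and unique; the recommended
#' convention is `<name>_<compartment-id>` (e.g. `ATP_c`).
#'
#' @param id Species identifier.
#' @param name Human-readable name. Defaults to `id`.
#' @param compartment Id of the compartment the species lives in.
#' @param initial_count Non-negative integer initial molecule count.
#' @param cross_refs Optional character vector of external database
#'   identifiers, carried opaquely.
#' @return An object of class `wc_species`.
#' @export
wc_species <- function(id, name = id, compartment, initial_count = 0,
                       cross_refs = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(compartment), length(compartment) == 1L)
  structure(list(id = id, name = name, compartment = compartment,
                 initial_count = as.numeric(initial_count),
                 cross_refs = cross_refs),
            class = "wc_species")
}

#' Define an irreversible mass-action reaction
#'
#' All reactions are irreversible; reversible reactions are split into two
#' irreversible halves when read from SBML. The rate constant follows the
#' stochastic combinatorial-count convention documented in [propensity()]:
#' the propensity of the reaction at counts `n` is
#' `c * prod(choose(n_i, s_i))` over its reactants. The same constant drives
#' the deterministic engine through the count-based power law
#' `c * prod(n_i^s_i)`, so the two encodings of a reaction agree in the
#' large-count limit.
#'
#' @param id Reaction identifier, unique within a model.
#' @param reactants Named integer vector: species id -> positive integer
#'   stoichiometry. May be empty (zero-order source reaction).
#' @param products Named integer vector, as `reactants`. May be empty.
#' @param rate_constant Either a non-negative number (per second, for the
#'   count convention above) or the name of a model parameter to resolve at
#'   evaluation time (this is how Boolean rules retune kinetics).
#' @param enabled Logical; disabled reactions have zero propensity/rate.
#'   Boolean rules may toggle this between steps.
#' @return An object of class `wc_reaction`.
#' @export
wc_reaction <- function(id, reactants = numeric(0), products = numeric(0),
                        rate_constant = 0, enabled = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- .check_stoich(reactants, id, "reactant")
  products <- .check_stoich(products, id, "product")
  if (is.character(rate_constant)) {
    stopifnot(length(rate_constant) == 1L, nzchar(rate_constant))
  } else {
    stopifnot(is.numeric(rate_constant), length(rate_constant) == 1L)
    if (!is.finite(rate_constant) || rate_constant < 0) {
      stop("reaction '", id, "': rate constant must be finite and >= 0", call. = FALSE)
    }
  }
  structure(list(id = id, reactants = reactants, products = products,
                 rate_constant = rate_constant, enabled = isTRUE(enabled)),
            class = "wc_reaction")
}

.check_stoich <- function(x, rxn_id, side) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction '", rxn_id, "': ", side, " stoichiometries must be named by species id",
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("reaction '", rxn_id, "': duplicate ", side, " species", call. = FALSE)
  }
  x <- vapply(x, as.numeric, numeric(1))
  if (any(!is.finite(x)) || any(x <= 0) || any(x != round(x))) {
    stop("reaction '", rxn_id, "': ", side, " stoichiometries must be positive integers",
         call. = FALSE)
  }
  x
}

#' Supported submodel formalisms
#' @export
WC_FORMALISMS <- c("SSA", "ODE", "FBA", "BOOLEAN")

#' Define a pathway submodel
#'
#' A submodel is one pathway-level component model in a single mathematical
#' formalism. SSA and ODE submodels carry mass-action reactions; FBA
#' submodels additionally carry flux bounds, an objective, and the set of
#' internal (steady-state) metabolites; Boolean submodels carry regulatory
#' rules (see [boolean_rule()]).
#'
#' @param id Submodel identifier.
#' @param formalism One of `"SSA"`, `"ODE"`, `"FBA"`, `"BOOLEAN"`.
#' @param species List of [wc_species()] the submodel declares locally.
#' @param reactions List of [wc_reaction()] (SSA/ODE/FBA).
#' @param fba For FBA submodels, a list with elements `lower` and `upper`
#'   (named per-reaction flux bounds, molecules per second), `objective`
#'   (named per-reaction maximization coefficients) and `internal`
#'   (character vector of species ids held at steady state, contributing no
#'   species deltas).
#' @param rules For Boolean submodels, a list of [boolean_rule()].
#' @param interface_species Character vector of species ids the submodel
#'   reads/writes; defaults to all species referenced by its payload.
#' @return An object of class `wc_submodel`.
#' @export
wc_submodel <- function(id, formalism, species = list(), reactions = list(),
                        fba = NULL, rules = NULL, interface_species = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  formalism <- match.arg(formalism, WC_FORMALISMS)
  stopifnot(is.list(species), is.list(reactions))
  if (formalism == "FBA" && is.null(fba)) {
    stop("submodel '", id, "': FBA formalism requires an fba payload", call. = FALSE)
  }
  if (formalism == "BOOLEAN" && is.null(rules)) {
    stop("submodel '", id, "': BOOLEAN formalism requires a rules payload", call. = FALSE)
  }
  if (formalism %in% c("SSA", "ODE") && length(reactions) == 0L && length(species) == 0L) {
    # allowed: degenerate empty submodel (round-trip fixture); no error
  }
  if (!is.null(fba)) {
    fba$lower <- .named_numeric(fba$lower)
    fba$upper <- .named_numeric(fba$upper)
    fba$objective <- .named_numeric(fba$objective)
    fba$internal <- as.character(fba$internal %||% character(0))
  }
  if (is.null(interface_species)) {
    interface_species <- .payload_species(reactions, rules, species)
  }
  structure(list(id = id, formalism = formalism, species = species,
                 reactions = reactions, fba = fba, rules = rules,
                 interface_species = sort(unique(interface_species))),
            class = "wc_submodel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.named_numeric <- function(x) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

.payload_species <- function(reactions, rules, species) {
  out <- vapply(species, function(s) s$id, character(1))
  for (r in reactions) out <- c(out, names(r$reactants), names(r$products))
  unique(out)
}

#' Compose a whole-cell model
#'
#' Usually produced by [merge_shared_species()] or [read_manifest()] rather
#' than called directly. The global species set is the union of all
#' submodels' species under an explicit local-to-global identity mapping.
#'
#' @param compartments List of [wc_compartment()].
#' @param species List of [wc_species()] with globally unique ids.
#' @param submodels List of [wc_submodel()] whose payloads reference global
#'   species ids.
#' @param parameters Named numeric vector of model parameters (referenced by
#'   name from rate constants and Boolean rules).
#' @return An object of class `wc_model`.
#' @export
wc_model <- function(compartments = list(), species = list(),
                     submodels = list(), parameters = numeric(0)) {
  structure(list(compartments = compartments, species = species,
                 submodels = submodels,
                 parameters = .named_numeric(as.list(parameters))),
            class = "wc_model")
}

#' @export
print.wc_model <- function(x, ...) {
  cat("Whole-cell model:", length(x$compartments), "compartments,",
      length(x$species), "global species,", length(x$submodels), "submodels\n")
  for (sm in x$submodels) {
    cat(sprintf("  %-20s [%s]  %d reactions, %d interface species\n",
                sm$id, sm$formalism, length(sm$reactions),
                length(sm$interface_species)))
  }
  invisible(x)
}

species_ids <- function(model) vapply(model$species, function(s) s$id, character(1))

initial_counts <- function(model) {
  stats::setNames(vapply(model$species, function(s) s$initial_count, numeric(1)),
                  species_ids(model))
}

model_reactions <- function(model) {
  out <- list()
  for (sm in model$submodels) for (r in sm$reactions) out[[length(out) + 1L]] <- r
  out
}

#' Validate a whole-cell model
#'
#' Checks every structural invariant: unique ids, positive volumes,
#' non-negative integer initial counts, reactions referencing only existing
#' species, formalism payloads present and well-formed, interface sets
#' contained in the global species set, and Boolean rules referring only to
#' existing targets. Validation is side-effect free and idempotent.
#'
#' @param model A [wc_model()].
#' @return An object of class `wc_validation`: a list with character vectors
#'   `errors` and `warnings`. The model satisfies all invariants iff
#'   `length(errors) == 0`.
#' @export
validate_model <- function(model) {
  errors <- character(0)
  warnings <- character(0)
  err <- function(...) errors[[length(errors) + 1L]] <<- paste0(...)

  comp_ids <- vapply(model$compartments, function(x) x$id, character(1))
  if (anyDuplicated(comp_ids)) {
    err("duplicate compartment ids: ",
        paste(unique(comp_ids[duplicated(comp_ids)]), collapse = ", "),
        " [compartment-id-unique]")
  }
  for (cmp in model$compartments) {
    if (!is.finite(cmp$volume) || cmp$volume <= 0) {
      err("compartment '", cmp$id, "': volume must be > 0 [compartment-volume-positive]")
    }
  }

  sp_ids <- species_ids(model)
  if (anyDuplicated(sp_ids)) {
    err("duplicate global species ids: ",
        paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", "),
        " [species-id-unique]")
  }
  for (sp in model$species) {
    if (!(sp$compartment %in% comp_ids)) {
      err("species '", sp$id, "': unknown compartment '", sp$compartment,
          "' [species-compartment-exists]")
    }
    if (!is.finite(sp$initial_count) || sp$initial_count < 0 ||
        sp$initial_count != round(sp$initial_count)) {
      err("species '", sp$id,
          "': initial_count must be a non-negative integer [species-count-nonnegative]")
    }
  }

  rxn_ids <- character(0)
  for (sm in model$submodels) {
    if (!(sm$formalism %in% WC_FORMALISMS)) {
      err("submodel '", sm$id, "': unknown formalism '", sm$formalism,
          "' [submodel-formalism]")
      next
    }
    extra <- setdiff(sm$interface_species, sp_ids)
    if (length(extra)) {
      err("submodel '", sm$id, "': interface species not in global set: ",
          paste(extra, collapse = ", "), " [interface-subset]")
    }
    for (r in sm$reactions) {
      rxn_ids <- c(rxn_ids, r$id)
      unknown <- setdiff(c(names(r$reactants), names(r$products)), sp_ids)
      for (u in unknown) {
        err("reaction '", r$id, "': references unknown species '", u,
            "' [reaction-species-exists]")
      }
      if (is.character(r$rate_constant) &&
          !(r$rate_constant %in% names(model$parameters))) {
        err("reaction '", r$id, "': rate parameter '", r$rate_constant,
            "' not in model parameters [reaction-rate-parameter]")
      }
      if (is.numeric(r$rate_constant) && r$rate_constant < 0) {
        err("reaction '", r$id, "': rate constant < 0 [reaction-rate-nonnegative]")
      }
    }
    if (sm$formalism == "FBA") {
      errors <- c(errors, .validate_fba_payload(sm, sp_ids))
    }
    if (sm$formalism == "BOOLEAN") {
      errors <- c(errors, .validate_rules_payload(sm, model, sp_ids))
    }
  }
  if (anyDuplicated(rxn_ids)) {
    err("duplicate reaction ids across submodels: ",
        paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
        " [reaction-id-unique]")
  }

  structure(list(errors = errors, warnings = warnings), class = "wc_validation")
}

.validate_fba_payload <- function(sm, sp_ids) {
  errors <- character(0)
  rids <- vapply(sm$reactions, function(r) r$id, character(1))
  bad_bounds <- intersect(names(sm$fba$lower), names(sm$fba$upper))
  for (rid in bad_bounds) {
    if (sm$fba$lower[[rid]] > sm$fba$upper[[rid]]) {
      errors <- c(errors, paste0("submodel '", sm$id, "': reaction '", rid,
                                 "' has lower bound > upper bound [fba-bounds-ordered]"))
    }
  }
  unknown <- setdiff(c(names(sm$fba$lower), names(sm$fba$upper),
                       names(sm$fba$objective)), rids)
  if (length(unknown)) {
    errors <- c(errors, paste0("submodel '", sm$id,
                               "': fba bounds/objective name unknown reactions: ",
                               paste(unique(unknown), collapse = ", "),
                               " [fba-reaction-exists]"))
  }
  missing_internal <- setdiff(sm$fba$internal, sp_ids)
  if (length(missing_internal)) {
    errors <- c(errors, paste0("submodel '", sm$id,
                               "': fba internal species not in global set: ",
                               paste(missing_internal, collapse = ", "),
                               " [fba-internal-exists]"))
  }
  errors
}

.validate_rules_payload <- function(sm, model, sp_ids) {
  errors <- character(0)
  all_rxn_ids <- vapply(model_reactions(model), function(r) r$id, character(1))
  for (rule in sm$rules) {
    idents <- tryCatch(condition_identifiers(rule$condition), error = function(e) NULL)
    if (is.null(idents)) {
      errors <- c(errors, paste0("rule '", rule$id,
                                 "': condition does not parse under the rule grammar",
                                 " [rule-grammar]"))
      next
    }
    unknown <- setdiff(idents, c(sp_ids, names(model$parameters)))
    if (length(unknown)) {
      errors <- c(errors, paste0("rule '", rule$id,
                                 "': condition references unknown identifiers: ",
                                 paste(unknown, collapse = ", "), " [rule-identifiers]"))
    }
    eff <- rule$effect
    if (!is.null(eff$parameter) && !(eff$parameter %in% names(model$parameters))) {
      errors <- c(errors, paste0("rule '", rule$id, "': effect targets unknown parameter '",
                                 eff$parameter, "' [rule-target-exists]"))
    }
    if (!is.null(eff$reaction) && !(eff$reaction %in% all_rxn_ids)) {
      errors <- c(errors, paste0("rule '", rule$id, "': effect targets unknown reaction '",
                                 eff$reaction, "' [rule-target-exists]"))
    }
  }
  errors
}

#' @export
print.wc_validation <- function(x, ...) {
  if (length(x$errors) == 0L) {
    cat("Model is valid.\n")
  } else {
    cat("Model has", length(x$errors), "error(s):\n")
    for (e in x$errors) cat("  -", e, "\n")
  }
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Merge submodels into a whole-cell model over shared global species
#'
#' Realizes the composition scheme: the global species set is the union of
#' all submodel species under an explicit (submodel, local id) -> global id
#' mapping. Mapping is never inferred from name matching; every local
#' species must be mapped. Two local species mapped to the same global id
#' must sit in the same compartment. Initial counts come from the
#' composition manifest (the `global_counts` argument), never from the
#' per-submodel files, which resolves conflicting per-submodel initial
#' values by a single precedence rule.
#'
#' @param submodels List of [wc_submodel()] with local species ids.
#' @param mapping Named list: `mapping[[submodel_id]]` is a named character
#'   vector mapping local species id -> global species id.
#' @param compartments List of [wc_compartment()] for the composed model.
#' @param global_counts Named numeric vector of initial counts per global
#'   species id; unlisted species start at 0.
#' @param parameters Named numeric vector of model parameters.
#' @return A composed [wc_model()] (not yet validated; run
#'   [validate_model()]).
#' @export
merge_shared_species <- function(submodels, mapping, compartments,
                                 global_counts = numeric(0),
                                 parameters = numeric(0)) {
  global <- list()   # global id -> wc_species
  out_submodels <- list()
  for (sm in submodels) {
    map <- mapping[[sm$id]]
    local_ids <- vapply(sm$species, function(s) s$id, character(1))
    if (is.null(map)) {
      if (length(local_ids)) {
        stop("composition error: no species mapping for submodel '", sm$id, "'",
             call. = FALSE)
      }
      map <- stats::setNames(character(0), character(0))
    }
    unmapped <- setdiff(local_ids, names(map))
    if (length(unmapped)) {
      stop("composition error: submodel '", sm$id, "' has unmapped local species: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    for (sp in sm$species) {
      gid <- unname(map[[sp$id]])
      if (!is.null(global[[gid]])) {
        if (!identical(global[[gid]]$compartment, sp$compartment)) {
          stop("composition error: global species '", gid,
               "' mapped from compartment '", sp$compartment,
               "' by submodel '", sm$id, "' but previously placed in '",
               global[[gid]]$compartment, "'", call. = FALSE)
        }
      } else {
        global[[gid]] <- wc_species(gid, name = sp$name,
                                    compartment = sp$compartment,
                                    initial_count = 0,
                                    cross_refs = sp$cross_refs)
      }
    }
    out_submodels[[length(out_submodels) + 1L]] <- .relabel_submodel(sm, map)
  }

  extra <- setdiff(names(global_counts), names(global))
  if (length(extra)) {
    stop("composition error: initial counts given for species no submodel declares: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (gid in names(global_counts)) {
    global[[gid]]$initial_count <- as.numeric(global_counts[[gid]])
  }

  wc_model(compartments = compartments,
           species = unname(global[order(names(global))]),
           submodels = out_submodels,
           parameters = parameters)
}

.relabel_submodel <- function(sm, map) {
  relabel <- function(v) {
    if (length(v) == 0L) return(v)
    stats::setNames(v, unname(map[names(v)]))
  }
  reactions <- lapply(sm$reactions, function(r) {
    r$reactants <- relabel(r$reactants)
    r$products <- relabel(r$products)
    r
  })
  species <- lapply(sm$species, function(sp) {
    sp$id <- unname(map[[sp$id]])
    sp
  })
  fba <- sm$fba
  if (!is.null(fba)) fba$internal <- unname(map[fba$internal])
  wc_submodel(sm$id, sm$formalism, species = species, reactions = reactions,
              fba = fba, rules = sm$rules,
              interface_species = unname(map[vapply(sm$species, function(s) s$id,
                                                    character(1))]))
}
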