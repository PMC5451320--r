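# Composition manifest: the explicit replacement for SBML hierarchical
# composition / SED-ML shared variables. Each submodel file stays valid
# standalone SBML; the manifest declares the formalism of each submodel,
# the local-to-global species identity mapping (never inferred by name
# matching), the global initial counts, the model parameters, and the
# Boolean rule list.

#' Build a composition manifest object
#'
#' @param submodels List of [wc_submodel()] with local species ids
#'   (Boolean submodels carry their rules here, not in SBML).
#' @param mapping Named list of named character vectors: local -> global
#'   species id per submodel. Boolean submodels may be omitted.
#' @param compartments List of [wc_compartment()].
#' @param initial_counts Named numeric vector of global initial counts.
#' @param parameters Named numeric vector of model parameters.
#' @return An object of class `wc_manifest`.
#' @export
wc_manifest <- function(submodels, mapping, compartments,
                        initial_counts = numeric(0), parameters = numeric(0)) {
  structure(list(submodels = submodels, mapping = mapping,
                 compartments = compartments,
                 initial_counts = initial_counts, parameters = parameters),
            class = "wc_manifest")
}

#' Compose the whole-cell model described by a manifest
#'
#' @param manifest A [wc_manifest()].
#' @return A composed [wc_model()].
#' @export
compose_model <- function(manifest) {
  merge_shared_species(manifest$submodels, manifest$mapping,
                       manifest$compartments,
                       global_counts = manifest$initial_counts,
                       parameters = manifest$parameters)
}

#' Write a manifest and its submodel SBML files to a directory
#'
#' Writes one standalone SBML file per non-Boolean submodel plus
#' `manifest.yml` (or `.json`). The directory round-trips through
#' [read_manifest()].
#'
#' @param manifest A [wc_manifest()].
#' @param dir Output directory (created if missing).
#' @param format `"yaml"` (default) or `"json"`.
#' @return The manifest file path, invisibly.
#' @export
write_manifest <- function(manifest, dir, format = c("yaml", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (sm in manifest$submodels) {
    if (identical(sm$formalism, "BOOLEAN")) {
      entries[[length(entries) + 1L]] <- list(
        id = sm$id, formalism = "BOOLEAN",
        rules = lapply(sm$rules, function(r) {
          eff <- r$effect
          list(id = r$id, condition = r$condition, effect = eff)
        }))
    } else {
      file <- paste0(sm$id, ".xml")
      write_submodel_sbml(sm, manifest$compartments, file.path(dir, file))
      map <- manifest$mapping[[sm$id]]
      entries[[length(entries) + 1L]] <- list(
        id = sm$id, formalism = sm$formalism, file = file,
        species_map = as.list(map))
    }
  }
  body <- list(submodels = entries,
               initial_counts = as.list(manifest$initial_counts),
               parameters = as.list(manifest$parameters))
  path <- file.path(dir, paste0("manifest.", if (format == "yaml") "yml" else "json"))
  if (format == "yaml") {
    yaml::write_yaml(body, path)
  } else {
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a composition manifest and compose the whole-cell model
#'
#' Parses the manifest (YAML or JSON by extension), loads every referenced
#' SBML submodel file, applies the declared species mappings, and returns
#' the composed model, which must pass [validate_model()].
#'
#' @param path Path to `manifest.yml` / `manifest.yaml` / `manifest.json`.
#' @return A composed [wc_model()] with the parsed [wc_manifest()] attached
#'   as attribute `"manifest"`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop("manifest must be .yml/.yaml or .json: ", path, call. = FALSE)
  }
  base <- dirname(path)

  submodels <- list()
  mapping <- list()
  compartments <- list()
  for (entry in raw$submodels) {
    frm <- entry$formalism
    if (is.null(frm) || !(frm %in% WC_FORMALISMS)) {
      stop("manifest schema error: submodel '", entry$id %||% "?",
           "' has unknown formalism '", frm %||% "<missing>", "'", call. = FALSE)
    }
    if (frm == "BOOLEAN") {
      rules <- lapply(entry$rules, function(r)
        boolean_rule(r$id, r$condition, r$effect))
      submodels[[length(submodels) + 1L]] <-
        wc_submodel(entry$id, "BOOLEAN", rules = rules)
      next
    }
    file <- file.path(base, entry$file)
    if (!file.exists(file)) {
      stop("manifest error: submodel '", entry$id, "' file not found: ", file,
           call. = FALSE)
    }
    parsed <- read_submodel_sbml(file, formalism = frm, id = entry$id)
    submodels[[length(submodels) + 1L]] <- parsed$submodel
    map <- unlist(entry$species_map)
    mapping[[entry$id]] <- stats::setNames(as.character(map), names(map))
    for (cmp in parsed$compartments) {
      prev <- compartments[[cmp$id]]
      if (!is.null(prev) && abs(prev$volume - cmp$volume) > 1e-12 * prev$volume) {
        stop("composition error: compartment '", cmp$id,
             "' has conflicting volumes across submodel files", call. = FALSE)
      }
      compartments[[cmp$id]] <- cmp
    }
  }

  manifest <- wc_manifest(
    submodels, mapping, unname(compartments),
    initial_counts = unlist(raw$initial_counts) %||% numeric(0),
    parameters = unlist(raw$parameters) %||% numeric(0))
  model <- compose_model(manifest)
  rep_v <- validate_model(model)
  if (length(rep_v$errors)) {
    stop("composed model fails validation:\n  ",
         paste(rep_v$errors, collapse = "\n  "), call. = FALSE)
  }
  attr(model, "manifest") <- manifest
  model
}

#' Write a trajectory to disk
#'
#' CSV layout: a header line `time` followed by the global species ids,
#' then one row per recorded output point, with integer counts stored
#' losslessly. Per-step diagnostics (step length, scaled species count,
#' retries) go to a `<path>.diagnostics.csv` sidecar when requested.
#'
#' @param trajectory A `wc_trajectory`.
#' @param path Output file path.
#' @param format Only `"csv"` is supported.
#' @param diagnostics Also write the sidecar diagnostics CSV?
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("csv", "hdf5"),
                             diagnostics = FALSE) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("format 'hdf5' is not supported by this build; use 'csv'", call. = FALSE)
  }
  df <- as.data.frame(trajectory)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (diagnostics) {
    utils::write.csv(trajectory$diagnostics,
                     paste0(path, ".diagnostics.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return A list with `times` and `counts` (matrix with species columns).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- NULL
  list(times = df$time, counts = counts)
}
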