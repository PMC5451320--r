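#' Stochastic propensity of a mass-action reaction
#'
#' Uses the combinatorial-count convention: the propensity is
#' `a = c * prod(choose(n_i, s_i))` over reactants, the number of distinct
#' reactant combinations times the stochastic rate constant. A reaction
#' with no reactants (a source) has propensity `c`. The propensity is zero
#' when any reactant count is below its stoichiometry or the reaction is
#' disabled. Rate constants calibrated under the permutation convention
#' (with `s_i!` factors) must be divided by `prod(factorial(s_i))` before
#' use here.
#'
#' @param reaction A [wc_reaction()].
#' @param counts Named numeric vector of current molecule counts covering
#'   all reactants.
#' @param parameters Named numeric vector used to resolve parameter-valued
#'   rate constants.
#' @return Propensity in events per second (non-negative scalar).
#' @export
propensity <- function(reaction, counts, parameters = numeric(0)) {
  if (!reaction$enabled) return(0)
  c0 <- resolve_rate(reaction, parameters)
  s <- reaction$reactants
  if (length(s) == 0L) return(c0)
  n <- counts[names(s)]
  if (anyNA(n)) {
    stop("propensity: counts missing for reactant(s) ",
         paste(names(s)[is.na(n)], collapse = ", "), " of reaction '",
         reaction$id, "'", call. = FALSE)
  }
  if (any(n < 0)) {
    stop("state corruption: negative count for reactant of reaction '",
         reaction$id, "'", call. = FALSE)
  }
  a <- c0 * prod(choose(n, s))
  if (!is.finite(a)) {
    stop("propensity overflow in reaction '", reaction$id, "'", call. = FALSE)
  }
  a
}

resolve_rate <- function(reaction, parameters) {
  k <- reaction$rate_constant
  if (is.character(k)) {
    if (!(k %in% names(parameters))) {
      stop("reaction '", reaction$id, "': rate parameter '", k, "' not defined",
           call. = FALSE)
    }
    k <- parameters[[k]]
  }
  k
}

#' Build a change request
#'
#' A change request is a submodel's proposed per-species integer deltas for
#' one time step (negative = consumption), subject to central arbitration.
#' Zero deltas are dropped.
#'
#' @param submodel_id Id of the requesting submodel.
#' @param deltas Named numeric vector of integer-valued deltas.
#' @param diagnostics List of engine diagnostics (e.g. `n_events`,
#'   `infeasible`).
#' @return An object of class `wc_request`.
#' @export
change_request <- function(submodel_id, deltas = numeric(0), diagnostics = list()) {
  deltas <- deltas[deltas != 0]
  if (length(deltas) && any(deltas != round(deltas))) {
    stop("change request from '", submodel_id, "' has non-integer deltas", call. = FALSE)
  }
  structure(list(submodel = submodel_id, deltas = deltas,
                 diagnostics = diagnostics),
            class = "wc_request")
}

#' Advance an SSA submodel over one controller step
#'
#' Gillespie direct method on a private copy of the snapshot counts:
#' exponential waiting times at the total propensity, reaction choice
#' proportional to individual propensities. Events are simulated until the
#' next firing time would exceed `dt`; that straddling event is discarded,
#' so the returned request is attributable entirely to `[t, t + dt)`. The
#' snapshot itself is never modified.
#'
#' @param snapshot A [wc_snapshot()] (read-only input state).
#' @param submodel An SSA [wc_submodel()].
#' @param dt Step length in seconds (> 0).
#' @param seed Integer substream seed (see the per-submodel stream
#'   convention in [wc_simulate()]).
#' @return A list of class `wc_ssa_result`: `request` ([change_request()]),
#'   `n_events` (number of reaction firings), and `final_local_time`
#'   (local time of the last accepted event, <= dt).
#' @export
ssa_advance <- function(snapshot, submodel, dt, seed) {
  stopifnot(identical(submodel$formalism, "SSA"), dt > 0)
  counts <- snapshot$counts
  params <- snapshot$parameters
  rxns <- submodel$reactions
  n_events <- 0L
  t_local <- 0
  last_t <- 0
  deltas <- stats::setNames(numeric(length(submodel$interface_species)),
                            submodel$interface_species)
  with_stream(seed, {
    repeat {
      a <- vapply(rxns, propensity, numeric(1), counts = counts, parameters = params)
      a0 <- sum(a)
      if (a0 <= 0) break
      tau <- -log(stats::runif(1)) / a0
      if (t_local + tau > dt) break   # straddling event discarded
      t_local <- t_local + tau
      last_t <- t_local
      j <- min(findInterval(stats::runif(1) * a0, cumsum(a)) + 1L, length(rxns))
      r <- rxns[[j]]
      if (length(r$reactants)) {
        counts[names(r$reactants)] <- counts[names(r$reactants)] - r$reactants
        deltas[names(r$reactants)] <- deltas[names(r$reactants)] - r$reactants
      }
      if (length(r$products)) {
        counts[names(r$products)] <- counts[names(r$products)] + r$products
        deltas[names(r$products)] <- deltas[names(r$products)] + r$products
      }
      n_events <- n_events + 1L
    }
  })
  structure(list(request = change_request(submodel$id, deltas,
                                          diagnostics = list(n_events = n_events)),
                 n_events = n_events,
                 final_local_time = last_t),
            class = "wc_ssa_result")
}
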