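#' Deterministic mass-action net rates
#'
#' Count-based rate law: each enabled reaction contributes
#' `c * prod(n_i^s_i)` (molecules per second) times its stoichiometry to the
#' net rate of every species it touches. Using counts rather than
#' concentrations means an SSA and an ODE encoding of the same reaction
#' agree in the large-count limit without any unit conversion; compartment
#' volumes therefore do not enter the rate law.
#'
#' @param counts Named numeric vector of molecule counts.
#' @param reactions List of [wc_reaction()].
#' @param parameters Named numeric vector for parameter-valued rate
#'   constants.
#' @return Named numeric vector of net rates (molecules per second) over
#'   every species referenced by the reactions.
#' @export
net_rates <- function(counts, reactions, parameters = numeric(0)) {
  touched <- unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  rates <- stats::setNames(numeric(length(touched)), touched)
  for (r in reactions) {
    if (!r$enabled) next
    k <- resolve_rate(r, parameters)
    v <- k
    if (length(r$reactants)) {
      n <- pmax(counts[names(r$reactants)], 0)
      v <- k * prod(n ^ r$reactants)
    }
    if (v == 0) next
    if (length(r$reactants)) {
      rates[names(r$reactants)] <- rates[names(r$reactants)] - v * r$reactants
    }
    if (length(r$products)) {
      rates[names(r$products)] <- rates[names(r$products)] + v * r$products
    }
  }
  rates
}

#' Advance an ODE submodel over one controller step
#'
#' Integrates the submodel's mass-action rate equations over `[0, dt]` with
#' the classical fixed-substep fourth-order Runge-Kutta method (via
#' \pkg{deSolve}), using at least `ceiling(dt / h_max)` substeps. The
#' continuous per-species delta plus the residual carried over from the
#' previous step is rounded to the nearest integer; the new fractional
#' residual (always in (-1, 1)) is returned for the next step. Over any run
#' of steps the summed integer deltas therefore differ from the summed
#' continuous deltas by less than one molecule per species. If rounding
#' would drive the submodel's private copy of a count negative, the delta
#' is clipped at the available amount and the residual reset to zero.
#'
#' @param snapshot A [wc_snapshot()].
#' @param submodel An ODE [wc_submodel()].
#' @param dt Step length in seconds (> 0).
#' @param carry Named numeric vector of per-species fractional residuals
#'   from the previous step (missing species start at 0).
#' @param h_max Maximum RK4 substep length; defaults to `dt / 10`.
#' @return List with `request` ([change_request()]) and `carry` (updated
#'   residual vector).
#' @export
ode_advance <- function(snapshot, submodel, dt, carry = numeric(0),
                        h_max = dt / 10) {
  stopifnot(identical(submodel$formalism, "ODE"), dt > 0)
  sp <- submodel$interface_species
  y0 <- snapshot$counts[sp]
  if (anyNA(y0)) {
    stop("ode_advance: snapshot missing counts for ",
         paste(sp[is.na(y0)], collapse = ", "), call. = FALSE)
  }
  names(y0) <- sp
  params <- snapshot$parameters
  rxns <- submodel$reactions

  n_sub <- max(1L, as.integer(ceiling(dt / h_max - 1e-12)))
  deriv <- function(t, y, parms) {
    r <- net_rates(y, rxns, params)
    dy <- stats::setNames(numeric(length(y)), names(y))
    dy[names(r)] <- r
    list(unname(dy))
  }
  sol <- deSolve::rk4(y = y0, times = seq(0, dt, length.out = n_sub + 1L),
                      func = deriv, parms = NULL)
  yT <- sol[nrow(sol), -1]
  if (any(!is.finite(yT))) {
    stop("ode_advance: non-finite state for species ",
         paste(sp[!is.finite(yT)], collapse = ", "), " in submodel '",
         submodel$id, "'", call. = FALSE)
  }
  cont <- as.numeric(yT) - as.numeric(y0)
  names(cont) <- sp

  resid <- stats::setNames(numeric(length(sp)), sp)
  present <- intersect(names(carry), sp)
  resid[present] <- carry[present]

  x <- cont + resid
  d_int <- round(x)
  new_resid <- x - d_int
  clip <- (y0 + d_int) < 0
  if (any(clip)) {
    d_int[clip] <- -y0[clip]
    new_resid[clip] <- 0
  }
  list(request = change_request(submodel$id, d_int),
       carry = new_resid)
}
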