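# Dynamic FBA engine: each step, build a linear program whose exchange
# bounds are tightened by current pool availability, maximize the
# objective, and convert boundary fluxes to an integer change request.

# Cap used for infinite bounds when handing the LP to the solver; an
# optimum pressed against this cap is reported as unbounded.
.FBA_BIG <- 1e12

#' Build the per-step FBA linear program
#'
#' Internal metabolites (those listed in the submodel's `fba$internal`) are
#' held at steady state: `S_internal %*% v = 0`. All other interface
#' species are boundary species exchanged with the global pool. Static flux
#' bounds are tightened by availability: a reaction consuming boundary
#' species `s` with stoichiometry `k` cannot run faster than
#' `n_s / (k * dt)`, and an aggregate constraint additionally limits the
#' total consumption of each boundary species to `n_s / dt`, so an FBA
#' request alone can never overdraw a pool.
#'
#' @param snapshot A [wc_snapshot()].
#' @param submodel An FBA [wc_submodel()].
#' @param dt Step length in seconds (> 0).
#' @return An object of class `wc_fba_problem`: stoichiometry blocks
#'   (`S_internal`, `S_boundary`), tightened `lower`/`upper` bounds,
#'   availability constraint rows (`A_avail`, `b_avail`), and the
#'   maximization `objective`.
#' @export
build_fba_problem <- function(snapshot, submodel, dt) {
  stopifnot(identical(submodel$formalism, "FBA"), dt > 0)
  rxns <- submodel$reactions
  rids <- vapply(rxns, function(r) r$id, character(1))
  sp <- submodel$interface_species
  internal <- intersect(submodel$fba$internal, sp)
  boundary <- setdiff(sp, internal)

  S <- matrix(0, nrow = length(sp), ncol = length(rxns),
              dimnames = list(sp, rids))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    if (length(r$reactants)) S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    if (length(r$products)) S[names(r$products), j] <- S[names(r$products), j] + r$products
  }

  lower <- stats::setNames(rep(0, length(rids)), rids)
  upper <- stats::setNames(rep(Inf, length(rids)), rids)
  lower[names(submodel$fba$lower)] <- submodel$fba$lower
  upper[names(submodel$fba$upper)] <- submodel$fba$upper
  # disabled reactions are pinned to zero flux
  for (j in seq_along(rxns)) {
    if (!rxns[[j]]$enabled) {
      lower[j] <- 0
      upper[j] <- 0
    }
  }

  counts <- snapshot$counts
  # per-reaction tightening by availability of each consumed boundary species
  for (s in boundary) {
    n_s <- counts[[s]]
    for (j in seq_along(rids)) {
      k <- -S[s, j]
      if (k > 0) upper[j] <- min(upper[j], n_s / (k * dt))
    }
  }
  # aggregate availability rows: total consumption of s <= n_s / dt
  A_avail <- NULL
  b_avail <- numeric(0)
  for (s in boundary) {
    cons <- pmax(-S[s, ], 0)
    if (any(cons > 0)) {
      A_avail <- rbind(A_avail, cons)
      b_avail <- c(b_avail, counts[[s]] / dt)
    }
  }

  objective <- stats::setNames(rep(0, length(rids)), rids)
  objective[names(submodel$fba$objective)] <- submodel$fba$objective

  structure(list(S_internal = S[internal, , drop = FALSE],
                 S_boundary = S[boundary, , drop = FALSE],
                 lower = lower, upper = upper,
                 A_avail = A_avail, b_avail = b_avail,
                 objective = objective,
                 reactions = rids,
                 internal_species = internal,
                 boundary_species = boundary),
            class = "wc_fba_problem")
}

#' Solve an FBA linear program
#'
#' Maximizes the objective subject to internal steady state, availability
#' rows, and flux bounds. Degenerate optima are possible: the flux vector
#' is solver-dependent, but the objective value is unique and is the only
#' quantity downstream code relies on. Infeasible and unbounded problems
#' are reported in `status`, never as silent zeros.
#'
#' @param problem A `wc_fba_problem` from [build_fba_problem()].
#' @return An object of class `wc_fba_solution`: `fluxes` (named, molecules
#'   per second), `objective_value`, `status` in
#'   `{"optimal", "infeasible", "unbounded"}`.
#' @export
solve_lp <- function(problem) {
  rids <- problem$reactions
  lb <- problem$lower
  ub <- problem$upper
  if (any(lb > ub + 1e-12)) {
    return(.fba_solution(rids, status = "infeasible"))
  }
  ubc <- pmin(ub, .FBA_BIG)
  # shift x = v - lb so the solver's x >= 0 convention applies
  span <- ubc - lb
  Aeq <- problem$S_internal
  A <- problem$A_avail
  cc <- unname(problem$objective)

  args <- list(cc = cc, maximize = TRUE, maxiter = 1000L, bigM = 1e7)
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    args$Aeq <- unname(Aeq)
    args$beq <- as.numeric(-Aeq %*% lb)
  }
  ineqA <- rbind(if (!is.null(A)) unname(A), diag(length(rids)))
  ineqb <- c(if (!is.null(A)) problem$b_avail - as.numeric(A %*% lb), unname(span))
  args$A <- ineqA
  args$b <- ineqb

  res <- tryCatch(do.call(pracma::linprog, args), error = function(e) NULL)
  if (is.null(res) || is.null(res$errno) || res$errno != 1 || anyNA(res$x)) {
    return(.fba_solution(rids, status = "infeasible"))
  }
  v <- lb + res$x
  obj <- sum(problem$objective * v)
  if (any(ub > .FBA_BIG & v > .FBA_BIG * 0.99) || obj > .FBA_BIG * 0.99) {
    return(.fba_solution(rids, status = "unbounded"))
  }
  structure(list(fluxes = stats::setNames(v, rids),
                 objective_value = obj, status = "optimal"),
            class = "wc_fba_solution")
}

.fba_solution <- function(rids, status) {
  structure(list(fluxes = stats::setNames(rep(NA_real_, length(rids)), rids),
                 objective_value = NA_real_, status = status),
            class = "wc_fba_solution")
}

#' Advance an FBA submodel over one controller step
#'
#' Solves the availability-tightened LP and converts the optimal boundary
#' fluxes to integer species deltas (`flux * dt`, rounded with a persistent
#' per-species residual carry, as in [ode_advance()]). Internal metabolites
#' are at steady state and contribute no deltas. An infeasible or unbounded
#' LP degrades to a zero request with a diagnostic flag: metabolism halts
#' for the step, the simulation continues.
#'
#' @param snapshot A [wc_snapshot()].
#' @param submodel An FBA [wc_submodel()].
#' @param dt Step length in seconds (>= 0); `dt = 0` yields a zero request.
#' @param carry Named numeric vector of fractional residuals.
#' @return List with `request` ([change_request()]; diagnostics carry
#'   `status` and `infeasible`), `carry`, and `solution`
#'   (the [solve_lp()] result, or NULL when `dt = 0`).
#' @export
fba_advance <- function(snapshot, submodel, dt, carry = numeric(0)) {
  stopifnot(identical(submodel$formalism, "FBA"), dt >= 0)
  if (dt == 0) {
    return(list(request = change_request(submodel$id),
                carry = carry, solution = NULL))
  }
  problem <- build_fba_problem(snapshot, submodel, dt)
  sol <- solve_lp(problem)
  boundary <- problem$boundary_species
  resid <- stats::setNames(numeric(length(boundary)), boundary)
  present <- intersect(names(carry), boundary)
  resid[present] <- carry[present]

  if (!identical(sol$status, "optimal")) {
    return(list(request = change_request(submodel$id,
                                         diagnostics = list(status = sol$status,
                                                            infeasible = TRUE)),
                carry = resid, solution = sol))
  }
  cont <- as.numeric(problem$S_boundary %*% sol$fluxes) * dt
  names(cont) <- boundary
  x <- cont + resid
  d_int <- round(x)
  new_resid <- x - d_int
  avail <- snapshot$counts[boundary]
  clip <- (avail + d_int) < 0
  if (any(clip)) {   # can only arise from rounding at the availability edge
    d_int[clip] <- -avail[clip]
    new_resid[clip] <- 0
  }
  list(request = change_request(submodel$id, d_int,
                                diagnostics = list(status = "optimal",
                                                   infeasible = FALSE,
                                                   objective_value = sol$objective_value)),
       carry = new_resid, solution = sol)
}
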