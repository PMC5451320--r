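# Independent oracles, deliberately written without reusing package
# internals: a naive direct-method SSA over a plain rate table, and a
# brute-force vertex-enumeration LP solver for small flux polytopes.

# Naive Gillespie direct method. `rxns` is a list of lists with elements
# `reactants`, `products` (named stoichiometry vectors) and `k`. Draw
# order matches the package convention (one uniform for the waiting time,
# one for the reaction choice), so that with the same seed the event
# sequences of oracle and engine can be compared directly.
oracle_ssa <- function(rxns, counts, t_end, seed) {
  set.seed(seed)
  t <- 0
  n_events <- 0L
  repeat {
    a <- vapply(rxns, function(r) {
      if (length(r$reactants) == 0L) return(r$k)
      r$k * prod(choose(counts[names(r$reactants)], r$reactants))
    }, numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t - log(runif(1)) / a0
    if (t > t_end) break
    j <- which(cumsum(a) >= runif(1) * a0)[1]
    r <- rxns[[j]]
    for (sp in names(r$reactants)) counts[sp] <- counts[sp] - r$reactants[[sp]]
    for (sp in names(r$products)) counts[sp] <- counts[sp] + r$products[[sp]]
    n_events <- n_events + 1L
  }
  list(counts = counts, n_events = n_events)
}

# Brute-force LP: maximize obj'v subject to Aeq v = beq, A v <= b,
# lb <= v <= ub, by enumerating all candidate vertices (solutions of n
# active constraints) and keeping the feasible one with the best
# objective. Only for tiny problems (n <= 6).
oracle_lp_vertex <- function(obj, Aeq = NULL, beq = NULL, A = NULL, b = NULL,
                             lb, ub, tol = 1e-9) {
  n <- length(obj)
  rows <- list()
  add <- function(a, rhs, eq) rows[[length(rows) + 1L]] <<- list(a = a, rhs = rhs, eq = eq)
  if (!is.null(Aeq)) for (i in seq_len(nrow(Aeq))) add(Aeq[i, ], beq[i], TRUE)
  if (!is.null(A)) for (i in seq_len(nrow(A))) add(A[i, ], b[i], FALSE)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) add(replace(numeric(n), j, 1), lb[j], FALSE)
    if (is.finite(ub[j])) add(replace(numeric(n), j, 1), ub[j], FALSE)
  }
  eq_idx <- which(vapply(rows, function(r) r$eq, logical(1)))
  free_idx <- setdiff(seq_along(rows), eq_idx)
  need <- n - length(eq_idx)
  if (need < 0) need <- 0
  combos <- if (need == 0) list(integer(0)) else
    asplit(utils::combn(free_idx, need), 2)
  feasible <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(FALSE)
    if (!is.null(Aeq) && any(abs(as.numeric(Aeq %*% v) - beq) > tol)) return(FALSE)
    if (!is.null(A) && any(as.numeric(A %*% v) > b + tol)) return(FALSE)
    TRUE
  }
  best <- -Inf
  best_v <- NULL
  for (cmb in combos) {
    act <- c(eq_idx, cmb)
    M <- do.call(rbind, lapply(rows[act], function(r) r$a))
    rhs <- vapply(rows[act], function(r) r$rhs, numeric(1))
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (feasible(v)) {
      val <- sum(obj * v)
      if (val > best + tol) {
        best <- val
        best_v <- v
      }
    }
  }
  if (is.null(best_v)) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = best, v = best_v)
}

# Shared fixtures ------------------------------------------------------

# Linear chain A -> B (SSA) -> C (ODE) used by the hybrid-coupling checks.
chain_model <- function(A0 = 250, k1 = 0.2, k2 = 0.05) {
  ssa <- wc_submodel("flux_ab", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("ab", c(A = 1), c(B = 1), k1)))
  ode <- wc_submodel("flux_bc", "ODE",
    species = list(wc_species("B", compartment = "c"),
                   wc_species("C", compartment = "c")),
    reactions = list(wc_reaction("bc", c(B = 1), c(C = 1), k2)))
  man <- wc_manifest(list(ssa, ode),
    mapping = list(flux_ab = c(A = "A_c", B = "B_c"),
                   flux_bc = c(B = "B_c", C = "C_c")),
    compartments = list(wc_compartment("c", "cytosol", 1e-15)),
    initial_counts = c(A_c = A0, B_c = 0, C_c = 0))
  compose_model(man)
}

# Closed two-state toggle A <-> B (SSA), conserving A + B exactly.
toggle_model <- function(n0 = 50, k = 0.05) {
  ssa <- wc_submodel("toggle", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("fwd", c(A = 1), c(B = 1), k),
                     wc_reaction("rev", c(B = 1), c(A = 1), k)))
  man <- wc_manifest(list(ssa),
    mapping = list(toggle = c(A = "A_c", B = "B_c")),
    compartments = list(wc_compartment("c", "cytosol", 1e-15)),
    initial_counts = c(A_c = n0, B_c = n0))
  compose_model(man)
}

# Immigration-death process 0 -> A (rate b), A -> 0 (rate d per molecule);
# stationary law is Poisson(b/d).
birth_death_model <- function(b = 10, d = 0.1, a0 = 100) {
  ssa <- wc_submodel("bd", "SSA",
    species = list(wc_species("A", compartment = "c")),
    reactions = list(wc_reaction("birth", numeric(0), c(A = 1), b),
                     wc_reaction("death", c(A = 1), numeric(0), d)))
  man <- wc_manifest(list(ssa),
    mapping = list(bd = c(A = "A_c")),
    compartments = list(wc_compartment("c", "cytosol", 1e-15)),
    initial_counts = c(A_c = a0))
  compose_model(man)
}

# Structural deep-comparison of submodels, invariant to list ordering.
expect_same_submodel <- function(got, want) {
  expect_identical(got$id, want$id)
  expect_identical(got$formalism, want$formalism)
  key <- function(xs) order(vapply(xs, function(x) x$id, character(1)))
  gs <- got$species[key(got$species)]
  ws <- want$species[key(want$species)]
  expect_equal(lapply(gs, function(s) s[c("id", "compartment", "initial_count")]),
               lapply(ws, function(s) s[c("id", "compartment", "initial_count")]))
  gr <- got$reactions[key(got$reactions)]
  wr <- want$reactions[key(want$reactions)]
  norm <- function(r) list(id = r$id,
                           reactants = r$reactants[sort(names(r$reactants))],
                           products = r$products[sort(names(r$products))],
                           rate = r$rate_constant, enabled = r$enabled)
  expect_equal(lapply(gr, norm), lapply(wr, norm))
  if (!is.null(want$fba)) {
    expect_equal(got$fba$lower[sort(names(want$fba$lower))],
                 want$fba$lower[sort(names(want$fba$lower))])
    expect_equal(got$fba$upper[sort(names(want$fba$upper))],
                 want$fba$upper[sort(names(want$fba$upper))])
    expect_equal(got$fba$objective[sort(names(want$fba$objective))],
                 want$fba$objective[sort(names(want$fba$objective))])
    expect_setequal(got$fba$internal, want$fba$internal)
  }
}

fixed_dt_config <- function(t_max, dt, seed = 1L) {
  sim_config(t_max = t_max, dt_init = dt, dt_min = dt, dt_max = dt, seed = seed)
}
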