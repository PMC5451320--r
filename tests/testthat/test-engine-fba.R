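# toy chain: uptake 0 -> A (bound [0, 10]), growth A -> biomass (objective)
chain_fba <- function(uptake_ub = 10, growth_ub = Inf) {
  wc_submodel("f", "FBA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("BM", compartment = "c")),
    reactions = list(
      wc_reaction("up", numeric(0), c(A = 1), 0),
      wc_reaction("gr", c(A = 1), c(BM = 1), 0)),
    fba = list(lower = c(up = 0, gr = 0),
               upper = c(up = uptake_ub, gr = growth_ub),
               objective = c(gr = 1), internal = "A"))
}

# growth draws directly on the boundary pool of A (no internal metabolite)
pool_fba <- function(growth_ub = Inf) {
  wc_submodel("f", "FBA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("BM", compartment = "c")),
    reactions = list(wc_reaction("gr", c(A = 1), c(BM = 1), 0)),
    fba = list(lower = c(gr = 0), upper = c(gr = growth_ub),
               objective = c(gr = 1), internal = character(0)))
}

test_that("availability tightens static uptake bounds to n/dt", {
  sm <- pool_fba(growth_ub = 10)
  p <- build_fba_problem(wc_snapshot(0, c(A = 5, BM = 0)), sm, dt = 1)
  expect_equal(unname(p$upper[["gr"]]), 5)              # min(10, 5/1)
  p0 <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  expect_equal(unname(p0$upper[["gr"]]), 0)
  ph <- build_fba_problem(wc_snapshot(0, c(A = 5, BM = 0)), sm, dt = 0.5)
  expect_equal(unname(ph$upper[["gr"]]), 10)            # min(10, 5/0.5)
})

test_that("LP objective matches brute-force vertex enumeration on the toy chain", {
  sm <- chain_fba()
  p <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  sol <- solve_lp(p)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-12)
  S <- p$S_internal
  ora <- oracle_lp_vertex(unname(p$objective), Aeq = unname(S),
                          beq = rep(0, nrow(S)),
                          lb = unname(p$lower), ub = unname(pmin(p$upper, 1e9)))
  expect_lt(abs(sol$objective_value - ora$objective), 1e-9)
  # steady state holds at the optimum
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
})

test_that("degenerate parallel routes have a unique objective value", {
  sm <- wc_submodel("f", "FBA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("BM", compartment = "c")),
    reactions = list(
      wc_reaction("up", numeric(0), c(A = 1), 0),
      wc_reaction("gr1", c(A = 1), c(BM = 1), 0),
      wc_reaction("gr2", c(A = 1), c(BM = 1), 0)),
    fba = list(lower = c(up = 0, gr1 = 0, gr2 = 0),
               upper = c(up = 10, gr1 = 6, gr2 = 6),
               objective = c(gr1 = 1, gr2 = 1), internal = "A"))
  p <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  sol <- solve_lp(p)
  expect_identical(sol$status, "optimal")
  ora <- oracle_lp_vertex(unname(p$objective), Aeq = unname(p$S_internal),
                          beq = rep(0, nrow(p$S_internal)),
                          lb = unname(p$lower), ub = unname(pmin(p$upper, 1e9)))
  expect_lt(abs(sol$objective_value - 10), 1e-9)
  expect_lt(abs(sol$objective_value - ora$objective), 1e-9)
})

test_that("contradictory bounds are reported as infeasible, never silent zeros", {
  sm <- chain_fba()
  sm$fba$lower[["up"]] <- 5
  sm$fba$upper[["up"]] <- 3
  p <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  expect_identical(solve_lp(p)$status, "infeasible")
})

test_that("optimal fluxes convert to flux*dt requests on boundary species", {
  sm <- pool_fba(growth_ub = 5)
  out <- fba_advance(wc_snapshot(0, c(A = 100, BM = 0)), sm, dt = 1)
  expect_equal(unname(out$request$deltas[c("A", "BM")]), c(-5, 5))
  expect_false(out$request$diagnostics$infeasible)
  # internal metabolites contribute no deltas
  sm2 <- chain_fba()
  out2 <- fba_advance(wc_snapshot(0, c(A = 50, BM = 0)), sm2, dt = 1)
  expect_false("A" %in% names(out2$request$deltas))
  expect_equal(unname(out2$request$deltas[["BM"]]), 10)
})

test_that("infeasible problems degrade to a flagged zero request", {
  sm <- chain_fba()
  sm$fba$lower[["gr"]] <- 50   # demands more than uptake can supply
  out <- fba_advance(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  expect_length(out$request$deltas, 0)
  expect_true(out$request$diagnostics$infeasible)
})

test_that("a zero-length step produces a zero request", {
  out <- fba_advance(wc_snapshot(0, c(A = 10, BM = 0)), pool_fba(), dt = 0)
  expect_length(out$request$deltas, 0)
})

test_that("an FBA request alone can never overdraw a boundary pool", {
  sm <- pool_fba()   # unbounded growth, limited only by availability
  for (n in c(0, 1, 3, 17)) {
    for (dt in c(0.25, 1, 2)) {
      out <- fba_advance(wc_snapshot(0, c(A = n, BM = 0)), sm, dt = dt)
      dA <- if ("A" %in% names(out$request$deltas)) out$request$deltas[["A"]] else 0
      expect_gte(n + dA, 0)
    }
  }
})

test_that("relaxing an upper bound never decreases the objective", {
  sm <- chain_fba(uptake_ub = 5, growth_ub = 8)
  p1 <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  v1 <- solve_lp(p1)$objective_value
  sm$fba$upper[["up"]] <- 12
  p2 <- build_fba_problem(wc_snapshot(0, c(A = 0, BM = 0)), sm, dt = 1)
  v2 <- solve_lp(p2)$objective_value
  expect_gte(v2, v1 - 1e-12)
})

test_that("an unbounded objective is reported as unbounded", {
  sm <- wc_submodel("f", "FBA",
    species = list(wc_species("BM", compartment = "c")),
    reactions = list(wc_reaction("gr", numeric(0), c(BM = 1), 0)),
    fba = list(lower = c(gr = 0), upper = c(gr = Inf),
               objective = c(gr = 1), internal = character(0)))
  p <- build_fba_problem(wc_snapshot(0, c(BM = 0)), sm, dt = 1)
  expect_identical(solve_lp(p)$status, "unbounded")
})
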