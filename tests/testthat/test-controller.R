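test_that("largest-remainder scaling matches exact integer arithmetic", {
  rq <- function(id, d) change_request(id, d)
  # pool 4, two requests of -3: floor(3*4/6) = 2 each, no remainder
  d4 <- arbitrate(list(rq("s1", c(A = -3)), rq("s2", c(A = -3))), c(A = 4))
  expect_equal(unname(c(d4$accepted$s1[["A"]], d4$accepted$s2[["A"]])), c(-2, -2))
  expect_equal(unname(d4$committed[["A"]]), 0)
  expect_identical(d4$scaled_species, "A")

  # pool 5: floors 2,2; leftover unit to the first submodel by id
  d5 <- arbitrate(list(rq("s1", c(A = -3)), rq("s2", c(A = -3))), c(A = 5))
  expect_equal(unname(c(d5$accepted$s1[["A"]], d5$accepted$s2[["A"]])), c(-3, -2))
  expect_equal(unname(d5$committed[["A"]]), 0)

  # tie-break is by submodel id, not list position
  d5r <- arbitrate(list(rq("s2", c(A = -3)), rq("s1", c(A = -3))), c(A = 5))
  expect_equal(unname(d5r$accepted$s1[["A"]]), -3)
  expect_equal(unname(d5r$accepted$s2[["A"]]), -2)

  # feasible requests are accepted verbatim
  ok <- arbitrate(list(rq("s1", c(A = -2, B = 4)), rq("s2", c(A = -1))),
                  c(A = 10, B = 0))
  expect_length(ok$scaled_species, 0)
  expect_equal(unname(ok$committed[c("A", "B")]), c(7, 4))

  # production is never scaled, even on an empty pool
  pos <- arbitrate(list(rq("s1", c(A = 5))), c(A = 0))
  expect_length(pos$scaled_species, 0)
  expect_equal(unname(pos$committed[["A"]]), 5)

  # production counts toward availability for consumers
  mix <- arbitrate(list(rq("maker", c(A = 6)), rq("user", c(A = -8))), c(A = 0))
  expect_equal(unname(mix$accepted$user[["A"]]), -6)
  expect_equal(unname(mix$committed[["A"]]), 0)
})

test_that("the adaptive step halves on conflict, doubles after clean runs", {
  cfg <- sim_config(t_max = 10, dt_init = 1, dt_min = 0.125, dt_max = 2,
                    clean_steps_to_grow = 3)
  scaled <- structure(list(scaled_species = "A"), class = "wc_commit")
  clean <- structure(list(scaled_species = character(0)), class = "wc_commit")

  a <- adapt_dt(scaled, dt = 1, cfg, clean_counter = 2L, retries = 0L)
  expect_true(a$redo)
  expect_equal(a$dt_next, 0.5)
  expect_equal(a$clean_counter, 0L)

  # scaling at the floor commits with a warning flag, dt unchanged
  b <- adapt_dt(scaled, dt = 0.125, cfg, clean_counter = 0L, retries = 3L)
  expect_false(b$redo)
  expect_true(b$warn)
  expect_equal(b$dt_next, 0.125)

  # the retry budget forces a scaled commit even above the floor
  b2 <- adapt_dt(scaled, dt = 0.5, cfg, clean_counter = 0L, retries = 8L)
  expect_false(b2$redo)
  expect_true(b2$warn)

  # third consecutive clean step doubles dt, bounded by dt_max
  c1 <- adapt_dt(clean, dt = 0.5, cfg, clean_counter = 2L, retries = 0L)
  expect_false(c1$redo)
  expect_equal(c1$dt_next, 1.0)
  expect_equal(c1$clean_counter, 0L)
  c2 <- adapt_dt(clean, dt = 2, cfg, clean_counter = 2L, retries = 0L)
  expect_equal(c2$dt_next, 2)   # capped at dt_max
})

test_that("submodels with null dynamics produce zero requests", {
  sm1 <- wc_submodel("s1", "SSA",
    species = list(wc_species("A", compartment = "c")),
    reactions = list(wc_reaction("r1", c(A = 1), numeric(0), 0)))
  sm2 <- wc_submodel("s2", "ODE",
    species = list(wc_species("A", compartment = "c")),
    reactions = list(wc_reaction("r2", c(A = 1), numeric(0), 0)))
  man <- wc_manifest(list(sm1, sm2),
    mapping = list(s1 = c(A = "A_c"), s2 = c(A = "A_c")),
    compartments = list(wc_compartment("c", volume = 1e-15)),
    initial_counts = c(A_c = 10))
  model <- compose_model(man)
  snap <- wc_snapshot(0, c(A_c = 10))
  out <- collect_requests(snap, model$submodels, dt = 1)
  expect_length(out$requests, 2)
  expect_true(all(vapply(out$requests, function(r) length(r$deltas) == 0, logical(1))))
})

test_that("per-submodel streams make request collection order-independent", {
  model <- chain_model(A0 = 100)
  snap <- wc_snapshot(0, c(A_c = 100, B_c = 20, C_c = 0))
  fwd <- collect_requests(snap, model$submodels, dt = 0.5, master_seed = 11,
                          step = 3)
  rev <- collect_requests(snap, rev(model$submodels), dt = 0.5, master_seed = 11,
                          step = 3)
  by_id <- function(rs) {
    o <- order(vapply(rs, function(r) r$submodel, character(1)))
    lapply(rs[o], function(r) r$deltas)
  }
  expect_identical(by_id(fwd$requests), by_id(rev$requests))
})

test_that("requests from submodels on disjoint species have disjoint keys", {
  model <- chain_model(A0 = 200)
  # A is only in the SSA submodel, C only in the ODE submodel
  snap <- wc_snapshot(0, c(A_c = 200, B_c = 50, C_c = 0))
  out <- collect_requests(snap, model$submodels, dt = 0.5, master_seed = 2)
  ssa_keys <- names(out$requests[[1]]$deltas)
  ode_keys <- names(out$requests[[2]]$deltas)
  expect_true(all(ssa_keys %in% c("A_c", "B_c")))
  expect_true(all(ode_keys %in% c("B_c", "C_c")))
  expect_false("C_c" %in% ssa_keys)
  expect_false("A_c" %in% ode_keys)
})

test_that("a model with no active reactions yields a constant trajectory", {
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list())
  man <- wc_manifest(list(sm), mapping = list(s = c(A = "A_c", B = "B_c")),
    compartments = list(wc_compartment("c", volume = 1e-15)),
    initial_counts = c(A_c = 7, B_c = 3))
  tr <- wc_simulate(compose_model(man), fixed_dt_config(t_max = 10, dt = 1))
  expect_true(all(tr$counts[, "A_c"] == 7))
  expect_true(all(tr$counts[, "B_c"] == 3))
  expect_equal(nrow(tr$counts), 11)   # committed steps + 1
})

test_that("a closed toggle conserves total copy number exactly", {
  model <- toggle_model(n0 = 50)
  tr <- wc_simulate(model, fixed_dt_config(t_max = 50, dt = 0.5, seed = 5))
  expect_true(all(rowSums(tr$counts[, c("A_c", "B_c")]) == 100))
  expect_true(all(tr$counts >= 0))
})

test_that("identical model, config and seed reproduce the trajectory bit for bit", {
  mc <- make_minimal_cell_model()
  cfg <- sim_config(t_max = 5, dt_init = 0.1, seed = 123)
  t1 <- wc_simulate(mc$model, cfg)
  t2 <- wc_simulate(mc$model, cfg)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$diagnostics, t2$diagnostics)
})

test_that("a single SSA submodel with dt >= t_max reproduces plain Gillespie", {
  # same derived stream, one controller step: the event sequence must match
  # an independently coded direct-method oracle exactly
  model <- birth_death_model(b = 4, d = 0.2, a0 = 10)
  cfg <- sim_config(t_max = 8, dt_init = 8, dt_min = 8, dt_max = 8, seed = 31)
  tr <- wc_simulate(model, cfg)
  seed <- wcsim:::stream_seed(31L, "bd", 1L, 0L)
  ora <- oracle_ssa(list(list(reactants = numeric(0), products = c(A_c = 1), k = 4),
                         list(reactants = c(A_c = 1), products = numeric(0), k = 0.2)),
                    c(A_c = 10), t_end = 8, seed = seed)
  expect_equal(unname(tr$counts[nrow(tr$counts), "A_c"]),
               unname(ora$counts[["A_c"]]))
})

test_that("conflicting consumption triggers redo, scaling only at the floor", {
  # two SSA submodels racing for the same tiny pool
  mk <- function(id) wc_submodel(id, "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction(paste0(id, "_r"), c(A = 1), c(B = 1), 50)))
  man <- wc_manifest(list(mk("s1"), mk("s2")),
    mapping = list(s1 = c(A = "A_c", B = "B_c"), s2 = c(A = "A_c", B = "B_c")),
    compartments = list(wc_compartment("c", volume = 1e-15)),
    initial_counts = c(A_c = 4, B_c = 0))
  model <- compose_model(man)
  cfg <- sim_config(t_max = 2, dt_init = 1, dt_min = 0.25, dt_max = 1, seed = 3)
  tr <- suppressWarnings(wc_simulate(model, cfg))
  expect_true(all(tr$counts >= 0))
  # the racing steps either redid at smaller dt or scaled at the floor
  expect_true(any(tr$diagnostics$retries > 0) || any(tr$diagnostics$scaled_at_floor))
  # scaled-at-floor commits accept production in full while curtailing
  # consumption, so the copy-number sum may only change on flagged steps
  sums <- rowSums(tr$counts[, c("A_c", "B_c")])
  expect_true(all(diff(sums)[!tr$diagnostics$scaled_at_floor] == 0))
})

test_that("sequential reference mode approaches controller mode as dt shrinks", {
  model <- chain_model(A0 = 150)
  mean_c <- function(mode, dt, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- wc_simulate(model, fixed_dt_config(t_max = 5, dt = dt, seed = s),
                        mode = mode)
      tr$counts[nrow(tr$counts), "C_c"]
    }, numeric(1)))
  }
  seeds <- 1:40
  gap_coarse <- abs(mean_c("controller", 1, seeds) - mean_c("sequential", 1, seeds))
  gap_fine <- abs(mean_c("controller", 0.25, seeds) - mean_c("sequential", 0.25, seeds))
  expect_lt(gap_fine, gap_coarse + 0.5)  # gap shrinks (noise allowance)
})

test_that("trajectory accessors expose a tidy view of the run", {
  mc <- make_minimal_cell_model()
  tr <- wc_simulate(mc$model, sim_config(t_max = 2, dt_init = 0.1, seed = 1))
  df <- as.data.frame(tr)
  expect_identical(names(df)[1], "time")
  expect_equal(nrow(df), length(tr$times))
  s <- summary(tr)
  expect_true(all(c("species", "initial", "final") %in% names(s)))
  expect_output(print(tr), "trajectory")
})
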