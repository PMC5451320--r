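test_that("propensity follows the combinatorial mass-action convention", {
  expect_equal(propensity(wc_reaction("r", c(A = 1, B = 1), c(C = 1), 2.0),
                          c(A = 3, B = 4)), 24.0)
  expect_equal(propensity(wc_reaction("r", c(A = 2), c(B = 1), 1.0),
                          c(A = 4)), 6.0)          # C(4, 2)
  expect_equal(propensity(wc_reaction("r", c(A = 2), c(B = 1), 1.0),
                          c(A = 1)), 0)            # insufficient copies
  expect_equal(propensity(wc_reaction("r", numeric(0), c(A = 1), 5.0),
                          c(A = 0)), 5.0)          # empty product
})

test_that("disabled reactions and corrupt states are handled", {
  r <- wc_reaction("r", c(A = 1), c(B = 1), 3, enabled = FALSE)
  expect_equal(propensity(r, c(A = 10)), 0)
  r_on <- wc_reaction("r", c(A = 1), c(B = 1), 3)
  expect_error(propensity(r_on, c(A = -1)), "state corruption")
})

test_that("parameter-valued rate constants resolve through the snapshot", {
  r <- wc_reaction("r", c(A = 1), c(B = 1), "k_x")
  expect_equal(propensity(r, c(A = 4), parameters = c(k_x = 0.5)), 2.0)
  expect_error(propensity(r, c(A = 4)), "k_x")
})

test_that("an absorbing state yields a zero request", {
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r", c(A = 1), c(B = 1), 1)))
  res <- ssa_advance(wc_snapshot(0, c(A = 0, B = 3)), sm, dt = 5, seed = 1)
  expect_equal(res$n_events, 0L)
  expect_length(res$request$deltas, 0)
})

test_that("a finite pool is exhausted completely given enough time", {
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r", c(A = 1), c(B = 1), 5)))
  res <- ssa_advance(wc_snapshot(0, c(A = 5, B = 0)), sm, dt = 1e4, seed = 42)
  expect_equal(res$n_events, 5L)
  expect_equal(unname(res$request$deltas[c("A", "B")]), c(-5, 5))
  expect_lte(res$final_local_time, 1e4)
})

test_that("the snapshot is never modified by the engine", {
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r", c(A = 1), c(B = 1), 5)))
  snap <- wc_snapshot(0, c(A = 5, B = 0))
  before <- snap$counts
  invisible(ssa_advance(snap, sm, dt = 10, seed = 7))
  expect_identical(snap$counts, before)
})

test_that("identical snapshot, dt and stream state reproduce the result exactly", {
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r1", c(A = 1), c(B = 1), 0.4),
                     wc_reaction("r2", c(B = 1), c(A = 1), 0.3)))
  snap <- wc_snapshot(0, c(A = 40, B = 10))
  a <- ssa_advance(snap, sm, dt = 3, seed = 99)
  b <- ssa_advance(snap, sm, dt = 3, seed = 99)
  expect_identical(a, b)
})

test_that("request deltas equal the summed stoichiometry of fired events", {
  # in A -> B each event moves exactly one molecule, so deltas = +-n_events
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r", c(A = 1), c(B = 1), 0.2)))
  for (seed in 1:5) {
    res <- ssa_advance(wc_snapshot(0, c(A = 100, B = 0)), sm, dt = 1, seed = seed)
    d <- res$request$deltas
    if (res$n_events == 0) {
      expect_length(d, 0)
    } else {
      expect_equal(unname(d[c("A", "B")]), c(-res$n_events, res$n_events))
    }
  }
})

test_that("immigration-death long-run average matches b/d", {
  # stationary mean and variance of the process are both b/d
  model <- birth_death_model(b = 10, d = 0.1, a0 = 100)
  n_windows <- 20
  means <- vapply(seq_len(n_windows), function(rep) {
    tr <- wc_simulate(model, fixed_dt_config(t_max = 100, dt = 1, seed = 1000 + rep))
    keep <- tr$times > 50
    mean(tr$counts[keep, "A_c"])
  }, numeric(1))
  se <- stats::sd(means) / sqrt(n_windows)
  expect_lt(abs(mean(means) - 100), 3 * se)
})

test_that("event-count distribution matches a naive direct-method oracle", {
  # two-reaction toy model; chi-square on n_events at alpha = 0.01
  rxns <- list(list(reactants = c(A = 1), products = c(B = 1), k = 0.5),
               list(reactants = c(B = 1), products = c(A = 1), k = 0.25))
  sm <- wc_submodel("s", "SSA",
    species = list(wc_species("A", compartment = "c"),
                   wc_species("B", compartment = "c")),
    reactions = list(wc_reaction("r1", c(A = 1), c(B = 1), 0.5),
                     wc_reaction("r2", c(B = 1), c(A = 1), 0.25)))
  n_rep <- 1500
  counts0 <- c(A = 12, B = 0)
  eng <- vapply(seq_len(n_rep), function(i)
    ssa_advance(wc_snapshot(0, counts0), sm, dt = 1, seed = 20000 + i)$n_events,
    numeric(1))
  ora <- vapply(seq_len(n_rep), function(i)
    oracle_ssa(rxns, counts0, t_end = 1, seed = 50000 + i)$n_events, numeric(1))
  # pool sparse tails so expected cell counts stay reasonable
  brks <- c(-0.5, seq(0.5, 9.5), Inf)
  o <- table(cut(eng, brks))
  e <- table(cut(ora, brks))
  keep <- (o + e) > 0
  suppressWarnings(p <- stats::chisq.test(rbind(o[keep], e[keep]))$p.value)
  expect_gt(p, 0.01)
})
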