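#' Take a state snapshot
#'
#' The snapshot is the immutable input state every submodel reads within a
#' step: simulation time, non-negative integer species counts, and the
#' current parameter values. All engines work on private copies; nothing
#' mutates a snapshot, which is what enforces the arrow of time — no
#' submodel ever sees another submodel's uncommitted output.
#'
#' @param time Simulation time in seconds.
#' @param counts Named numeric vector of non-negative integer counts.
#' @param parameters Named numeric vector of parameter values.
#' @return An object of class `wc_snapshot`.
#' @export
wc_snapshot <- function(time, counts, parameters = numeric(0)) {
  if (any(counts < 0)) stop("snapshot counts must be non-negative", call. = FALSE)
  structure(list(time = time, counts = counts, parameters = parameters),
            class = "wc_snapshot")
}

#' Simulation configuration
#'
#' @param t_max End time in seconds.
#' @param dt_init Initial step length (seconds).
#' @param dt_min,dt_max Bounds on the adaptive step; must satisfy
#'   `0 < dt_min <= dt_init <= dt_max`.
#' @param clean_steps_to_grow Number of consecutive scale-free committed
#'   steps after which the step doubles (bounded by `dt_max`).
#' @param seed Master seed; every substream is derived from it.
#' @param output_stride Record every `output_stride`-th committed step
#'   (the initial and final states are always recorded).
#' @param max_retries Maximum redo attempts within one step before a scaled
#'   commit is forced.
#' @return An object of class `wc_config`.
#' @export
sim_config <- function(t_max, dt_init = 1, dt_min = dt_init / 8,
                       dt_max = dt_init * 4, clean_steps_to_grow = 3L,
                       seed = 1L, output_stride = 1L, max_retries = 8L) {
  stopifnot(t_max >= 0, dt_min > 0, dt_min <= dt_init, dt_init <= dt_max,
            clean_steps_to_grow >= 1, output_stride >= 1, max_retries >= 0)
  structure(list(t_max = t_max, dt_init = dt_init, dt_min = dt_min,
                 dt_max = dt_max, clean_steps_to_grow = as.integer(clean_steps_to_grow),
                 seed = as.integer(seed), output_stride = as.integer(output_stride),
                 max_retries = as.integer(max_retries)),
            class = "wc_config")
}

#' Collect change requests from all dynamical submodels
#'
#' Invokes every non-Boolean submodel's engine with the identical snapshot.
#' Each submodel draws from its own substream derived from (master seed,
#' submodel id, step, retry), so the order of invocation is unobservable in
#' the results. Boolean submodels are evaluated separately by the
#' controller (see [evaluate_rules()]).
#'
#' @param snapshot A [wc_snapshot()].
#' @param submodels List of [wc_submodel()].
#' @param dt Step length (seconds).
#' @param master_seed Master simulation seed.
#' @param step Step index (1-based).
#' @param retry Retry index within the step.
#' @param carries Named list of per-submodel residual carries.
#' @return List with `requests` (list of [change_request()], one per
#'   non-Boolean submodel) and `carries` (updated, uncommitted).
#' @export
collect_requests <- function(snapshot, submodels, dt, master_seed = 1L,
                             step = 1L, retry = 0L, carries = list()) {
  requests <- list()
  for (sm in submodels) {
    res <- switch(sm$formalism,
      SSA = {
        out <- tryCatch(
          ssa_advance(snapshot, sm, dt, stream_seed(master_seed, sm$id, step, retry)),
          error = function(e) stop("submodel '", sm$id, "': ", conditionMessage(e),
                                   call. = FALSE))
        list(request = out$request, carry = carries[[sm$id]])
      },
      ODE = {
        out <- tryCatch(
          ode_advance(snapshot, sm, dt, carry = carries[[sm$id]] %||% numeric(0)),
          error = function(e) stop("submodel '", sm$id, "': ", conditionMessage(e),
                                   call. = FALSE))
        list(request = out$request, carry = out$carry)
      },
      FBA = {
        out <- tryCatch(
          fba_advance(snapshot, sm, dt, carry = carries[[sm$id]] %||% numeric(0)),
          error = function(e) stop("submodel '", sm$id, "': ", conditionMessage(e),
                                   call. = FALSE))
        list(request = out$request, carry = out$carry)
      },
      BOOLEAN = NULL
    )
    if (is.null(res)) next
    requests[[length(requests) + 1L]] <- res$request
    carries[[sm$id]] <- res$carry
  }
  list(requests = requests, carries = carries)
}

#' Arbitrate change requests against the global pool
#'
#' The central controller's accept/reject policy. Production (positive
#' deltas) is always accepted in full and counts toward availability. For
#' each species whose total requested consumption `C_s` exceeds the
#' available pool `A_s` (current count plus total production), each
#' consuming submodel's consumption `r_i` is scaled to
#' `floor(r_i * A_s / C_s)` and the remaining units are distributed by
#' largest fractional remainder, ties broken by ascending submodel id.
#' When no species is in deficit all requests are accepted verbatim. The
#' committed pool is non-negative for every species by construction.
#'
#' @param requests List of [change_request()].
#' @param counts Named numeric vector of current (non-negative) counts.
#' @return An object of class `wc_commit`: `accepted` (named list of
#'   accepted delta vectors per submodel), `scaled_species` (ids that
#'   required scaling), `scaling` (data frame of per-(species, submodel)
#'   requested vs accepted consumption), `committed` (new counts vector).
#' @export
arbitrate <- function(requests, counts) {
  stopifnot(all(counts >= 0))
  accepted <- stats::setNames(
    lapply(requests, function(rq) rq$deltas),
    vapply(requests, function(rq) rq$submodel, character(1)))

  all_sp <- unique(unlist(lapply(requests, function(rq) names(rq$deltas))))
  scaled_species <- character(0)
  scaling <- list()

  for (s in all_sp) {
    prod_s <- 0
    cons <- numeric(0)   # positive consumption magnitudes per submodel
    for (rq in requests) {
      if (!(s %in% names(rq$deltas))) next
      d <- rq$deltas[[s]]
      if (d > 0) prod_s <- prod_s + d else if (d < 0) cons[[rq$submodel]] <- -d
    }
    C_s <- sum(cons)
    A_s <- counts[[s]] + prod_s
    if (C_s <= A_s || C_s == 0) next

    share <- cons * A_s / C_s
    fl <- floor(share)
    leftover <- round(A_s - sum(fl))
    if (leftover > 0) {
      rem <- share - fl
      ord <- order(-rem, names(cons))
      take <- ord[seq_len(leftover)]
      fl[take] <- fl[take] + 1
    }
    for (i in seq_along(cons)) {
      sm_id <- names(cons)[[i]]
      accepted[[sm_id]][[s]] <- -fl[[i]]
      scaling[[length(scaling) + 1L]] <-
        data.frame(species = s, submodel = sm_id,
                   requested = -cons[[i]], accepted = -fl[[i]])
    }
    scaled_species <- c(scaled_species, s)
  }

  committed <- counts
  for (sm_id in names(accepted)) {
    d <- accepted[[sm_id]]
    if (length(d)) committed[names(d)] <- committed[names(d)] + d
  }
  committed <- round(committed)
  if (any(committed < 0)) {
    stop("internal error: arbitration committed a negative count", call. = FALSE)
  }
  structure(list(accepted = accepted,
                 scaled_species = scaled_species,
                 scaling = if (length(scaling)) do.call(rbind, scaling) else NULL,
                 committed = committed),
            class = "wc_commit")
}

#' Adapt the time step after arbitration
#'
#' If any scaling occurred and the step can still shrink (above `dt_min`,
#' retry budget not exhausted), the step is redone from the same snapshot
#' at half the step length with a fresh retry-indexed substream. Scaling at
#' the floor commits anyway with a warning flag — the simulation never
#' aborts. After `clean_steps_to_grow` consecutive scale-free commits the
#' step doubles, bounded by `dt_max`.
#'
#' @param decision A [arbitrate()] result.
#' @param dt Step length used for the attempt.
#' @param config A [sim_config()].
#' @param clean_counter Current count of consecutive clean committed steps.
#' @param retries Retries already used within this step.
#' @return List: `dt_next` (step length for the redo or the next step),
#'   `redo` (logical), `clean_counter` (updated), `warn` (logical: scaled
#'   commit at the floor).
#' @export
adapt_dt <- function(decision, dt, config, clean_counter = 0L, retries = 0L) {
  scaled <- length(decision$scaled_species) > 0
  if (scaled && dt > config$dt_min && retries < config$max_retries) {
    return(list(dt_next = max(dt / 2, config$dt_min), redo = TRUE,
                clean_counter = 0L, warn = FALSE))
  }
  if (scaled) {
    return(list(dt_next = dt, redo = FALSE, clean_counter = 0L, warn = TRUE))
  }
  clean_counter <- clean_counter + 1L
  if (clean_counter >= config$clean_steps_to_grow) {
    return(list(dt_next = min(2 * dt, config$dt_max), redo = FALSE,
                clean_counter = 0L, warn = FALSE))
  }
  list(dt_next = dt, redo = FALSE, clean_counter = clean_counter, warn = FALSE)
}

#' Run a multi-algorithm whole-cell simulation
#'
#' The integration meta-algorithm: per step, (1) take an immutable
#' snapshot; (2) integrate every dynamical submodel from that same
#' snapshot, collecting change requests; (3) arbitrate requests centrally
#' ([arbitrate()]); (4) on conflict, halve the step and redo from the same
#' snapshot ([adapt_dt()]), committing scaled only at the floor; (5) commit
#' the new non-negative state; (6) apply Boolean rule updates evaluated on
#' the step's snapshot, to take effect in the next step. Runs are fully
#' reproducible from (model, config): all randomness flows through
#' substreams derived from the master seed.
#'
#' `mode = "sequential"` provides the rejected sequential strategy as a
#' reference: submodels are integrated one after another within each step,
#' each seeing its predecessors' committed output, with a fixed step
#' length. On small models the controller-mode means converge to the
#' sequential-mode means as the step length shrinks.
#'
#' @param model A validated [wc_model()].
#' @param config A [sim_config()].
#' @param mode `"controller"` (default) or `"sequential"`.
#' @return An object of class `wc_trajectory`: `times`, `counts` (matrix,
#'   time by global species), and per-step `diagnostics` (step length
#'   used, number of scaled species, retries, warning flag).
#' @export
wc_simulate <- function(model, config, mode = c("controller", "sequential")) {
  mode <- match.arg(mode)
  rep_v <- validate_model(model)
  if (length(rep_v$errors)) {
    stop("model validation failed:\n  ", paste(rep_v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  counts <- initial_counts(model)
  parameters <- model$parameters
  submodels <- model$submodels
  rules <- unlist(lapply(submodels, function(sm)
    if (identical(sm$formalism, "BOOLEAN")) sm$rules else NULL), recursive = FALSE)
  if (mode == "sequential") {
    return(.simulate_sequential(model, config, counts, parameters, submodels, rules))
  }

  dt <- config$dt_init
  time <- 0
  clean_counter <- 0L
  carries <- list()
  step <- 0L
  n_warn <- 0L

  times <- time
  rows <- list(counts)
  diags <- list()

  while (time < config$t_max - 1e-12) {
    step <- step + 1L
    dt_step <- min(dt, config$t_max - time)
    retry <- 0L
    snap <- wc_snapshot(time, counts, parameters)
    repeat {
      cr <- collect_requests(snap, submodels, dt_step, config$seed, step, retry, carries)
      dec <- arbitrate(cr$requests, counts)
      ad <- adapt_dt(dec, dt_step, config, clean_counter, retry)
      if (!ad$redo) break
      retry <- retry + 1L
      dt_step <- ad$dt_next
    }

    counts <- dec$committed
    carries <- cr$carries
    time <- time + dt_step
    clean_counter <- ad$clean_counter
    dt <- min(max(ad$dt_next, config$dt_min), config$dt_max)
    if (ad$warn) {
      n_warn <- n_warn + 1L
      warning("step ", step, ": request scaling at dt_min (dt = ", dt_step,
              "); committed scaled requests", call. = FALSE)
    }

    if (length(rules)) {
      updates <- evaluate_rules(snap, rules)
      if (length(updates)) {
        upd_applied <- .apply_updates(submodels, parameters, updates)
        submodels <- upd_applied$submodels
        parameters <- upd_applied$parameters
      }
    }

    diags[[step]] <- data.frame(step = step, time = time, dt = dt_step,
                                n_scaled_species = length(dec$scaled_species),
                                retries = retry, scaled_at_floor = ad$warn)
    if (step %% config$output_stride == 0L || time >= config$t_max - 1e-12) {
      times <- c(times, time)
      rows[[length(rows) + 1L]] <- counts
    }
  }

  counts_mat <- do.call(rbind, rows)
  rownames(counts_mat) <- NULL
  structure(list(times = times, counts = counts_mat,
                 diagnostics = if (length(diags)) do.call(rbind, diags) else
                   data.frame(step = integer(0), time = numeric(0), dt = numeric(0),
                              n_scaled_species = integer(0), retries = integer(0),
                              scaled_at_floor = logical(0)),
                 n_warnings = n_warn, mode = mode, config = config),
            class = "wc_trajectory")
}

# Reference realization of the rejected sequential integration strategy:
# within each (fixed-length) step, submodels are integrated one after
# another, each seeing its predecessors' committed output. Kept for
# comparison with the controller's same-snapshot scheme; as dt -> 0 the
# two agree on small models.
.simulate_sequential <- function(model, config, counts, parameters, submodels, rules) {
  time <- 0
  step <- 0L
  carries <- list()
  times <- time
  rows <- list(counts)
  diags <- list()
  while (time < config$t_max - 1e-12) {
    step <- step + 1L
    dt_step <- min(config$dt_init, config$t_max - time)
    for (sm in submodels) {
      if (identical(sm$formalism, "BOOLEAN")) next
      snap <- wc_snapshot(time, counts, parameters)
      cr <- collect_requests(snap, list(sm), dt_step, config$seed, step, 0L, carries)
      dec <- arbitrate(cr$requests, counts)
      counts <- dec$committed
      carries <- cr$carries
    }
    snap <- wc_snapshot(time, counts, parameters)
    if (length(rules)) {
      updates <- evaluate_rules(snap, rules)
      if (length(updates)) {
        upd <- .apply_updates(submodels, parameters, updates)
        submodels <- upd$submodels
        parameters <- upd$parameters
      }
    }
    time <- time + dt_step
    diags[[step]] <- data.frame(step = step, time = time, dt = dt_step,
                                n_scaled_species = NA_integer_,
                                retries = 0L, scaled_at_floor = FALSE)
    if (step %% config$output_stride == 0L || time >= config$t_max - 1e-12) {
      times <- c(times, time)
      rows[[length(rows) + 1L]] <- counts
    }
  }
  counts_mat <- do.call(rbind, rows)
  rownames(counts_mat) <- NULL
  structure(list(times = times, counts = counts_mat,
                 diagnostics = do.call(rbind, diags),
                 n_warnings = 0L, mode = "sequential", config = config),
            class = "wc_trajectory")
}

.apply_updates <- function(submodels, parameters, updates) {
  for (u in updates) {
    if (u$type == "parameter") {
      parameters[[u$target]] <- u$value
    } else {
      for (i in seq_along(submodels)) {
        for (j in seq_along(submodels[[i]]$reactions)) {
          if (identical(submodels[[i]]$reactions[[j]]$id, u$target)) {
            submodels[[i]]$reactions[[j]]$enabled <- u$value
          }
        }
      }
    }
  }
  list(submodels = submodels, parameters = parameters)
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat("Whole-cell trajectory (", x$mode, " mode): ",
      length(x$times), " recorded states over [0, ",
      format(max(x$times)), "] s, ", ncol(x$counts), " species\n", sep = "")
  d <- x$diagnostics
  if (nrow(d)) {
    cat(sprintf("  %d committed steps; dt range [%g, %g]; %d redos; %d scaled-at-floor commits\n",
                nrow(d), min(d$dt), max(d$dt), sum(d$retries), sum(d$scaled_at_floor)))
  }
  invisible(x)
}

#' @export
summary.wc_trajectory <- function(object, ...) {
  final <- object$counts[nrow(object$counts), ]
  out <- data.frame(species = colnames(object$counts),
                    initial = object$counts[1, ],
                    final = final,
                    min = apply(object$counts, 2, min),
                    max = apply(object$counts, 2, max),
                    row.names = NULL)
  out
}

#' @export
as.data.frame.wc_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$counts, check.names = FALSE)
}

#' Plot species trajectories
#'
#' @param x A `wc_trajectory`.
#' @param species Character vector of species ids to plot (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.wc_trajectory <- function(x, species = colnames(x$counts), ...) {
  m <- x$counts[, species, drop = FALSE]
  graphics::matplot(x$times, m, type = "s", lty = 1,
                    xlab = "time (s)", ylab = "molecule count", ...)
  graphics::legend("topright", legend = species, col = seq_len(ncol(m)),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
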