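# Counter-based random substreams.
#
# Every stochastic draw in a simulation is made under a seed derived by
# hashing (master seed, submodel id, step index, retry index). Because the
# substream depends only on those labels, and never on how many draws other
# submodels have made, the order in which submodels are invoked cannot
# perturb anyone's random numbers, and a redone step (retry index bumped)
# gets fresh, independent draws from the same snapshot.

# 32-bit-safe polynomial string hash; exact in double arithmetic since
# 2147483647 * 31 + 255 < 2^53.
.wc_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a substream seed
#'
#' @param master Master simulation seed (integer).
#' @param submodel_id Submodel identifier.
#' @param step Step index (1-based).
#' @param retry Retry index within the step (0 for the first attempt).
#' @return An integer seed below 2^31.
#' @keywords internal
stream_seed <- function(master, submodel_id, step = 0L, retry = 0L) {
  .wc_hash(master, submodel_id, step, retry)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
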