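# Boolean regulatory rules: synchronous evaluation of threshold predicates
# over a state snapshot. Effects touch parameters and reaction enablement
# only — never species counts — so the controller's request arbitration
# remains the sole writer of the global pool. Updates emitted in step k
# take effect in the snapshot of step k+1.

#' Define a Boolean regulatory rule
#'
#' The condition is a string over a restricted grammar: comparisons of a
#' single species count or parameter against a numeric constant, using
#' `<`, `<=`, `>`, `>=`, `==`, combined with `&`, `|`, `!` and parentheses.
#' Comparison at an exact threshold follows the declared operator with no
#' epsilon smudging (counts are integers). The effect either sets a model
#' parameter to a fixed value or enables/disables a reaction.
#'
#' @param id Rule identifier.
#' @param condition Condition string, e.g. `"RNA1_c < 10 & RNA2_c < 10"`.
#' @param effect Either `list(parameter = "k_deg", value = 0)` or
#'   `list(reaction = "deg1", enabled = FALSE)`.
#' @return An object of class `wc_boolean_rule`.
#' @export
boolean_rule <- function(id, condition, effect) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(condition), length(condition) == 1L)
  .check_condition_ast(str2lang(condition))   # fail fast on bad grammar
  ok_param <- !is.null(effect$parameter) && !is.null(effect$value)
  ok_rxn <- !is.null(effect$reaction) && !is.null(effect$enabled)
  if (!xor(ok_param, ok_rxn)) {
    stop("rule '", id, "': effect must set exactly one of a parameter value ",
         "or a reaction enablement", call. = FALSE)
  }
  structure(list(id = id, condition = condition, effect = effect),
            class = "wc_boolean_rule")
}

.CMP_OPS <- c("<", "<=", ">", ">=", "==")
.BOOL_OPS <- c("&", "|", "&&", "||")

.check_condition_ast <- function(e) {
  if (is.numeric(e) || is.logical(e) || is.symbol(e)) return(invisible(TRUE))
  if (!is.call(e)) stop("unsupported token in rule condition", call. = FALSE)
  op <- as.character(e[[1]])
  if (op == "(") return(.check_condition_ast(e[[2]]))
  if (op == "!") return(.check_condition_ast(e[[2]]))
  if (op %in% .BOOL_OPS) {
    .check_condition_ast(e[[2]])
    .check_condition_ast(e[[3]])
    return(invisible(TRUE))
  }
  if (op %in% .CMP_OPS) {
    lhs <- e[[2]]; rhs <- e[[3]]
    ok <- (is.symbol(lhs) && is.numeric(rhs)) || (is.numeric(lhs) && is.symbol(rhs))
    if (!ok) {
      stop("rule comparisons must be <identifier> <op> <constant>", call. = FALSE)
    }
    return(invisible(TRUE))
  }
  stop("operator '", op, "' not allowed in rule conditions", call. = FALSE)
}

condition_identifiers <- function(condition) {
  e <- str2lang(condition)
  .check_condition_ast(e)
  collect <- function(x) {
    if (is.symbol(x)) return(as.character(x))
    if (is.call(x)) return(unlist(lapply(as.list(x)[-1], collect)))
    character(0)
  }
  unique(collect(e))
}

#' Evaluate Boolean rules against a snapshot
#'
#' All conditions are evaluated against the same snapshot (synchronous
#' update): permuting rule order can never change the resulting update set.
#' Effects of rules whose condition holds are returned as parameter /
#' enablement updates; the caller applies them at commit time so they take
#' effect in the next step's snapshot. Two true rules targeting the same
#' parameter or reaction with different values are a conflict and raise an
#' error naming both rules; agreeing duplicates collapse to one update.
#'
#' @param snapshot A [wc_snapshot()].
#' @param rules List of [boolean_rule()].
#' @return List of updates, each `list(type, target, value, rule)` with
#'   `type` in `{"parameter", "reaction"}`.
#' @export
evaluate_rules <- function(snapshot, rules) {
  if (length(rules) == 0L) return(list())
  env <- list2env(c(as.list(snapshot$counts), as.list(snapshot$parameters)),
                  parent = baseenv())
  updates <- list()
  for (rule in rules) {
    val <- eval(str2lang(rule$condition), envir = env)
    if (!isTRUE(val)) next
    eff <- rule$effect
    if (!is.null(eff$parameter)) {
      upd <- list(type = "parameter", target = eff$parameter,
                  value = as.numeric(eff$value), rule = rule$id)
    } else {
      upd <- list(type = "reaction", target = eff$reaction,
                  value = isTRUE(eff$enabled), rule = rule$id)
    }
    key <- paste0(upd$type, ":", upd$target)
    if (!is.null(updates[[key]])) {
      if (!identical(updates[[key]]$value, upd$value)) {
        stop("conflicting rule effects on ", upd$type, " '", upd$target,
             "' from rules '", updates[[key]]$rule, "' and '", rule$id, "'",
             call. = FALSE)
      }
    } else {
      updates[[key]] <- upd
    }
  }
  unname(updates)
}
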