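#' Build a plan from timestamped labels
#'
#' A plan is an ordered sequence of (timestamp, ground label) pairs; it is
#' the causal reading of an annotation tier.
#'
#' @param time_ms Integer timestamps in milliseconds, non-decreasing.
#' @param label Ground labels, same length.
#' @return A `data.frame` of class `semannot_plan` with columns `time_ms`
#'   and `label`.
#' @export
plan_steps <- function(time_ms, label) {
  stopifnot(length(time_ms) == length(label))
  if (is.unsorted(time_ms))
    stop("plan timestamps must be non-decreasing", call. = FALSE)
  out <- data.frame(time_ms = as.numeric(time_ms),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("semannot_plan", "data.frame")
  out
}

#' Validate an annotated label sequence as a plan
#'
#' Steps through the plan from the domain's initial state, checking each
#' action's precondition and applying its effects.  If every step is
#' applicable the verdict is `"valid"` and the full state trajectory is
#' returned; otherwise the verdict is `"invalid"` with the first failing
#' step, the violated sub-expression, and the values of the fluents that
#' sub-expression mentions.  Validation stops at the first failure because
#' the state after an impossible action is undefined.
#'
#' A label that does not resolve to any ground action of the domain is a
#' different kind of problem (a vocabulary error, not a causal one) and is
#' raised as an R error naming the step.
#'
#' An invalid verdict has two possible causes which only a human can tell
#' apart: the domain model may be too strict for the behaviour that really
#' occurred, or the label sequence may describe an impossible behaviour.
#' The report's `note` says so; nothing is auto-repaired.
#'
#' @param domain A `semannot_domain`.
#' @param plan A `semannot_plan` (see [plan_steps()], [tier_to_plan()]).
#' @param horizon Optional run duration in ms (defaults to the last
#'   timestamp); stored on the trajectory for time-normalised summaries.
#' @return A list of class `semannot_validation` with elements `report`
#'   (verdict, failing step, failed condition, state excerpt, note) and
#'   `trajectory` (a `state_trajectory`: initial state plus one successor
#'   state per validated step).
#' @examples
#' dom <- parse_domain(semannot_example("domains/toy_kitchen.dom"))
#' plan <- plan_steps(c(0, 2000), c("take-knife-drawer", "put-knife-board"))
#' v <- validate_plan(dom, plan)
#' v$report$verdict
#' query_property(v$trajectory, "is-at(knife)")
#' @export
validate_plan <- function(domain, plan, horizon = NULL) {
  grounds <- ground_actions(domain)
  idx <- ground_action_index(grounds)
  n <- nrow(plan)
  missing <- which(!(plan$label %in% names(idx)))
  if (length(missing) > 0)
    stop("unresolvable label(s): ",
         paste(sprintf("'%s' at step %d", plan$label[missing], missing),
               collapse = ", "), call. = FALSE)

  states <- vector("list", n + 1L)
  states[[1L]] <- domain$init
  classes <- character(n)
  report <- list(verdict = "valid", failing_step = NULL,
                 failed_condition = NULL, failed_label = NULL,
                 state_excerpt = NULL, note = NULL)
  k <- n
  for (i in seq_len(n)) {
    ga <- grounds[[idx[[plan$label[i]]]]]
    classes[i] <- ga$class
    viol <- first_violation(ga$pre_ground, states[[i]])
    if (!is.null(viol)) {
      keys <- expr_term_keys(viol)
      report <- list(
        verdict = "invalid",
        failing_step = i,
        failed_label = ga$label,
        failed_condition = deparse_ground_expr(viol),
        state_excerpt = states[[i]][keys],
        note = paste("Unsatisfied precondition: either the domain model is",
                     "stricter than the real setting, or the label sequence",
                     "describes an impossible behaviour.  Inspect the",
                     "annotation at this step first; if it is correct,",
                     "relax the domain."))
      k <- i - 1L
      break
    }
    states[[i + 1L]] <- ga$eff(states[[i]])
  }
  traj <- structure(list(
    states = states[seq_len(k + 1L)],
    times = plan$time_ms[seq_len(k)],
    labels = plan$label[seq_len(k)],
    classes = classes[seq_len(k)],
    duration = if (!is.null(horizon)) horizon
               else if (n > 0) plan$time_ms[n] else 0),
    class = "state_trajectory")
  structure(list(report = report, trajectory = traj),
            class = "semannot_validation")
}

#' @export
print.semannot_validation <- function(x, ...) {
  r <- x$report
  if (r$verdict == "valid") {
    cat("valid plan:", length(x$trajectory$labels), "step(s)\n")
  } else {
    cat("invalid plan at step ", r$failing_step, " ('", r$failed_label,
        "')\n  failed condition: ", r$failed_condition, "\n", sep = "")
    for (k in names(r$state_excerpt))
      cat("    ", k, " = ", format(r$state_excerpt[[k]]), "\n", sep = "")
  }
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param validation A `semannot_validation` (or its `report` element).
#' @param path Optional output path.
#' @return JSON string, invisibly if written to `path`.
#' @export
report_json <- function(validation, path = NULL) {
  r <- if (inherits(validation, "semannot_validation")) validation$report
       else validation
  r$state_excerpt <- lapply(r$state_excerpt, function(v)
    if (is.numeric(v)) v else as.character(v))
  js <- jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Track one ground fluent term through a trajectory
#'
#' Returns the value of the term after every step, including the initial
#' state (step 0) -- this is how object locations and counters can be read
#' off an annotation without ever having been stated explicitly.
#'
#' @param trajectory A `state_trajectory` from [validate_plan()].
#' @param term Ground fluent term key, e.g. `"is-at(knife)"` or
#'   `"objects_taken()"`.
#' @return Vector of values, length `length(trajectory$states)`.
#' @export
query_property <- function(trajectory, term) {
  if (!(term %in% names(trajectory$states[[1L]])))
    stop("unknown fluent term '", term, "'", call. = FALSE)
  vals <- lapply(trajectory$states, `[[`, term)
  unlist(vals, use.names = FALSE)
}

# state active at absolute time t (piecewise-constant between action times)
state_at_time <- function(trajectory, t) {
  i <- sum(trajectory$times <= t)
  trajectory$states[[i + 1L]]
}
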