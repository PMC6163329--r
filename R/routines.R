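# Routine mining from validated plans.  Because every input plan has been
# checked against the precondition/effect model, everything mined here is
# causally correct by construction: a Markov edge exists only if the two
# actions really followed each other in a validated run.

#' First-order Markov model of action successions
#'
#' Counts transitions between consecutive actions over a set of validated
#' plans, with pseudo-states `initial` (before the first action) and
#' `finish` (after the last), and row-normalises into maximum-likelihood
#' transition probabilities.  No smoothing is applied: a zero is
#' meaningful, it marks a succession never observed -- and, since only
#' validated plans enter, any succession that is causally impossible can
#' never acquire mass.
#'
#' @param plans List of validated plans: either `semannot_validation`
#'   objects, `state_trajectory` objects, or plain data.frames with a
#'   `label` column (assumed validated by the caller).
#' @param level `"class"` collapses ground labels to action classes;
#'   `"ground"` keeps full labels.
#' @return A list of class `transition_model`: `states`, `counts`
#'   (state x state integer matrix) and `probs` (row-normalised; rows with
#'   zero outgoing count are all-zero).
#' @export
build_markov <- function(plans, level = c("class", "ground")) {
  level <- match.arg(level)
  if (length(plans) == 0) stop("empty plan list", call. = FALSE)
  seqs <- lapply(plans, function(p) {
    if (inherits(p, "semannot_validation")) p <- p$trajectory
    if (inherits(p, "state_trajectory")) {
      if (level == "class") p$classes else p$labels
    } else {
      if (level == "class") label_class(p$label) else p$label
    }
  })
  states <- c("initial",
              sort(unique(unlist(seqs)), method = "radix"),
              "finish")
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  for (s in seqs) {
    path <- c("initial", s, "finish")
    for (i in seq_len(length(path) - 1L))
      counts[path[i], path[i + 1L]] <- counts[path[i], path[i + 1L]] + 1L
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(states = states, counts = counts, probs = probs),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("first-order transition model:", length(x$states), "states,",
      nz, "observed transitions\n")
  invisible(x)
}

#' Export a transition model as Graphviz DOT
#'
#' Edge pen width is proportional to the transition probability; the edge
#' label shows the raw count.
#'
#' @param model A `transition_model`.
#' @param path Optional output path.
#' @param min_prob Drop edges below this probability (default 0: keep all
#'   observed edges).
#' @return Character vector of DOT lines, invisibly when written.
#' @export
markov_dot <- function(model, path = NULL, min_prob = 0) {
  lines <- c("digraph routines {", "  rankdir=LR;",
             "  node [shape=ellipse];")
  for (from in model$states) for (to in model$states) {
    cnt <- model$counts[from, to]
    p <- model$probs[from, to]
    if (cnt > 0 && p >= min_prob)
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [penwidth=%.2f, label=\"%d\"];",
        from, to, 0.5 + 4 * p, cnt))
  }
  lines <- c(lines, "}")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Transition model as an edge table
#'
#' @param model A `transition_model`.
#' @return data.frame with columns `from`, `to`, `count`, `prob` (observed
#'   edges only).
#' @export
markov_edges <- function(model) {
  idx <- which(model$counts > 0, arr.ind = TRUE)
  out <- data.frame(from = model$states[idx[, 1]],
                    to = model$states[idx[, 2]],
                    count = model$counts[idx],
                    prob = model$probs[idx],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to, method = "radix"), , drop = FALSE]
}

#' Probability of a state property over normalised run time
#'
#' For each of `bins` equal bins of every run's own duration, gives the
#' fraction of runs in which the predicate `term == value` holds (each run
#' sampled at the bin midpoint of its piecewise-constant state).  Runs of
#' different lengths are thereby aligned on a common 0..1 time axis.
#'
#' @param trajectories List of `state_trajectory` objects (or
#'   `semannot_validation`s) with positive duration.
#' @param term Ground fluent term key, e.g. `"contains(bowl,water)"`.
#' @param value Value the term is compared against (entity name, number or
#'   logical).
#' @param bins Number of normalised-time bins (default 100).
#' @return A list of class `property_curve`: `term`, `value`, `time`
#'   (bin midpoints in 0..1), `probability`, `n_runs`.
#' @export
property_curve <- function(trajectories, term, value, bins = 100) {
  if (length(trajectories) == 0) stop("need at least one run", call. = FALSE)
  trajectories <- lapply(trajectories, function(t)
    if (inherits(t, "semannot_validation")) t$trajectory else t)
  durs <- vapply(trajectories, `[[`, numeric(1), "duration")
  if (any(durs <= 0)) stop("zero-duration run", call. = FALSE)
  mids <- (seq_len(bins) - 0.5) / bins
  holds <- vapply(trajectories, function(tr) {
    vapply(mids * tr$duration, function(t) {
      v <- state_at_time(tr, t)[[term]]
      if (is.null(v)) stop("unknown fluent term '", term, "'", call. = FALSE)
      isTRUE(v == value)
    }, logical(1))
  }, logical(bins))
  structure(list(term = term, value = value, time = mids,
                 probability = rowMeans(matrix(holds, nrow = bins)),
                 n_runs = length(trajectories)),
            class = "property_curve")
}

#' @export
print.property_curve <- function(x, ...) {
  cat(sprintf("P(%s = %s) over %d runs: %.2f at start, %.2f at end\n",
              x$term, format(x$value), x$n_runs,
              x$probability[1], x$probability[length(x$probability)]))
  invisible(x)
}

#' Write a property curve as CSV
#'
#' @param curve A `property_curve`.
#' @param path Output path.
#' @export
curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time = curve$time,
                              probability = curve$probability),
                   path, row.names = FALSE)
  invisible(path)
}

#' Initial-state table across runs
#'
#' Extracts the step-0 value of each listed fluent term per run, in run
#' order, and flags the runs where any listed value differs from the
#' previous run -- the signature of a changed experimental setup (objects
#' relocated between recordings).  Comparison is exact; no statistics.
#'
#' @param runs List of `state_trajectory` / `semannot_validation` objects,
#'   or of `semannot_domain`s (whose initial state is then used).
#' @param terms Character vector of ground fluent term keys.
#' @param run_ids Optional run labels (row names).
#' @return data.frame with one column per term plus a logical `changed`
#'   column (first run is `FALSE`).
#' @export
initial_state_table <- function(runs, terms, run_ids = NULL) {
  if (length(runs) == 0) stop("need at least one run", call. = FALSE)
  state0 <- function(r) {
    if (inherits(r, "semannot_validation")) r <- r$trajectory
    if (inherits(r, "state_trajectory")) r$states[[1]]
    else if (inherits(r, "semannot_domain")) r$init
    else stop("runs must be trajectories or domains", call. = FALSE)
  }
  states <- lapply(runs, state0)
  for (tm in terms)
    if (!(tm %in% names(states[[1]])))
      stop("fluent term '", tm, "' not declared", call. = FALSE)
  cols <- lapply(terms, function(tm)
    unlist(lapply(states, `[[`, tm), use.names = FALSE))
  names(cols) <- terms
  out <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  changed <- logical(length(runs))
  if (length(runs) > 1)
    for (i in 2:length(runs))
      changed[i] <- any(vapply(terms, function(tm)
        !identical(states[[i]][[tm]], states[[i - 1]][[tm]]), logical(1)))
  out$changed <- changed
  rownames(out) <- if (!is.null(run_ids)) run_ids else
    sprintf("run%02d", seq_along(runs))
  out
}

#' Object location timeline
#'
#' Reads each object's location fluent off a validated trajectory and
#' compresses it to a step function: one `(time, location)` entry per
#' change, starting with the initial location at the run start.
#'
#' @param trajectory A `state_trajectory` (or `semannot_validation`).
#' @param objects Character vector of entity names.
#' @param fluent Name of the entity-valued location fluent (default
#'   `"is-at"`).
#' @return Named list of data.frames with columns `time_ms` and
#'   `location`.
#' @export
location_timeline <- function(trajectory, objects, fluent = "is-at") {
  if (inherits(trajectory, "semannot_validation"))
    trajectory <- trajectory$trajectory
  out <- lapply(objects, function(obj) {
    key <- term_key(fluent, obj)
    if (!(key %in% names(trajectory$states[[1]])))
      stop("object '", obj, "' has no '", fluent, "' fluent", call. = FALSE)
    vals <- query_property(trajectory, key)
    times <- c(0, trajectory$times)
    keep <- c(TRUE, vals[-1] != vals[-length(vals)])
    data.frame(time_ms = times[keep], location = vals[keep],
               stringsAsFactors = FALSE)
  })
  names(out) <- objects
  out
}
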