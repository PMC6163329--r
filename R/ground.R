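# Grounding: instantiate action schemas over all type-correct entity
# bindings.  Each ground action carries compiled precondition/effect
# closures (fast path, used by applicability scans and the plan sampler)
# plus the ground expression tree (slow path, used for diagnostics when a
# step fails).

#' Ground every action schema of a domain
#'
#' Produces the full set of ground actions: one per type-correct binding of
#' each schema's parameters, in deterministic order (schema declaration
#' order, then lexicographic by argument tuple).
#'
#' @param domain A `semannot_domain`.
#' @return A list of ground actions; each has `label`, `class` (the schema
#'   name), `binding`, and internal evaluator closures.
#' @keywords internal
#' @export
ground_actions <- function(domain) {
  out <- list()
  for (si in seq_along(domain$schemas)) {
    sc <- domain$schemas[[si]]
    pnames <- names(sc$params)
    cand <- lapply(pnames, function(p)
      sort(entities_of_type(domain, sc$params[[p]]), method = "radix"))
    if (any(lengths(cand) == 0) && length(pnames) > 0) next
    bindings <- if (length(pnames) == 0) list(character(0)) else {
      grid <- expand.grid(rev(cand), stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(cand)), drop = FALSE]
      names(grid) <- pnames
      lapply(seq_len(nrow(grid)), function(r) {
        b <- as.character(grid[r, ])
        names(b) <- pnames
        b
      })
    }
    for (b in bindings) {
      label <- instantiate_label(sc$tokens, sc$name, b)
      out[[length(out) + 1L]] <- list(
        label = label,
        class = sc$name,
        schema = si,
        binding = b,
        pre = compile_expr(sc$precondition, b),
        eff = compile_effects(sc$effect, b),
        pre_ground = ground_expr(sc$precondition, b),
        eff_ground = ground_effects(sc$effect, b))
    }
  }
  out
}

instantiate_label <- function(tokens, name, binding) {
  if (length(tokens) == 0) return(name)
  paste(vapply(tokens, function(t)
    if (t$kind == "lit") t$value else unname(binding[[t$name]]),
    character(1)), collapse = "-")
}

# ---- binding substitution ---------------------------------------------------

bound_term_key <- function(term, binding) {
  args <- vapply(term$args, function(a)
    if (a$kind == "var") unname(binding[[a$name]]) else as.character(a$value),
    character(1))
  term_key(term$fluent, args)
}

# a parameter used where a number is needed must name an integer entity
# (multiplicity tokens such as the "1" in take-1-egg_shell-counter)
bound_numeric <- function(rhs, binding) {
  v <- unname(binding[[rhs$name]])
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num))
    stop("grounding error: parameter '", rhs$name, "' bound to entity '", v,
         "' where a number is required", call. = FALSE)
  num
}

ground_rhs <- function(rhs, binding, numeric = FALSE) {
  switch(rhs$kind,
    const = list(kind = "const", value = rhs$value),
    var = if (numeric)
            list(kind = "const", value = bound_numeric(rhs, binding))
          else list(kind = "const", value = unname(binding[[rhs$name]])),
    term = list(kind = "term", key = bound_term_key(rhs$term, binding)))
}

ground_expr <- function(expr, binding) {
  switch(expr$kind,
    true = expr,
    and = list(kind = "and", args = lapply(expr$args, ground_expr, binding)),
    not = list(kind = "not", arg = ground_expr(expr$arg, binding)),
    cmp = list(kind = "cmp", op = expr$op,
               key = bound_term_key(expr$term, binding),
               rhs = ground_rhs(expr$rhs, binding,
                                numeric = expr$term$range == "number")))
}

ground_effects <- function(effects, binding) {
  lapply(effects, function(e) list(
    op = e$op,
    key = bound_term_key(e$term, binding),
    value = ground_rhs(e$value, binding,
                       numeric = e$term$range == "number")))
}

# ---- compiled evaluators ----------------------------------------------------

compile_expr <- function(expr, binding) {
  g <- ground_expr(expr, binding)
  compile_ground_expr(g)
}

compile_ground_expr <- function(g) {
  switch(g$kind,
    true = function(state) TRUE,
    and = {
      fns <- lapply(g$args, compile_ground_expr)
      function(state) {
        for (f in fns) if (!f(state)) return(FALSE)
        TRUE
      }
    },
    not = {
      f <- compile_ground_expr(g$arg)
      function(state) !f(state)
    },
    cmp = {
      key <- g$key
      if (g$rhs$kind == "term") {
        key2 <- g$rhs$key
        switch(g$op,
          "="  = function(state) state[[key]] == state[[key2]],
          "<"  = function(state) state[[key]] <  state[[key2]],
          "<=" = function(state) state[[key]] <= state[[key2]],
          ">=" = function(state) state[[key]] >= state[[key2]],
          ">"  = function(state) state[[key]] >  state[[key2]])
      } else {
        val <- g$rhs$value
        switch(g$op,
          "="  = function(state) identical(state[[key]], val) ||
                   (is.numeric(val) && is.numeric(state[[key]]) &&
                    state[[key]] == val),
          "<"  = function(state) state[[key]] <  val,
          "<=" = function(state) state[[key]] <= val,
          ">=" = function(state) state[[key]] >= val,
          ">"  = function(state) state[[key]] >  val)
      }
    })
}

compile_effects <- function(effects, binding) {
  items <- ground_effects(effects, binding)
  function(state) {
    for (it in items) {
      v <- if (it$value$kind == "term") state[[it$value$key]] else it$value$value
      state[[it$key]] <- switch(it$op,
        assign = v,
        increase = state[[it$key]] + v,
        decrease = state[[it$key]] - v)
    }
    state
  }
}

# ---- diagnostics ------------------------------------------------------------

deparse_ground_expr <- function(g) {
  switch(g$kind,
    true = "(and)",
    and = paste0("(and ", paste(vapply(g$args, deparse_ground_expr,
                                       character(1)), collapse = " "), ")"),
    not = paste0("(not ", deparse_ground_expr(g$arg), ")"),
    cmp = {
      term <- gsub(",", " ", sub("\\)$", "", sub("\\(", " ", g$key)))
      rhs <- if (g$rhs$kind == "term")
        paste0("(", gsub(",", " ", sub("\\)$", "", sub("\\(", " ", g$rhs$key))), ")")
      else if (is.logical(g$rhs$value)) (if (g$rhs$value) "true" else "false")
      else as.character(g$rhs$value)
      paste0("(", g$op, " (", trimws(term), ") ", rhs, ")")
    })
}

expr_term_keys <- function(g) {
  switch(g$kind,
    true = character(0),
    and = unique(unlist(lapply(g$args, expr_term_keys))),
    not = expr_term_keys(g$arg),
    cmp = c(g$key, if (g$rhs$kind == "term") g$rhs$key))
}

# evaluate a ground expression, returning NULL if satisfied or the first
# violated sub-expression (innermost leaf for conjunctions; the negation
# itself when a (not ...) is violated)
first_violation <- function(g, state) {
  switch(g$kind,
    true = NULL,
    and = {
      for (a in g$args) {
        v <- first_violation(a, state)
        if (!is.null(v)) return(v)
      }
      NULL
    },
    not = if (is.null(first_violation(g$arg, state))) g else NULL,
    cmp = if (compile_ground_expr(g)(state)) NULL else g)
}

# ---- user-facing operations -------------------------------------------------

#' Initial state of a domain
#'
#' @param domain A `semannot_domain`.
#' @return Named list mapping every ground fluent term to its initial value.
#' @export
initial_state <- function(domain) domain$init

#' Ground actions applicable in a state
#'
#' Returns exactly those ground actions whose precondition evaluates to true
#' in the given state.
#'
#' @param domain A `semannot_domain`.
#' @param state A state (named list over ground fluent terms), e.g.
#'   [initial_state()].
#' @param grounds Optional precomputed [ground_actions()] list (an
#'   optimisation for repeated scans).
#' @return A list of ground actions; `applicable_labels()` returns just
#'   their labels.
#' @examples
#' dom <- parse_domain(semannot_example("domains/toy_kitchen.dom"))
#' applicable_labels(dom, initial_state(dom))
#' @export
applicable_actions <- function(domain, state, grounds = NULL) {
  if (is.null(grounds)) grounds <- ground_actions(domain)
  Filter(function(ga) ga$pre(state), grounds)
}

#' @rdname applicable_actions
#' @export
applicable_labels <- function(domain, state, grounds = NULL) {
  vapply(applicable_actions(domain, state, grounds), `[[`, character(1),
         "label")
}

#' Apply a ground action to a state
#'
#' Checks the action's precondition and applies its effects; every fluent
#' not written by an effect is unchanged (frame assumption).
#'
#' @param domain A `semannot_domain`.
#' @param state A state (named list over ground fluent terms).
#' @param action A ground action (from [ground_actions()] or
#'   [applicable_actions()]) or a ground label.
#' @param grounds Optional precomputed [ground_actions()] list.
#' @return The successor state.
#' @examples
#' dom <- parse_domain(semannot_example("domains/toy_kitchen.dom"))
#' s1 <- apply_action(dom, initial_state(dom), "take-knife-drawer")
#' s1[["objects_taken()"]]
#' @export
apply_action <- function(domain, state, action, grounds = NULL) {
  if (is.character(action)) {
    if (is.null(grounds)) grounds <- ground_actions(domain)
    action <- resolve_label(grounds, action)
  }
  viol <- first_violation(action$pre_ground, state)
  if (!is.null(viol))
    stop("precondition violated for '", action$label, "': ",
         deparse_ground_expr(viol), call. = FALSE)
  action$eff(state)
}

# label -> ground action lookup; first grounding wins on duplicate labels
resolve_label <- function(grounds, label) {
  for (ga in grounds) if (ga$label == label) return(ga)
  stop("unresolvable label '", label, "': not in the domain's label set",
       call. = FALSE)
}

ground_action_index <- function(grounds) {
  labels <- vapply(grounds, `[[`, character(1), "label")
  idx <- seq_along(grounds)[!duplicated(labels)]  # first occurrence wins
  names(idx) <- labels[!duplicated(labels)]
  idx
}
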