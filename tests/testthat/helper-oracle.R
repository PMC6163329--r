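# An independent brute-force simulator used as oracle for the plan engine:
# nested-loop grounding and direct interpretation of the parsed expression
# trees, sharing no evaluation code with the package's compiled path.

oracle_subtype <- function(dom, type, super) {
  repeat {
    if (is.na(type)) return(FALSE)
    if (type == super) return(TRUE)
    type <- dom$types[[type]]
  }
}

oracle_entities <- function(dom, type) {
  keep <- c()
  for (e in names(dom$entities))
    if (oracle_subtype(dom, dom$entities[[e]], type)) keep <- c(keep, e)
  keep
}

# all bindings of a schema via explicit recursion over parameters
oracle_bindings <- function(dom, schema) {
  pnames <- names(schema$params)
  recur <- function(i, acc) {
    if (i > length(pnames)) return(list(acc))
    cands <- sort(oracle_entities(dom, schema$params[[pnames[i]]]))
    out <- list()
    for (e in cands) {
      acc2 <- acc
      acc2[[pnames[i]]] <- e
      out <- c(out, recur(i + 1, acc2))
    }
    out
  }
  recur(1, list())
}

oracle_label <- function(schema, binding) {
  parts <- strsplit(schema$label_template, "-", fixed = TRUE)[[1]]
  for (j in seq_along(parts)) {
    if (grepl("^\\{", parts[j])) {
      role <- paste0("?", gsub("[{}]", "", parts[j]))
      parts[j] <- binding[[role]]
    }
  }
  paste(parts, collapse = "-")
}

oracle_term_key <- function(term, binding) {
  args <- character(length(term$args))
  for (k in seq_along(term$args)) {
    a <- term$args[[k]]
    args[k] <- if (a$kind == "var") binding[[a$name]] else as.character(a$value)
  }
  paste0(term$fluent, "(", paste(args, collapse = ","), ")")
}

oracle_rhs_value <- function(rhs, binding, state, numeric) {
  if (rhs$kind == "const") return(rhs$value)
  if (rhs$kind == "term") return(state[[oracle_term_key(rhs$term, binding)]])
  v <- binding[[rhs$name]]
  if (numeric) as.numeric(v) else v
}

oracle_eval <- function(expr, binding, state) {
  if (expr$kind == "true") return(TRUE)
  if (expr$kind == "and") {
    for (a in expr$args) if (!oracle_eval(a, binding, state)) return(FALSE)
    return(TRUE)
  }
  if (expr$kind == "not") return(!oracle_eval(expr$arg, binding, state))
  lhs <- state[[oracle_term_key(expr$term, binding)]]
  rhs <- oracle_rhs_value(expr$rhs, binding, state,
                          numeric = expr$term$range == "number")
  if (expr$op == "=") {
    if (is.numeric(lhs)) return(lhs == rhs)
    return(identical(lhs, rhs))
  }
  switch(expr$op,
         "<" = lhs < rhs, "<=" = lhs <= rhs,
         ">=" = lhs >= rhs, ">" = lhs > rhs)
}

oracle_apply <- function(dom, schema, binding, state) {
  for (e in schema$effect) {
    key <- oracle_term_key(e$term, binding)
    v <- oracle_rhs_value(e$value, binding, state,
                          numeric = e$term$range == "number")
    state[[key]] <- switch(e$op,
                           assign = v,
                           increase = state[[key]] + v,
                           decrease = state[[key]] - v)
  }
  state
}

# every applicable (schema index, binding, label) in a state
oracle_applicable <- function(dom, state) {
  out <- list()
  for (si in seq_along(dom$schemas)) {
    sc <- dom$schemas[[si]]
    for (b in oracle_bindings(dom, sc)) {
      if (oracle_eval(sc$precondition, b, state))
        out[[length(out) + 1]] <- list(schema = si, binding = b,
                                       label = oracle_label(sc, b))
    }
  }
  out
}

# ---- random domain generator (flat types, guaranteed well-formed) ----------

random_domain_text <- function(seed) {
  set.seed(seed)
  n_types <- sample(2:3, 1)
  types <- paste0("t", seq_len(n_types))
  ents <- lapply(types, function(t) paste0(t, "e", seq_len(sample(1:6, 1))))
  names(ents) <- types
  tA <- sample(types, 1); tB <- sample(types, 1); tC <- sample(types, 1)

  obj_lines <- vapply(types, function(t)
    paste0(paste(ents[[t]], collapse = " "), " - ", t), character(1))
  init <- c(
    vapply(ents[[tA]], function(e)
      sprintf("(= (floc %s) %s)", e, sample(ents[[tB]], 1)), character(1)),
    sprintf("(= (gnum) %d)", sample(0:2, 1)),
    vapply(ents[[tC]], function(e)
      sprintf("(= (bflag %s) %s)", e, sample(c("true", "false"), 1)),
      character(1)))

  n_schemas <- sample(1:5, 1)
  schemas <- vapply(seq_len(n_schemas), function(i) {
    k <- sample(0:2, 1)
    roles <- if (k > 0) paste0("?p", seq_len(k)) else character(0)
    ptypes <- if (k > 0) sample(types, k, replace = TRUE) else character(0)
    pick_arg <- function(need_type) {
      ok <- which(ptypes == need_type)
      if (length(ok) > 0 && stats::runif(1) < 0.6)
        roles[ok[sample.int(length(ok), 1)]]
      else ents[[need_type]][sample.int(length(ents[[need_type]]), 1)]
    }
    conjuncts <- character(0)
    for (j in seq_len(sample(0:3, 1))) {
      kind <- sample(1:3, 1)
      c_j <- if (kind == 1)
        sprintf("(= (floc %s) %s)", pick_arg(tA), pick_arg(tB))
      else if (kind == 2)
        sprintf("(%s (gnum) %d)", sample(c("<", "<=", ">=", ">"), 1),
                sample(0:3, 1))
      else
        sprintf("(= (bflag %s) %s)", pick_arg(tC),
                sample(c("true", "false"), 1))
      if (stats::runif(1) < 0.25) c_j <- sprintf("(not %s)", c_j)
      conjuncts <- c(conjuncts, c_j)
    }
    effects <- character(0)
    written <- character(0)
    for (j in seq_len(sample(0:2, 1))) {
      kind <- sample(1:3, 1)
      # at most one write per fluent so that no grounding can ever write
      # the same ground term twice
      if (kind == 1) {
        if ("floc" %in% written) next
        written <- c(written, "floc")
        effects <- c(effects, sprintf("(assign (floc %s) %s)", pick_arg(tA),
                                      pick_arg(tB)))
      } else if (kind == 2) {
        if ("gnum" %in% written) next
        written <- c(written, "gnum")
        effects <- c(effects, sprintf("(%s (gnum) 1)",
                                      sample(c("increase", "decrease"), 1)))
      } else {
        if ("bflag" %in% written) next
        written <- c(written, "bflag")
        effects <- c(effects, sprintf("(assign (bflag %s) %s)", pick_arg(tC),
                                      sample(c("true", "false"), 1)))
      }
    }
    label_parts <- paste0("a", i)
    for (r in roles)
      label_parts <- c(label_parts, paste0("{", sub("\\?", "", r), "}"))
    label <- paste(label_parts, collapse = "-")
    paste0("  (:action a", i, "\n",
           "    :parameters (",
           paste(mapply(function(r, t) paste(r, "-", t), roles, ptypes),
                 collapse = " "), ")\n",
           "    :precondition (and ", paste(conjuncts, collapse = " "), ")\n",
           "    :effect (and ", paste(effects, collapse = " "), ")\n",
           "    :label \"", label, "\")")
  }, character(1))

  c("(define (domain rnd)",
    paste0("  (:types ", paste(types, collapse = " "), " - object)"),
    paste0("  (:objects ", paste(obj_lines, collapse = " "), ")"),
    paste0("  (:functions (floc ?a - ", tA, ") - ", tB,
           " (gnum) - number (bflag ?a - ", tC, ") - boolean)"),
    paste0("  (:init ", paste(init, collapse = " "), ")"),
    schemas,
    ")")
}

# walk a random domain for a few steps, comparing package vs oracle at
# every state; returns invisibly, failing via expect_* on divergence
compare_with_oracle <- function(seed, n_steps = 4) {
  dom <- parse_domain(random_domain_text(seed))
  grounds <- ground_actions(dom)
  state_pkg <- initial_state(dom)
  state_orc <- initial_state(dom)
  for (step in seq_len(n_steps)) {
    app_pkg <- applicable_actions(dom, state_pkg, grounds)
    app_orc <- oracle_applicable(dom, state_orc)
    lab_pkg <- sort(vapply(app_pkg, `[[`, character(1), "label"))
    lab_orc <- sort(vapply(app_orc, function(x) x$label, character(1)))
    testthat::expect_identical(lab_pkg, lab_orc,
                               info = sprintf("seed %d step %d", seed, step))
    if (length(app_pkg) == 0) break
    pick <- sample.int(length(app_pkg), 1)
    ga <- app_pkg[[pick]]
    state_pkg <- ga$eff(state_pkg)
    orc <- app_orc[[match(ga$label, vapply(app_orc, function(x) x$label,
                                           character(1)))]]
    state_orc <- oracle_apply(dom, dom$schemas[[orc$schema]], orc$binding,
                              state_orc)
    testthat::expect_equal(state_pkg[sort(names(state_pkg))],
                           state_orc[sort(names(state_orc))],
                           info = sprintf("seed %d step %d", seed, step))
  }
  invisible(TRUE)
}
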