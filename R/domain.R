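#' Parse a behaviour domain file
#'
#' Reads a domain written in the package's s-expression dialect (a strict
#' subset of PDDL with typed objects and object/numeric/boolean fluents) and
#' returns a fully validated domain model.  The domain defines the semantic
#' structure behind an annotation vocabulary: entity types (a forest --
#' every type may name one parent), entities, fluents (functions from entity
#' tuples to an entity, a number, or a truth value), an initial state, and
#' action schemas with preconditions, effects and a printable label
#' template.
#'
#' The dialect is:
#' ```
#' (define (domain NAME)
#'   (:types t1 t2 - parent ...)
#'   (:objects a b - type ...)
#'   (:functions (fname ?p - type ...) - rangetype ...)
#'   (:init (= (fname args) value) ...)
#'   (:action NAME
#'     :parameters (?x - type ...)
#'     :precondition (and ...)
#'     :effect (and ...)
#'     :label "class-{x}-{y}"))
#' ```
#' Preconditions are built from `and`, `not`, equality of a fluent term with
#' a constant or parameter, and numeric comparison (`<`, `<=`, `=`, `>=`,
#' `>`) of a numeric fluent term with a constant, a parameter or another
#' numeric term.  Effects are `assign`, `increase`, `decrease`.  A bare
#' fluent term used as a condition abbreviates `(= term true)`.
#'
#' Boolean fluent instances missing from `:init` default to `false`; numeric
#' instances default to `0`; entity-valued instances must be assigned
#' explicitly (an error lists any that are not).
#'
#' @param text Domain file content as a character vector (lines or a single
#'   string), or a file path to read from.
#' @return An object of class `semannot_domain` with elements `name`,
#'   `types` (named parent vector), `entities` (named type vector),
#'   `fluents`, `schemas` and `init` (named list keyed by ground term,
#'   e.g. `"is-at(knife)"`).
#' @seealso [enumerate_labels()], [write_domain()], [validate_plan()]
#' @examples
#' dom <- parse_domain(semannot_example("domains/toy_kitchen.dom"))
#' dom$init[["is-at(knife)"]]
#' @export
parse_domain <- function(text) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  forms <- sexp_parse(text)
  if (length(forms) != 1 || sexp_is_atom(forms[[1]]))
    stop("domain file must contain exactly one (define ...) form", call. = FALSE)
  form <- forms[[1]]
  if (!identical(sexp_atom(form[[1]]), "define"))
    stop("expected (define ...)", sexp_where(form), call. = FALSE)
  head <- form[[2]]
  if (sexp_is_atom(head) || !identical(sexp_atom(head[[1]]), "domain"))
    stop("expected (domain NAME)", sexp_where(head), call. = FALSE)
  dom <- list(name = sexp_atom(head[[2]]),
              types = c(object = NA_character_),
              entities = character(0),
              fluents = list(),
              schemas = list(),
              init = list())
  class(dom) <- "semannot_domain"

  sections <- form[-(1:2)]
  for (sec in sections) {
    key <- sexp_atom(sec[[1]])
    dom <- switch(key,
      ":types"     = parse_types(dom, sec),
      ":objects"   = parse_objects(dom, sec),
      ":functions" = parse_functions(dom, sec),
      ":init"      = parse_init_section(dom, sec),
      ":action"    = parse_action(dom, sec),
      stop("unknown section '", key, "'", sexp_where(sec), call. = FALSE))
  }
  dom$init <- complete_initial_state(dom)
  dom
}

# ---- section parsers --------------------------------------------------------

# shared by :types and :objects:  name name - group  name - group ...
parse_typed_list <- function(items, what) {
  atoms <- vapply(items, function(x) {
    if (!sexp_is_atom(x))
      stop("expected a name in ", what, " list", sexp_where(x), call. = FALSE)
    sexp_atom(x)
  }, character(1))
  out <- list()
  pending <- character(0)
  i <- 1L
  while (i <= length(atoms)) {
    if (atoms[i] == "-") {
      if (i == length(atoms) || length(pending) == 0)
        stop("dangling '-' in ", what, " list", call. = FALSE)
      out[[length(out) + 1L]] <- list(names = pending, group = atoms[i + 1L])
      pending <- character(0)
      i <- i + 2L
    } else {
      pending <- c(pending, atoms[i])
      i <- i + 1L
    }
  }
  if (length(pending) > 0)
    out[[length(out) + 1L]] <- list(names = pending, group = "object")
  out
}

parse_types <- function(dom, sec) {
  for (grp in parse_typed_list(sec[-1], ":types")) {
    for (nm in grp$names) {
      if (nm %in% names(dom$types))
        stop("semantic error: type '", nm, "' declared twice", call. = FALSE)
      dom$types[nm] <- grp$group
    }
  }
  # parents must exist (forward references resolved now); cycles impossible
  # because each parent must already be declared or be 'object'
  for (nm in names(dom$types)) {
    p <- dom$types[[nm]]
    if (!is.na(p) && !(p %in% names(dom$types)))
      stop("semantic error: unknown parent type '", p, "' of '", nm, "'",
           call. = FALSE)
  }
  dom
}

parse_objects <- function(dom, sec) {
  for (grp in parse_typed_list(sec[-1], ":objects")) {
    if (!(grp$group %in% names(dom$types)))
      stop("semantic error: unknown type '", grp$group, "'", call. = FALSE)
    for (nm in grp$names) {
      if (grepl("-", nm, fixed = TRUE))
        stop("semantic error: entity name '", nm,
             "' may not contain '-' (reserved as the label separator)",
             call. = FALSE)
      if (nm %in% names(dom$entities))
        stop("semantic error: entity '", nm, "' declared twice", call. = FALSE)
      dom$entities[nm] <- grp$group
    }
  }
  dom
}

parse_functions <- function(dom, sec) {
  items <- sec[-1]
  i <- 1L
  while (i <= length(items)) {
    sig <- items[[i]]
    if (sexp_is_atom(sig))
      stop("expected a fluent signature", sexp_where(sig), call. = FALSE)
    if (i + 2L > length(items) || !identical(sexp_atom(items[[i + 1L]]), "-"))
      stop("fluent signature must be followed by '- rangetype'",
           sexp_where(sig), call. = FALSE)
    range <- sexp_atom(items[[i + 2L]])
    fname <- sexp_atom(sig[[1]])
    params <- character(0)
    j <- 2L
    while (j <= length(sig)) {
      v <- sexp_atom(sig[[j]])
      if (is.null(v) || !startsWith(v, "?"))
        stop("fluent parameter must be ?name", sexp_where(sig), call. = FALSE)
      if (j + 2L > length(sig) || !identical(sexp_atom(sig[[j + 1L]]), "-"))
        stop("fluent parameter '", v, "' must be typed", call. = FALSE)
      ptype <- sexp_atom(sig[[j + 2L]])
      if (!(ptype %in% names(dom$types)))
        stop("semantic error: unknown type '", ptype, "' in fluent '", fname,
             "'", call. = FALSE)
      params <- c(params, ptype)
      j <- j + 3L
    }
    if (!(range %in% c("number", "boolean")) && !(range %in% names(dom$types)))
      stop("semantic error: unknown range type '", range, "' of fluent '",
           fname, "'", call. = FALSE)
    if (fname %in% names(dom$fluents))
      stop("semantic error: fluent '", fname, "' declared twice", call. = FALSE)
    dom$fluents[[fname]] <- list(name = fname, params = params, range = range)
    i <- i + 3L
  }
  dom
}

parse_init_section <- function(dom, sec) {
  for (fact in sec[-1]) {
    if (sexp_is_atom(fact))
      stop("init fact must be a list", sexp_where(fact), call. = FALSE)
    if (identical(sexp_atom(fact[[1]]), "=")) {
      term <- parse_ground_term(dom, fact[[2]])
      val <- parse_value(dom, fact[[3]], range_of(dom, term$fluent))
      dom$init[[term_key(term$fluent, term$args)]] <- val
    } else {
      term <- parse_ground_term(dom, fact)
      if (range_of(dom, term$fluent) != "boolean")
        stop("semantic error: bare init fact '", term$fluent,
             "' is not boolean", call. = FALSE)
      dom$init[[term_key(term$fluent, term$args)]] <- TRUE
    }
  }
  dom
}

parse_ground_term <- function(dom, x) {
  if (sexp_is_atom(x)) stop("expected a fluent term", sexp_where(x), call. = FALSE)
  fname <- sexp_atom(x[[1]])
  fl <- dom$fluents[[fname]]
  if (is.null(fl))
    stop("semantic error: unknown fluent '", fname, "'", sexp_where(x),
         call. = FALSE)
  args <- vapply(x[-1], sexp_atom, character(1))
  check_term_args(dom, fl, args)
  list(fluent = fname, args = args)
}

check_term_args <- function(dom, fl, args, param_types = NULL) {
  if (length(args) != length(fl$params))
    stop("semantic error: fluent '", fl$name, "' takes ", length(fl$params),
         " argument(s), got ", length(args), call. = FALSE)
  for (k in seq_along(args)) {
    a <- args[[k]]
    atype <- if (startsWith(a, "?")) param_types[[a]] else dom$entities[[a]]
    if (is.null(atype) || is.na(atype))
      stop("semantic error: unknown ",
           if (startsWith(a, "?")) "parameter '" else "entity '", a,
           "' in term of fluent '", fl$name, "'", call. = FALSE)
    if (!is_subtype(dom, atype, fl$params[[k]]))
      stop("semantic error: argument '", a, "' of fluent '", fl$name,
           "' has type '", atype, "', expected '", fl$params[[k]], "'",
           call. = FALSE)
  }
}

parse_value <- function(dom, x, range) {
  v <- sexp_atom(x)
  if (is.null(v)) stop("expected a value", sexp_where(x), call. = FALSE)
  if (range == "boolean") {
    if (v %in% c("true", "false")) return(v == "true")
    stop("semantic error: boolean fluent assigned '", v, "'", call. = FALSE)
  }
  if (range == "number") {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num))
      stop("semantic error: numeric fluent assigned '", v, "'", call. = FALSE)
    return(num)
  }
  etype <- dom$entities[[v]]
  if (is.null(etype))
    stop("semantic error: unknown entity '", v, "'", call. = FALSE)
  if (!is_subtype(dom, etype, range))
    stop("semantic error: entity '", v, "' of type '", etype,
         "' assigned to fluent with range '", range, "'", call. = FALSE)
  v
}

parse_action <- function(dom, sec) {
  items <- sec[-1]
  name <- sexp_atom(items[[1]])
  fields <- list()
  i <- 2L
  while (i <= length(items)) {
    key <- sexp_atom(items[[i]])
    if (is.null(key) || !startsWith(key, ":"))
      stop("expected :keyword in action '", name, "'", call. = FALSE)
    fields[[key]] <- items[[i + 1L]]
    i <- i + 2L
  }
  params <- list()  # role -> type
  if (!is.null(fields[[":parameters"]])) {
    for (grp in parse_typed_list(fields[[":parameters"]], ":parameters")) {
      if (!(grp$group %in% names(dom$types)))
        stop("semantic error: unknown type '", grp$group, "' in action '",
             name, "'", call. = FALSE)
      for (nm in grp$names) {
        if (!startsWith(nm, "?"))
          stop("semantic error: parameter '", nm, "' of action '", name,
               "' must start with '?'", call. = FALSE)
        params[[nm]] <- grp$group
      }
    }
  }
  pre <- if (is.null(fields[[":precondition"]]))
           list(kind = "and", args = list())   # empty conjunction: true
         else parse_expr(dom, fields[[":precondition"]], params)
  eff <- if (is.null(fields[[":effect"]])) list()
         else parse_effects(dom, fields[[":effect"]], params)
  # one write per ground term: detectable statically when args are equal
  eff_keys <- vapply(eff, function(e)
    term_key(e$term$fluent, vapply(e$term$args, node_id, character(1))),
    character(1))
  if (anyDuplicated(eff_keys))
    stop("semantic error: action '", name, "' writes fluent term '",
         eff_keys[duplicated(eff_keys)][1], "' twice", call. = FALSE)
  lbl <- fields[[":label"]]
  if (is.null(lbl)) lbl <- name
  label_template <- as.vector(sexp_atom(lbl))
  tokens <- parse_label_template(label_template, names(params), name)
  dom$schemas[[length(dom$schemas) + 1L]] <-
    list(name = name, params = params, precondition = pre, effect = eff,
         label_template = label_template, tokens = tokens)
  dom
}

parse_label_template <- function(template, param_names, action) {
  parts <- strsplit(template, "-", fixed = TRUE)[[1]]
  tokens <- lapply(parts, function(p) {
    if (grepl("^\\{.+\\}$", p)) {
      nm <- paste0("?", substr(p, 2, nchar(p) - 1))
      if (!(nm %in% param_names))
        stop("semantic error: label of action '", action,
             "' references unknown parameter '", nm, "'", call. = FALSE)
      list(kind = "param", name = nm)
    } else list(kind = "lit", value = p)
  })
  seen <- vapply(Filter(function(t) t$kind == "param", tokens),
                 `[[`, character(1), "name")
  if (anyDuplicated(seen))
    stop("semantic error: label of action '", action,
         "' references a parameter twice", call. = FALSE)
  tokens
}

# ---- expressions ------------------------------------------------------------

# argument node inside a (possibly lifted) fluent term
arg_node <- function(dom, a, params) {
  if (startsWith(a, "?")) {
    if (is.null(params[[a]]))
      stop("semantic error: unknown parameter '", a, "'", call. = FALSE)
    list(kind = "var", name = a)
  } else {
    if (is.null(dom$entities[[a]]) )
      stop("semantic error: unknown entity '", a, "'", call. = FALSE)
    list(kind = "const", value = a)
  }
}

node_id <- function(nd) if (nd$kind == "var") nd$name else as.character(nd$value)

parse_term <- function(dom, x, params) {
  if (sexp_is_atom(x)) stop("expected a fluent term", sexp_where(x), call. = FALSE)
  fname <- sexp_atom(x[[1]])
  fl <- dom$fluents[[fname]]
  if (is.null(fl))
    stop("semantic error: unknown fluent '", fname, "'", sexp_where(x),
         call. = FALSE)
  raw <- vapply(x[-1], sexp_atom, character(1))
  args <- lapply(raw, function(a) arg_node(dom, a, params))
  check_term_args(dom, fl, as.list(raw), param_types = params)
  list(fluent = fname, args = args, range = fl$range)
}

# right-hand side of a comparison: constant, parameter, or numeric term
parse_rhs <- function(dom, x, params, range, numeric_op) {
  if (!sexp_is_atom(x)) {
    if (!numeric_op)
      stop("semantic error: fluent-valued right-hand side only allowed in ",
           "numeric comparisons", call. = FALSE)
    t2 <- parse_term(dom, x, params)
    if (t2$range != "number")
      stop("semantic error: numeric comparison against non-numeric fluent '",
           t2$fluent, "'", call. = FALSE)
    return(list(kind = "term", term = t2))
  }
  v <- sexp_atom(x)
  if (startsWith(v, "?")) {
    ptype <- params[[v]]
    if (is.null(ptype))
      stop("semantic error: unknown parameter '", v, "'", call. = FALSE)
    if (!numeric_op && !(range %in% c("number", "boolean")) &&
        !is_subtype(dom, ptype, range))
      stop("semantic error: parameter '", v, "' of type '", ptype,
           "' compared with fluent of range '", range, "'", call. = FALSE)
    return(list(kind = "var", name = v))
  }
  list(kind = "const", value = parse_value(dom, x, range))
}

parse_expr <- function(dom, x, params) {
  if (sexp_is_atom(x))
    stop("expected an expression", sexp_where(x), call. = FALSE)
  head <- sexp_atom(x[[1]])
  if (identical(head, "and"))
    return(list(kind = "and", args = lapply(x[-1], parse_expr, dom = dom,
                                            params = params)))
  if (identical(head, "not"))
    return(list(kind = "not", arg = parse_expr(dom, x[[2]], params = params)))
  if (head %in% c("=", "<", "<=", ">=", ">")) {
    term <- parse_term(dom, x[[2]], params)
    numeric_op <- head != "="
    if (numeric_op && term$range != "number")
      stop("semantic error: '", head, "' applied to non-numeric fluent '",
           term$fluent, "'", call. = FALSE)
    rhs <- parse_rhs(dom, x[[3]], params, term$range,
                     numeric_op || term$range == "number")
    return(list(kind = "cmp", op = head, term = term, rhs = rhs))
  }
  # bare boolean fluent term
  term <- parse_term(dom, x, params)
  if (term$range != "boolean")
    stop("semantic error: bare condition on non-boolean fluent '",
         term$fluent, "'", call. = FALSE)
  list(kind = "cmp", op = "=", term = term,
       rhs = list(kind = "const", value = TRUE))
}

parse_effects <- function(dom, x, params) {
  head <- sexp_atom(x[[1]])
  if (identical(head, "and"))
    return(unlist(lapply(x[-1], parse_effects, dom = dom, params = params),
                  recursive = FALSE))
  if (!(head %in% c("assign", "increase", "decrease")))
    stop("semantic error: unknown effect '", head, "'", sexp_where(x),
         call. = FALSE)
  term <- parse_term(dom, x[[2]], params)
  if (head %in% c("increase", "decrease") && term$range != "number")
    stop("semantic error: '", head, "' applied to non-numeric fluent '",
         term$fluent, "'", call. = FALSE)
  rhs <- parse_rhs(dom, x[[3]], params, term$range,
                   term$range == "number")
  list(list(op = head, term = term, value = rhs))
}

# ---- type and term helpers --------------------------------------------------

is_subtype <- function(dom, type, super) {
  while (!is.na(type)) {
    if (type == super) return(TRUE)
    type <- dom$types[[type]]
    if (is.null(type)) return(FALSE)
  }
  FALSE
}

entities_of_type <- function(dom, type) {
  nm <- names(dom$entities)
  nm[vapply(nm, function(e) is_subtype(dom, dom$entities[[e]], type),
            logical(1))]
}

range_of <- function(dom, fname) dom$fluents[[fname]]$range

term_key <- function(fluent, args) {
  paste0(fluent, "(", paste(args, collapse = ","), ")")
}

#' @export
print.semannot_domain <- function(x, ...) {
  cat("Behaviour domain '", x$name, "'\n", sep = "")
  cat("  types:    ", length(x$types) - 1L, "\n", sep = "")
  cat("  entities: ", length(x$entities), "\n", sep = "")
  cat("  fluents:  ", length(x$fluents), "\n", sep = "")
  cat("  schemas:  ", length(x$schemas), " (",
      length(unique(vapply(x$schemas, `[[`, character(1), "name"))),
      " action classes)\n", sep = "")
  cat("  initial state: ", length(x$init), " ground fluents\n", sep = "")
  invisible(x)
}

# every type-correct ground instance of every declared fluent
ground_fluent_keys <- function(dom) {
  out <- character(0)
  ranges <- character(0)
  for (fl in dom$fluents) {
    cand <- lapply(fl$params, function(t) sort(entities_of_type(dom, t)))
    if (length(cand) == 0) {
      out <- c(out, term_key(fl$name, character(0)))
      ranges <- c(ranges, fl$range)
    } else {
      grid <- expand.grid(rev(cand), stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(cand)), drop = FALSE]
      keys <- apply(grid, 1, function(r) term_key(fl$name, r))
      out <- c(out, keys)
      ranges <- c(ranges, rep(fl$range, length(keys)))
    }
  }
  names(ranges) <- out
  ranges
}

# fill in defaults and reject unassigned entity-valued fluents
complete_initial_state <- function(dom) {
  ranges <- ground_fluent_keys(dom)
  init <- dom$init
  unknown <- setdiff(names(init), names(ranges))
  if (length(unknown) > 0)
    stop("semantic error: initial state assigns undeclared term '",
         unknown[1], "'", call. = FALSE)
  missing <- setdiff(names(ranges), names(init))
  for (k in missing) {
    r <- ranges[[k]]
    if (r == "boolean") init[[k]] <- FALSE
    else if (r == "number") init[[k]] <- 0
    else stop("semantic error: entity-valued fluent term '", k,
              "' has no initial value", call. = FALSE)
  }
  init[order(names(init))]
}

#' Enumerate the annotation vocabulary of a domain
#'
#' Instantiates every action schema's label template with all type-correct
#' entity bindings and returns the resulting ground labels -- the finite
#' label set an annotator chooses from.  Order is deterministic: schemas in
#' declaration order, bindings lexicographic by argument tuple; duplicates
#' are removed keeping the first occurrence.
#'
#' @param domain A `semannot_domain`.
#' @return Character vector of ground labels.
#' @examples
#' dom <- parse_domain(semannot_example("domains/toy_kitchen.dom"))
#' enumerate_labels(dom)
#' @export
enumerate_labels <- function(domain) {
  ga <- ground_actions(domain)
  unique(vapply(ga, `[[`, character(1), "label"))
}

#' Serialise a domain back to its file dialect
#'
#' Writes a parsed domain as text; re-parsing the output yields an equal
#' domain (defaulted boolean/numeric initial values become explicit).
#'
#' @param domain A `semannot_domain`.
#' @param path Optional path; if `NULL` the text is returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_domain <- function(domain, path = NULL) {
  fmt_val <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    as.character(v)
  }
  lines <- c(sprintf("(define (domain %s)", domain$name))
  tnames <- setdiff(names(domain$types), "object")
  if (length(tnames) > 0)
    lines <- c(lines, paste0("  (:types ",
      paste(vapply(tnames, function(t)
        paste(t, "-", domain$types[[t]]), character(1)), collapse = " "),
      ")"))
  if (length(domain$entities) > 0)
    lines <- c(lines, paste0("  (:objects ",
      paste(vapply(names(domain$entities), function(e)
        paste(e, "-", domain$entities[[e]]), character(1)), collapse = " "),
      ")"))
  if (length(domain$fluents) > 0) {
    sig <- vapply(domain$fluents, function(fl) {
      ps <- if (length(fl$params) == 0) "" else
        paste0(" ", paste(sprintf("?x%d - %s", seq_along(fl$params), fl$params),
                          collapse = " "))
      sprintf("(%s%s) - %s", fl$name, ps, fl$range)
    }, character(1))
    lines <- c(lines, paste0("  (:functions ", paste(sig, collapse = " "), ")"))
  }
  if (length(domain$init) > 0) {
    facts <- vapply(names(domain$init), function(k) {
      term <- sub("\\)$", "", k)
      term <- sub("\\(", " ", term)
      term <- gsub(",", " ", term, fixed = TRUE)
      sprintf("(= (%s) %s)", trimws(term), fmt_val(domain$init[[k]]))
    }, character(1))
    lines <- c(lines, "  (:init", paste0("    ", facts), "  )")
  }
  for (sc in domain$schemas)
    lines <- c(lines, write_schema(sc))
  lines <- c(lines, ")")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

write_schema <- function(sc) {
  fmt_arg <- function(a) if (a$kind == "var") a$name else as.character(a$value)
  fmt_term <- function(t)
    paste0("(", paste(c(t$fluent, vapply(t$args, fmt_arg, character(1))),
                      collapse = " "), ")")
  fmt_rhs <- function(r) switch(r$kind,
    var = r$name,
    term = fmt_term(r$term),
    const = if (is.logical(r$value)) (if (r$value) "true" else "false")
            else as.character(r$value))
  fmt_expr <- function(e) switch(e$kind,
    true = "(and)",
    and = paste0("(and ", paste(vapply(e$args, fmt_expr, character(1)),
                                collapse = " "), ")"),
    not = paste0("(not ", fmt_expr(e$arg), ")"),
    cmp = paste0("(", e$op, " ", fmt_term(e$term), " ", fmt_rhs(e$rhs), ")"))
  params <- if (length(sc$params) == 0) "()" else
    paste0("(", paste(vapply(names(sc$params), function(p)
      paste(p, "-", sc$params[[p]]), character(1)), collapse = " "), ")")
  effs <- vapply(sc$effect, function(e)
    paste0("(", e$op, " ", fmt_term(e$term), " ", fmt_rhs(e$value), ")"),
    character(1))
  eff_str <- if (length(effs) == 0) "(and)" else
    paste0("(and ", paste(effs, collapse = " "), ")")
  c(sprintf("  (:action %s", sc$name),
    sprintf("    :parameters %s", params),
    sprintf("    :precondition %s", fmt_expr(sc$precondition)),
    sprintf("    :effect %s", eff_str),
    sprintf("    :label \"%s\")", sc$label_template))
}

#' Path to a packaged example file
#'
#' @param name Relative path under the package's `extdata` directory, e.g.
#'   `"domains/brownie.dom"`.  With no argument, lists available files.
#' @return A file path (or a character vector of relative paths).
#' @export
semannot_example <- function(name = NULL) {
  base <- system.file("extdata", package = "semannot")
  if (is.null(name))
    return(dir(base, recursive = TRUE))
  path <- file.path(base, name)
  if (!file.exists(path))
    stop("no packaged example '", name, "'", call. = FALSE)
  path
}
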