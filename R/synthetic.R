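# Synthetic study generator.  Emulates what a small annotated kitchen study
# looks like -- a toy domain, causally valid plans sampled by forward
# search, log-normal segment durations, and a two-annotator corruption
# model (boundary jitter + label confusion) -- so that every other module
# is testable without external recordings.

#' Generator configuration
#'
#' Bundles every knob of the synthetic study generator.  The seed fully
#' determines the output; one global random stream is drawn per seed (no
#' per-operation seeds).
#'
#' @param seed Integer seed.
#' @param n_runs Number of runs for [gen_study()].
#' @param max_plan_length Maximum actions per sampled plan.
#' @param dur_meanlog,dur_sdlog Log-normal segment duration model, in log
#'   milliseconds.  Defaults `log(2000)` and `0.75`: a right-skewed
#'   distribution with median 2 s, the scale of fine-grained kitchen
#'   actions.
#' @param jitter_sd Gaussian boundary jitter (ms) for [corrupt_tier()].
#' @param confusion_rate Per-segment probability that the second annotator
#'   writes a different (co-typed) label.
#' @param relocation_run Optional run index from which the initial object
#'   placement changes (emulates a mid-study setup change).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_runs = 10L, max_plan_length = 30L,
                             dur_meanlog = log(2000), dur_sdlog = 0.75,
                             jitter_sd = 0, confusion_rate = 0,
                             relocation_run = NULL) {
  stopifnot(confusion_rate >= 0, confusion_rate <= 1, jitter_sd >= 0,
            max_plan_length >= 1)
  structure(list(seed = as.integer(seed), n_runs = as.integer(n_runs),
                 max_plan_length = as.integer(max_plan_length),
                 dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog,
                 jitter_sd = jitter_sd, confusion_rate = confusion_rate,
                 relocation_run = relocation_run),
            class = "generator_config")
}

#' Packaged toy kitchen domains
#'
#' Returns one of the three packaged recipe domains.  Their action-class
#' dictionaries are fixed: 11 classes for `brownie` (open, close, take,
#' put, walk, turn_on, fill, clean, stir, shake, other), 12 for `eggs`
#' (adds turn_off) and 12 for `sandwich` (adds cut); 13 classes in the
#' union.  Entity sets are small kitchen inventories.
#'
#' @param flavour `"brownie"`, `"eggs"` or `"sandwich"`.
#' @return A `semannot_domain`.
#' @examples
#' length(unique(vapply(gen_toy_domain("brownie")$schemas,
#'                      `[[`, character(1), "name")))
#' @export
gen_toy_domain <- function(flavour = c("brownie", "eggs", "sandwich")) {
  flavour <- match.arg(flavour)
  parse_domain(semannot_example(file.path("domains",
                                          paste0(flavour, ".dom"))))
}

# draw from the global stream (callers seed it)
gen_plan_impl <- function(domain, config, grounds = NULL, run_id = "run",
                          t0 = 0) {
  if (is.null(grounds)) grounds <- ground_actions(domain)
  state <- domain$init
  labels <- character(0)
  repeat {
    if (length(labels) >= config$max_plan_length) break
    app <- applicable_actions(domain, state, grounds)
    if (length(app) == 0) {
      if (length(labels) == 0)
        stop("dead-end initial state: no action applicable", call. = FALSE)
      break
    }
    ga <- app[[sample.int(length(app), 1L)]]
    labels <- c(labels, ga$label)
    state <- ga$eff(state)
  }
  n <- length(labels)
  durs <- pmax(1, round(stats::rlnorm(n, config$dur_meanlog,
                                      config$dur_sdlog)))
  starts <- t0 + cumsum(c(0, durs[-n]))
  tier <- annotation_tier(starts, starts + durs, labels,
                          run_id = run_id, annotator_id = "A")
  list(plan = plan_steps(starts, labels), tier = tier)
}

#' Sample a causally valid plan and its timed tier
#'
#' Builds a plan by repeatedly sampling uniformly from the actions
#' applicable in the current state (forward search with no goal bias),
#' until `max_plan_length` actions or a dead end.  Segment durations are
#' drawn from the log-normal duration model; the resulting tier is
#' gap-free and, by construction, always validates.
#'
#' @param domain A `semannot_domain`.
#' @param config A [generator_config()]; its seed determines the output.
#' @param run_id Run identifier for the tier.
#' @return A list with elements `plan` (a `semannot_plan`) and `tier` (an
#'   [annotation_tier()], annotator `"A"`).
#' @export
gen_plan <- function(domain, config = generator_config(), run_id = "run") {
  withr::with_seed(config$seed,
                   gen_plan_impl(domain, config, run_id = run_id))
}

corrupt_tier_impl <- function(tier, config, domain = NULL) {
  seg <- tier$segments
  n <- nrow(seg)
  if (n == 0) return(tier)
  bounds <- c(seg$start[1], seg$end)
  if (config$jitter_sd > 0 && n > 1) {
    inner <- bounds[2:n] + stats::rnorm(n - 1, 0, config$jitter_sd)
    inner <- sort(pmin(pmax(round(inner), bounds[1] + 1),
                       bounds[n + 1] - 1))
    # enforce strictly increasing boundaries after clipping
    for (i in seq_along(inner)[-1])
      if (inner[i] <= inner[i - 1]) inner[i] <- inner[i - 1] + 1
    inner <- pmin(inner, bounds[n + 1] - rev(seq_len(n - 1)))
    bounds <- c(bounds[1], inner, bounds[n + 1])
  }
  labels <- seg$label
  if (config$confusion_rate > 0) {
    vocab <- if (!is.null(domain)) enumerate_labels(domain)
             else unique(labels)
    cls <- label_class(vocab)
    flip <- stats::runif(n) < config$confusion_rate
    for (i in which(flip)) {
      cand <- vocab[cls == label_class(labels[i]) & vocab != labels[i]]
      if (length(cand) == 0) cand <- setdiff(vocab, labels[i])
      if (length(cand) > 0)
        labels[i] <- cand[sample.int(length(cand), 1L)]
    }
  }
  annotation_tier(bounds[-(n + 1)], bounds[-1], labels,
                  run_id = tier$run_id, annotator_id = "B")
}

#' Corrupt a tier into a second annotator's version
#'
#' Emulates the two systematic ways real annotators disagree: segment
#' boundaries are perturbed by Gaussian noise (`jitter_sd`, clipped so the
#' segment order and the overall span are preserved) and each label is
#' independently replaced, with probability `confusion_rate`, by a
#' different label of the same action class (drawn from the domain's label
#' set when a domain is supplied, otherwise from the tier's own labels).
#'
#' @param tier An [annotation_tier()].
#' @param config A [generator_config()] (uses `seed`, `jitter_sd`,
#'   `confusion_rate`).
#' @param domain Optional `semannot_domain` supplying the label vocabulary
#'   for confusions.
#' @return A new tier with `annotator_id = "B"`.
#' @export
corrupt_tier <- function(tier, config = generator_config(), domain = NULL) {
  withr::with_seed(config$seed, corrupt_tier_impl(tier, config, domain))
}

# deterministically relocate one object to emulate a setup change:
# the first (alphabetically) entity assigned by the first single-parameter
# entity-valued fluent moves to the next admissible location
relocate_domain <- function(domain) {
  for (fl in domain$fluents) {
    if (fl$range %in% c("number", "boolean") || length(fl$params) != 1) next
    objs <- sort(entities_of_type(domain, fl$params[1]), method = "radix")
    locs <- sort(entities_of_type(domain, fl$range), method = "radix")
    if (length(objs) == 0 || length(locs) < 2) next
    obj <- objs[1]
    key <- term_key(fl$name, obj)
    cur <- domain$init[[key]]
    alt <- setdiff(locs, c(cur, "hands"))
    if (length(alt) == 0) next
    domain$init[[key]] <- alt[1]
    return(domain)
  }
  domain
}

#' Generate a full synthetic annotation study
#'
#' Draws `n_runs` runs from one random stream seeded by `config$seed`:
#' each run gets a sampled plan, annotator A's gap-free tier, and
#' annotator B's corrupted tier.  If `relocation_run` is set, runs from
#' that index onwards start from a deterministically altered initial state
#' (one object relocated), emulating a mid-study setup change.
#'
#' @param domain A `semannot_domain` (e.g. [gen_toy_domain()]).
#' @param config A [generator_config()].
#' @return A list of runs; each is a list with `run_id`, `domain`, `plan`,
#'   `tier_a`, `tier_b`.
#' @export
gen_study <- function(domain, config = generator_config()) {
  # grounding depends only on schemas and entities, so it can be shared
  # between the original and the relocated variant of the domain
  grounds <- ground_actions(domain)
  reloc <- if (!is.null(config$relocation_run)) relocate_domain(domain)
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_runs), function(i) {
      run_id <- sprintf("S%02d", i)
      relocated <- !is.null(config$relocation_run) &&
        i >= config$relocation_run
      dom_i <- if (relocated) reloc else domain
      gen <- gen_plan_impl(dom_i, config, grounds = grounds,
                           run_id = run_id)
      tier_b <- corrupt_tier_impl(gen$tier, config, domain = dom_i)
      list(run_id = run_id, domain = dom_i, plan = gen$plan,
           tier_a = gen$tier, tier_b = tier_b)
    })
  })
}
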