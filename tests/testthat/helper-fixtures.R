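# Shared fixtures: packaged domains and small inline domain builders.

toy_kitchen <- function() {
  parse_domain(semannot_example("domains/toy_kitchen.dom"))
}

table5_tier <- function() {
  read_tier(semannot_example("annotation/brownie_S09_extract.tsv"),
            format = "elan-tsv", run_id = "S09")
}

# n takeables x m locations, take + put only
grid_domain_text <- function(n_takeable, m_location) {
  c("(define (domain grid)",
    "  (:types takeable location - object)",
    paste0("  (:objects ", paste0("o", seq_len(n_takeable), collapse = " "),
           " - takeable ",
           paste0("l", seq_len(m_location), collapse = " "),
           " - location hands - location)"),
    "  (:functions (is-at ?w - takeable) - location",
    "              (objects_taken) - number)",
    paste0("  (:init ",
           paste(sprintf("(= (is-at o%d) l1)", seq_len(n_takeable)),
                 collapse = " "),
           " (= (objects_taken) 0))"),
    "  (:action take",
    "    :parameters (?what - takeable ?from - location)",
    "    :precondition (and (= (is-at ?what) ?from) (< (objects_taken) 3))",
    "    :effect (and (assign (is-at ?what) hands)",
    "                 (increase (objects_taken) 1))",
    "    :label \"take-{what}-{from}\")",
    "  (:action put",
    "    :parameters (?what - takeable ?to - location)",
    "    :precondition (= (is-at ?what) hands)",
    "    :effect (and (assign (is-at ?what) ?to)",
    "                 (decrease (objects_taken) 1))",
    "    :label \"put-{what}-{to}\")",
    ")")
}

# a tier covering [0, sum(durs)) with the given labels, gap-free
quick_tier <- function(labels, durs = rep(1000, length(labels)),
                       run_id = "run", annotator_id = "A") {
  starts <- cumsum(c(0, durs[-length(durs)]))
  annotation_tier(starts, starts + durs, labels, run_id = run_id,
                  annotator_id = annotator_id)
}

# two one-label tiers over [0, horizon) agreeing on exactly `frac` of it
tier_pair_with_agreement <- function(frac, horizon = 1000, run_id = "run") {
  cut <- round(frac * horizon)
  a <- annotation_tier(0, horizon, "x", run_id = run_id, annotator_id = "A")
  b <- if (cut == horizon) {
    annotation_tier(0, horizon, "x", run_id = run_id, annotator_id = "B")
  } else {
    annotation_tier(c(0, cut), c(cut, horizon), c("x", "y"),
                    run_id = run_id, annotator_id = "B")
  }
  list(a, b)
}
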