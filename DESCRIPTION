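Package: semannot
Title: Model-Based Semantic Annotation of Goal-Directed Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for creating, validating and exploring semantic annotation
    of goal-directed human behaviour. Timestamped action labels are treated as
    grounded plan operators of a typed precondition/effect domain model, so an
    annotation can be checked for causal validity, the evolving world state can
    be simulated from the labels alone, interrater reliability between two
    annotators can be scored on a common time base (raw agreement, Cohen's
    kappa, Krippendorff's alpha), and causally-correct behavioural routines
    (first-order Markov models, state-property probability curves, initial
    state tables, object location timelines) can be mined from validated
    plans. Includes a synthetic study generator (toy kitchen domains, random
    forward-sampled plans, a two-annotator corruption model) and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
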