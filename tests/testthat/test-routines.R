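validated <- function(dom, labels, times = NULL, horizon = NULL) {
  if (is.null(times)) times <- seq(0, by = 1000,
                                   length.out = length(labels))
  v <- validate_plan(dom, plan_steps(times, labels), horizon = horizon)
  stopifnot(v$report$verdict == "valid")
  v
}

test_that("a single plan yields a chain with unit probabilities", {
  dom <- toy_kitchen()
  v <- validated(dom, c("take-knife-drawer", "put-knife-board"))
  m <- build_markov(list(v), level = "class")
  expect_identical(m$states, c("initial", "put", "take", "finish"))
  expect_identical(m$probs["initial", "take"], 1)
  expect_identical(m$probs["take", "put"], 1)
  expect_identical(m$probs["put", "finish"], 1)
  expect_identical(sum(m$counts), 3L)
})

test_that("transition probabilities are maximum-likelihood row shares", {
  dom <- toy_kitchen()
  v1 <- validated(dom, c("take-knife-drawer", "put-knife-board"))
  v2 <- validated(dom, c("take-knife-drawer", "walk-kitchen-kitchen",
                         "put-knife-board"))
  m <- build_markov(list(v1, v2), level = "class")
  # one of the two take transitions goes to put
  expect_identical(m$counts["take", "put"], 1L)
  expect_identical(m$probs["take", "put"], 0.5)
  expect_identical(m$probs["take", "walk"], 0.5)
  rs <- rowSums(m$probs)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  expect_error(build_markov(list()), "empty")
})

test_that("ground-level models keep full labels and zeros stay zero", {
  dom <- toy_kitchen()
  v <- validated(dom, c("take-knife-drawer", "put-knife-board",
                        "take-knife-board", "put-knife-counter"))
  m <- build_markov(list(v), level = "ground")
  expect_true("take-knife-drawer" %in% m$states)
  # a succession that never occurred has zero mass, no smoothing
  expect_identical(m$counts["take-knife-drawer", "take-knife-drawer"], 0L)
  edges <- markov_edges(m)
  expect_identical(sum(edges$count), sum(m$counts))
  dot <- markov_dot(m)
  expect_true(any(grepl("\"initial\" -> \"take-knife-drawer\"", dot)))
})

test_that("property curves aggregate run fractions per normalised bin", {
  dom <- gen_toy_domain("brownie")
  oil <- "fill-butter-butter_dish-baking_pan"
  runs <- list(
    validated(dom, c("other", oil, "other"), horizon = 3000),
    validated(dom, c("other", "other", oil), horizon = 3000),
    validated(dom, c(oil, "other", "other"), horizon = 3000),
    validated(dom, c("other", "other", "other"), horizon = 3000))
  pc <- property_curve(runs, "contains(baking_pan,butter)", TRUE, bins = 20)
  expect_true(all(pc$probability >= 0 & pc$probability <= 1))
  # terminal value: share of runs whose final state satisfies the predicate
  final_share <- mean(vapply(runs, function(v)
    isTRUE(v$trajectory$states[[4]][["contains(baking_pan,butter)"]]),
    logical(1)))
  expect_identical(final_share, 0.75)
  expect_identical(pc$probability[20], 0.75)
  expect_identical(pc$probability[1], 0.25)  # only the oil-first run

  # predicate true throughout -> flat at one
  flat <- property_curve(runs, "objects_taken()", 0, bins = 10)
  expect_identical(flat$probability, rep(1, 10))
})

test_that("a single run's curve is its own 0/1 trace", {
  dom <- toy_kitchen()
  v <- validated(dom, c("take-knife-drawer", "put-knife-board"),
                 times = c(0, 1000), horizon = 2000)
  pc <- property_curve(list(v), "is-at(knife)", "hands", bins = 2)
  expect_identical(pc$probability, c(1, 0))
  expect_error(property_curve(list(), "is-at(knife)", "hands"), "one run")
})

test_that("initial-state tables flag setup changes between runs", {
  dom <- toy_kitchen()
  same <- initial_state_table(list(dom, dom, dom), "is-at(knife)")
  expect_false(any(same$changed))

  moved <- dom
  moved$init[["is-at(knife)"]] <- "board"
  tab <- initial_state_table(c(rep(list(dom), 4), rep(list(moved), 2)),
                             "is-at(knife)")
  expect_identical(which(tab$changed), 5L)
  expect_identical(tab[["is-at(knife)"]],
                   c(rep("drawer", 4), rep("board", 2)))
  expect_error(initial_state_table(list(dom), "is-at(fork)"),
               "not declared")
})

test_that("relocated synthetic studies show exactly one change point", {
  dom <- toy_kitchen()
  cfg <- generator_config(seed = 8, n_runs = 30, max_plan_length = 6,
                          relocation_run = 26)
  study <- gen_study(dom, cfg)
  runs <- lapply(study, function(r)
    validate_plan(r$domain, r$plan, horizon = tier_horizon(r$tier_a)))
  tab <- initial_state_table(runs, "is-at(knife)",
                             run_ids = vapply(study, `[[`, character(1),
                                              "run_id"))
  expect_identical(which(tab$changed), 26L)
})

test_that("location timelines compress to one entry per move", {
  dom <- toy_kitchen()
  v <- validated(dom, c("take-knife-drawer", "put-knife-board"),
                 times = c(500, 2500))
  tl <- location_timeline(v, "knife")
  expect_identical(tl$knife$time_ms, c(0, 500, 2500))
  expect_identical(tl$knife$location, c("drawer", "hands", "board"))

  # an object never touched keeps a single entry
  dom2 <- gen_toy_domain("brownie")
  v2 <- validated(dom2, c("other", "open-fridge"))
  tl2 <- location_timeline(v2, c("bowl", "brownie_box"))
  expect_identical(nrow(tl2$bowl), 1L)
  expect_identical(tl2$bowl$location, "cupboard_tr")
  expect_error(location_timeline(v2, "fridge"), "no 'is-at' fluent")
})

test_that("timeline length matches the number of location writes", {
  dom <- gen_toy_domain("brownie")
  gen <- gen_plan(dom, generator_config(seed = 12, max_plan_length = 40))
  v <- validate_plan(dom, gen$plan)
  for (obj in c("bowl", "oil_bottle")) {
    tl <- location_timeline(v, obj)[[obj]]
    key <- paste0("is-at(", obj, ")")
    vals <- query_property(v$trajectory, key)
    moves <- sum(vals[-1] != vals[-length(vals)])
    expect_identical(nrow(tl), moves + 1L)
    # consistent with the raw property series
    expect_identical(tl$location[nrow(tl)], vals[length(vals)])
  }
})
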