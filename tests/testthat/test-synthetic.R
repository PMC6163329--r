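classes_of <- function(dom)
  unique(vapply(dom$schemas, `[[`, character(1), "name"))

test_that("the recipe dictionaries have the published class counts", {
  brownie <- classes_of(gen_toy_domain("brownie"))
  eggs <- classes_of(gen_toy_domain("eggs"))
  sandwich <- classes_of(gen_toy_domain("sandwich"))
  expect_length(brownie, 11)
  expect_length(eggs, 12)
  expect_length(sandwich, 12)
  expect_length(union(brownie, union(eggs, sandwich)), 13)
  expect_true("turn_off" %in% eggs)
  expect_false("cut" %in% eggs)
  expect_true("cut" %in% sandwich)
  expect_false("turn_off" %in% sandwich)
})

test_that("plan sampling is deterministic in the seed", {
  dom <- toy_kitchen()
  cfg <- generator_config(seed = 123, max_plan_length = 15)
  g1 <- gen_plan(dom, cfg)
  g2 <- gen_plan(dom, cfg)
  expect_identical(g1, g2)
  g3 <- gen_plan(dom, generator_config(seed = 124, max_plan_length = 15))
  expect_false(identical(g1$plan$label, g3$plan$label))
})

test_that("sampled plans always validate and their tiers are gap-free", {
  for (dom in list(toy_kitchen(), gen_toy_domain("eggs"))) {
    for (seed in 1:25) {
      gen <- gen_plan(dom, generator_config(seed = seed,
                                            max_plan_length = 12))
      expect_true(tier_is_gap_free(gen$tier))
      v <- validate_plan(dom, gen$plan)
      expect_identical(v$report$verdict, "valid")
    }
  }
})

test_that("a dead-end initial state is reported", {
  dom <- parse_domain(c(
    "(define (domain stuck)",
    "  (:types t - object) (:objects a - t)",
    "  (:functions (ok ?x - t) - boolean) (:init )",
    "  (:action go :parameters (?x - t)",
    "    :precondition (= (ok ?x) true)",
    "    :effect (and) :label \"go-{x}\"))"))
  expect_error(gen_plan(dom, generator_config(seed = 1)), "dead-end")
})

test_that("corruption with zero noise is the identity up to annotator id", {
  dom <- toy_kitchen()
  gen <- gen_plan(dom, generator_config(seed = 6))
  b <- corrupt_tier(gen$tier, generator_config(seed = 6))
  expect_identical(b$segments, gen$tier$segments)
  expect_identical(b$annotator_id, "B")
  expect_identical(interrater(gen$tier, b)$agreement, 1)
})

test_that("full label confusion over a rich vocabulary destroys agreement", {
  dom <- toy_kitchen()
  gen <- gen_plan(dom, generator_config(seed = 7, max_plan_length = 20))
  cfg <- generator_config(seed = 7, confusion_rate = 1)
  b <- corrupt_tier(gen$tier, cfg, domain = dom)
  expect_lt(interrater(gen$tier, b)$agreement, 1)
  # boundaries stay intact when only labels are confused
  expect_identical(b$segments[c("start", "end")],
                   gen$tier$segments[c("start", "end")])
})

test_that("confused labels stay within the action class when possible", {
  dom <- gen_toy_domain("brownie")
  gen <- gen_plan(dom, generator_config(seed = 13, max_plan_length = 25))
  cfg <- generator_config(seed = 13, confusion_rate = 1)
  b <- corrupt_tier(gen$tier, cfg, domain = dom)
  cls_a <- label_class(gen$tier$segments$label)
  cls_b <- label_class(b$segments$label)
  # classes with several groundings keep their class under confusion
  # (other and turn_on ground to a single label and must fall back)
  multi <- !(cls_a %in% c("other", "turn_on"))
  expect_identical(cls_b[multi], cls_a[multi])
})

test_that("jitter preserves the span and the segment order", {
  dom <- toy_kitchen()
  gen <- gen_plan(dom, generator_config(seed = 17, max_plan_length = 20))
  cfg <- generator_config(seed = 17, jitter_sd = 800)
  b <- corrupt_tier(gen$tier, cfg)
  expect_true(tier_is_gap_free(b))
  expect_identical(tier_horizon(b), tier_horizon(gen$tier))
  expect_identical(b$segments$label, gen$tier$segments$label)
  expect_true(all(b$segments$end > b$segments$start))
})

test_that("agreement degrades monotonically with boundary jitter", {
  dom <- toy_kitchen()
  levels <- c(0, 150, 500, 1500)
  mean_agree <- vapply(levels, function(j) {
    mean(vapply(1:20, function(s) {
      gen <- gen_plan(dom, generator_config(seed = s,
                                            max_plan_length = 12))
      b <- corrupt_tier(gen$tier,
                        generator_config(seed = s + 1000, jitter_sd = j))
      interrater(gen$tier, b, resolution = 20)$agreement
    }, numeric(1)))
  }, numeric(1))
  expect_identical(mean_agree[1], 1)
  expect_true(all(diff(mean_agree) < 0))
})

test_that("agreement degrades monotonically with label confusion", {
  dom <- toy_kitchen()
  levels <- c(0, 0.15, 0.45, 0.9)
  mean_agree <- vapply(levels, function(cr) {
    mean(vapply(1:20, function(s) {
      gen <- gen_plan(dom, generator_config(seed = s,
                                            max_plan_length = 12))
      b <- corrupt_tier(gen$tier,
                        generator_config(seed = s + 2000,
                                         confusion_rate = cr),
                        domain = dom)
      interrater(gen$tier, b, resolution = 20)$agreement
    }, numeric(1)))
  }, numeric(1))
  expect_identical(mean_agree[1], 1)
  expect_true(all(diff(mean_agree) < 0))
})

test_that("generated studies round-trip through the annotation files", {
  dom <- gen_toy_domain("sandwich")
  study <- gen_study(dom, generator_config(seed = 19, n_runs = 2,
                                           max_plan_length = 10,
                                           jitter_sd = 150,
                                           confusion_rate = 0.1))
  for (r in study) for (tier in list(r$tier_a, r$tier_b))
    for (fmt in c("elan-tsv", "csv")) {
      back <- read_tier(write_tier(tier, format = fmt), format = fmt,
                        run_id = tier$run_id)
      expect_equal(back, tier, ignore_attr = TRUE)
    }
  expect_identical(study[[1]]$tier_b$annotator_id, "B")
})
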