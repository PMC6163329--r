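test_that("slicing samples the covering segment at each slice start", {
  tier <- annotation_tier(0, 100, "take-knife-drawer")
  expect_identical(slice_tier(tier, resolution = 50, horizon = 200),
                   c("take-knife-drawer", "take-knife-drawer",
                     "NONE", "NONE"))
  # gap-free tier: no NONE before the last segment end
  gen <- gen_plan(toy_kitchen(), generator_config(seed = 2))
  s <- slice_tier(gen$tier, resolution = 10)
  expect_false(any(s == "NONE"))
})

test_that("slicing agrees with a per-millisecond scan oracle", {
  gen <- gen_plan(toy_kitchen(), generator_config(seed = 9,
                                                  max_plan_length = 8))
  tier <- gen$tier
  horizon <- tier_horizon(tier) + 137  # some uncovered tail
  for (res in c(1, 7, 10, 250)) {
    # oracle: label at every single millisecond, then take slice starts
    per_ms <- rep("NONE", horizon)
    for (i in seq_len(nrow(tier$segments)))
      per_ms[(tier$segments$start[i] + 1):tier$segments$end[i]] <-
        tier$segments$label[i]
    starts <- seq(0, horizon - 1, by = res)
    expect_identical(slice_tier(tier, res, horizon), per_ms[starts + 1])
  }
})

test_that("identical non-trivial tiers score perfect reliability", {
  tier <- quick_tier(c("a-x", "b-y", "a-x"))
  r <- interrater(tier, tier)
  expect_identical(r$agreement, 1)
  expect_identical(r$kappa, 1)
  expect_identical(r$alpha, 1)
  expect_identical(sum(r$confusion) - sum(diag(r$confusion)), 0L)
})

test_that("the four-slice worked example gives kappa one half", {
  r <- agreement_stats(c("x", "x", "y", "y"), c("x", "y", "y", "y"))
  expect_identical(r$agreement, 0.75)
  expect_identical(r$kappa, 0.5)   # p_o = .75, p_e = .5
  expect_identical(r$n_slices, 4L)
})

test_that("kappa matches an independent implementation on random series", {
  skip_if_not_installed("e1071")
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(letters[1:5], 500, replace = TRUE,
                prob = stats::runif(5))
    b <- ifelse(stats::runif(500) < 0.6, a,
                sample(letters[1:5], 500, replace = TRUE))
    r <- agreement_stats(a, b)
    ref <- e1071::classAgreement(table(a, b))
    expect_equal(r$kappa, ref$kappa, tolerance = 1e-12)
    expect_equal(r$agreement, ref$diag, tolerance = 1e-12)
  }
})

test_that("alpha and kappa converge for two coders at large n", {
  set.seed(4)
  n <- 1e5
  a <- sample(letters[1:4], n, replace = TRUE)
  b <- ifelse(stats::runif(n) < 0.7, a, sample(letters[1:4], n, TRUE))
  r <- agreement_stats(a, b)
  expect_lt(abs(r$alpha - r$kappa), 1 / n * 10)
  expect_lte(r$kappa, 1)
  expect_lte(r$alpha, 1)
})

test_that("metrics are invariant under label renaming and annotator swap", {
  gen <- gen_plan(toy_kitchen(), generator_config(seed = 21))
  cfg <- generator_config(seed = 22, jitter_sd = 300, confusion_rate = 0.2)
  b <- corrupt_tier(gen$tier, cfg, domain = toy_kitchen())
  r <- interrater(gen$tier, b)

  # bijective renaming of the label set
  relabel <- function(tier) {
    tier$segments$label <- paste0("Z", tier$segments$label)
    tier
  }
  r2 <- interrater(relabel(gen$tier), relabel(b))
  expect_equal(r2$agreement, r$agreement)
  expect_equal(r2$kappa, r$kappa)
  expect_equal(r2$alpha, r$alpha)

  # swapping annotators transposes the confusion table
  r3 <- interrater(b, gen$tier)
  expect_equal(r3$agreement, r$agreement)
  expect_equal(r3$kappa, r$kappa)
  expect_identical(unname(unclass(r3$confusion)),
                   unname(t(unclass(r$confusion))))
})

test_that("kappa equals agreement when chance agreement is zero", {
  # disjoint label sets: p_e = 0
  r <- agreement_stats(c("a", "a", "b", "b"), c("c", "c", "d", "d"))
  expect_identical(r$kappa, r$agreement)
})

test_that("empty tiers make reliability undefined", {
  e <- annotation_tier(numeric(0), numeric(0), character(0))
  expect_error(interrater(e, e), "undefined")
  expect_error(interrater(quick_tier("a-x"),
                          quick_tier("a-x", run_id = "other")),
               "different runs")
})

test_that("class-level comparison collapses ground labels to classes", {
  a <- quick_tier(c("take-knife-drawer", "put-knife-board"))
  b <- quick_tier(c("take-knife-board", "put-knife-board"))
  expect_lt(interrater(a, b)$agreement, 1)
  expect_identical(interrater(a, b, level = "class")$agreement, 1)
})

test_that("uncovered time counts as disagreement unless excluded", {
  a <- annotation_tier(0, 1000, "x-l")
  b <- annotation_tier(0, 500, "x-l")
  r <- interrater(a, b, resolution = 1)
  expect_equal(r$agreement, 0.5)
  expect_identical(interrater(a, b, resolution = 1,
                              ignore_none = TRUE)$agreement, 1)
})

test_that("identical tiers have no disagreement intervals", {
  tier <- quick_tier(c("a-x", "b-y"))
  expect_identical(nrow(diff_segments(tier, tier)), 0L)
})

test_that("a uniform time shift is classified as boundary shifts", {
  gen <- gen_plan(toy_kitchen(), generator_config(seed = 31,
                                                  max_plan_length = 10))
  seg <- gen$tier$segments
  shifted <- annotation_tier(seg$start + 200, seg$end + 200, seg$label,
                             run_id = gen$tier$run_id, annotator_id = "B")
  d <- diff_segments(gen$tier, shifted, window = 1000)
  expect_gt(nrow(d), 0)
  expect_true(all(d$kind == "boundary-shift"))
})

test_that("substituted labels are not classified as boundary shifts", {
  a <- quick_tier(c("take-knife-drawer", "put-knife-board"))
  b <- quick_tier(c("take-knife-drawer", "stir-bowl"))
  d <- diff_segments(a, b)
  expect_identical(d$kind, "substitution")
  expect_identical(d$label_a, "put-knife-board")
  expect_identical(d$label_b, "stir-bowl")
})

test_that("total disagreement time matches one minus agreement", {
  gen <- gen_plan(toy_kitchen(), generator_config(seed = 41))
  cfg <- generator_config(seed = 42, jitter_sd = 400, confusion_rate = 0.3)
  b <- corrupt_tier(gen$tier, cfg, domain = toy_kitchen())
  horizon <- max(tier_horizon(gen$tier), tier_horizon(b))
  d <- diff_segments(gen$tier, b)
  r <- interrater(gen$tier, b, resolution = 1)
  expect_equal(sum(d$end - d$start), (1 - r$agreement) * horizon,
               tolerance = 1e-9)
})

test_that("the learning curve reports per-step gains and the trend", {
  tier <- quick_tier(c("a-x", "b-y"))
  flat <- learning_curve(list(list(tier, tier), list(tier, tier),
                              list(tier, tier)))
  expect_identical(flat$agreement, c(1, 1, 1))
  expect_identical(flat$diffs, c(0, 0))
  expect_equal(flat$slope, 0)

  pairs <- lapply(c(0.5, 0.73, 0.96), tier_pair_with_agreement)
  lc <- learning_curve(pairs, resolution = 1)
  expect_equal(lc$agreement, c(0.5, 0.73, 0.96))
  expect_equal(lc$diffs, c(0.23, 0.23))
  expect_gt(lc$slope, 0)
})
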