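test_that("stage durations count days between first observations", {
  tab <- data.frame(
    cell_id = "c1",
    day = c(0, 1, 2, 3, 5, 9, 10, 11),
    stage = c("juvenile", "juvenile", "juvenile", "adult", "adult",
              "adult", "reproductive", "offspring_emerged"))
  d <- stage_durations(tab)
  expect_equal(d$juvenile_days, 3)
  expect_equal(d$adult_days, 7)
  expect_equal(d$total_days, 11)
  expect_true(d$complete)
  # single observation: flagged incomplete, no total
  one <- stage_durations(data.frame(cell_id = "c2", day = 0,
                                    stage = "juvenile"))
  expect_false(one$complete)
  expect_true(is.na(one$total_days))
  expect_error(stage_durations(data.frame(cell_id = "c3", day = c(3, 1),
                                          stage = c("adult", "adult"))),
               "non-monotone")
  expect_warning(stage_durations(data.frame(
    cell_id = "c4", day = c(0, 20, 21),
    stage = c("juvenile", "adult", "offspring_emerged"))), "gap")
})

test_that("per-cell stage durations add up to the total for gap-free tables", {
  coh <- simulate_lifecycle_cohort(30, rng_seed = 4)
  d <- suppressWarnings(stage_durations(coh))
  d <- d[d$complete, ]
  sums <- unname(rowSums(d[, c("juvenile_days", "adult_days",
                               "pre_reproductive_days",
                               "reproductive_days")]))
  expect_equal(sums, d$total_days)
})

test_that("emergence classes use the 25- and 35-day boundaries, both middle-inclusive", {
  expect_equal(classify_emergence(c(24, 25, 30, 35, 36)),
               c("early", "middle", "middle", "middle", "late"))
  expect_error(classify_emergence(0), "positive")
})

test_that("transition percentages round from raw counts and ignore row order", {
  tab <- data.frame(
    parent_type = c(rep("type1", 65), rep("type2", 29)),
    own_type = c(rep("type2", 47), rep("type1", 18),
                 rep("type1", 27), rep("type2", 2)))
  tp <- transition_percentages(tab)
  t1 <- tp[tp$parent_type == "type1" & tp$own_type == "type2", ]
  t2 <- tp[tp$parent_type == "type2" & tp$own_type == "type1", ]
  expect_equal(t1$percent, 72)
  expect_equal(t1$count, 47)
  expect_equal(t1$total, 65)
  expect_equal(t2$percent, 93)
  set.seed(2)
  shuf <- tab[sample(nrow(tab)), ]
  tp2 <- transition_percentages(shuf)
  expect_equal(tp2[order(tp2$parent_type, tp2$own_type), ],
               tp[order(tp$parent_type, tp$own_type), ],
               ignore_attr = TRUE)
  zero <- data.frame(parent_type = rep("type1", 10),
                     own_type = rep("type1", 10))
  z <- transition_percentages(zero)
  expect_equal(z$percent[z$own_type == "type1"], 100)
})

test_that("synchrony index is the mean daily modal fraction with its known bounds", {
  allsame <- data.frame(day = rep(1:4, each = 6), stage = "adult")
  expect_equal(synchrony_index(allsame)$index, 1)
  split2 <- data.frame(day = rep(1, 4),
                       stage = c("adult", "adult", "juvenile", "juvenile"))
  expect_equal(synchrony_index(split2)$index, 0.5)
  unif4 <- data.frame(day = rep(1, 4),
                      stage = c("juvenile", "adult", "pre_reproductive",
                                "reproductive"))
  expect_equal(synchrony_index(unif4)$index, 0.25)
  # bounds: within [1/k, 1] for k observed stages
  coh <- simulate_lifecycle_cohort(40, rng_seed = 6)
  idx <- synchrony_index(coh)$index
  k <- length(unique(coh$stage))
  expect_gte(idx, 1 / k)
  expect_lte(idx, 1)
})

test_that("simulated cohorts recover their duration and transition parameters", {
  coh <- simulate_lifecycle_cohort(200, parent_type = "type1",
                                   rng_seed = 7)
  d <- suppressWarnings(stage_durations(coh))
  t2 <- d[d$reproductive_type == "type2" & d$complete, ]
  expect_equal(mean(t2$total_days), 25, tolerance = 1 / 25)
  tp <- transition_percentages(coh)
  sw <- tp[tp$parent_type == "type1" & tp$own_type == "type2", ]
  expect_equal(sw$percent, 72, tolerance = 0.12)
})
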