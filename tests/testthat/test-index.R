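test_that("raw category labels condense to their published scores", {
  expect_identical(standardize_trait("High average", "pace"), 2L)
  expect_identical(standardize_trait("3+", "rating"), 3L)
  expect_identical(standardize_trait("Sound", "soundness"), 2L)
  expect_identical(standardize_trait("Less than average", "pace"), 0L)
  expect_identical(standardize_trait(c("High", "Less than average"),
                                     "distraction"), c(1L, 0L))
  expect_error(standardize_trait("Bouncy", "pace"), "valid labels")
  expect_error(standardize_trait("Sound", "nosuchtrait"), "unknown trait")
})

test_that("standardization reproduces the published score-level counts", {
  fx <- make_fixture("table1", seed = 2)
  expected <- list(
    pace = c(`0` = 44, `1` = 551, `2` = 249),
    distraction = c(`0` = 460, `1` = 384),
    pull = c(`0` = 51, `1` = 744, `2` = 49),
    neck = c(`0` = 75, `1` = 496, `2` = 273),
    rating = c(`0` = 22, `1` = 32, `2` = 282, `3` = 305, `4` = 11,
               `5` = 174, `6` = 10, `7` = 8),
    soundness = c(`0` = 98, `1` = 484, `2` = 262))
  for (tr in names(expected)) {
    scores <- standardize_trait(fx[[tr]], tr)
    counts <- table(scores)
    expect_equal(as.integer(counts), unname(as.vector(expected[[tr]])),
                 info = tr)
    expect_identical(names(counts), names(expected[[tr]]), info = tr)
    expect_identical(sum(counts), 844L, info = tr)
  }
})

test_that("direction normalizations hit their forced values", {
  # negative: worst raw score -> 0, best -> 1
  expect_equal(normalize_negative(7, 7), 0)
  expect_equal(normalize_negative(0, 7), 1)
  expect_equal(normalize_negative(3, 7), 4 / 7)
  expect_error(normalize_negative(1, 0), "positive")
  expect_error(normalize_negative(8, 7), "0, x_max")
  # positive: retained directionality
  expect_equal(normalize_positive(2, 2), 1)
  expect_equal(normalize_positive(0, 2), 0)
  expect_equal(normalize_positive(1, 2), 0.5)
  # neutral: optimum at 1, symmetric falloff
  expect_equal(normalize_neutral(1), 1)
  expect_equal(normalize_neutral(0), 0)
  expect_equal(normalize_neutral(2), 0)
  expect_equal(normalize_neutral(1.5), 0.5)
})

test_that("behavior score weights normalized traits by |correlation|", {
  # worst-scoring dog on every trait -> 0
  worst <- data.frame(neck = 2, distraction = 1, rating = 7, soundness = 0,
                      trainability = 0, pace = 0, pull = 0)
  expect_equal(behavior_score(worst), 0)
  # best-scoring dog -> sum of weights
  best <- data.frame(neck = 0, distraction = 0, rating = 0, soundness = 2,
                     trainability = 10, pace = 1, pull = 1)
  w <- abs(c(0.107, 0.108, 0.144, 0.127, 0.531, 0.02, 0.017))
  expect_equal(behavior_score(best), sum(w))
  # soundness alone at half scale contributes 0.127 x 0.5
  half_sound <- data.frame(neck = 2, distraction = 1, rating = 7,
                           soundness = 1, trainability = 0, pace = 0, pull = 0)
  expect_equal(behavior_score(half_sound), 0.127 * 0.5)
  expect_error(behavior_score(worst[, -1]), "missing behavior")
})

test_that("behavior score is monotone in each trait's beneficial direction", {
  base <- neutral_behavior()
  for (tr in c("soundness")) {
    lo <- base; lo[[tr]] <- 0
    hi <- base; hi[[tr]] <- 2
    expect_gt(behavior_score(hi), behavior_score(lo))
  }
  for (tr in c("neck", "rating")) {
    lo <- base; hi <- base
    hi[[tr]] <- if (tr == "rating") 7 else 2
    expect_lt(behavior_score(hi), behavior_score(lo))
  }
  for (tr in c("pace", "pull")) {
    at_opt <- base
    off <- base; off[[tr]] <- 0
    off2 <- base; off2[[tr]] <- 2
    expect_gt(behavior_score(at_opt), behavior_score(off))
    expect_gt(behavior_score(at_opt), behavior_score(off2))
  }
})

test_that("health score sums signed correlations of diagnoses", {
  d <- empty_diagnoses()
  expect_equal(health_score(d), 0)
  d$atopic_dermatitis <- 1L
  expect_equal(health_score(d), -0.1)
  d$mandibular_distocclusion <- 1L
  expect_equal(health_score(d), -0.205)
  # nonincreasing in the number of diagnoses
  d_all <- empty_diagnoses()
  d_all[1, ] <- 1L
  expect_lt(health_score(d_all), health_score(d))
  bad <- empty_diagnoses(); bad$ppm <- 2L
  expect_error(health_score(bad), "0 or 1")
})

test_that("total score combines the two indices with configured weights", {
  expect_equal(total_score(-0.1, 0.5), 0.02 * (-0.1) + 0.324 * 0.5)
  expect_equal(total_score(-0.1, 0.5), 0.160, tolerance = 1e-3)
  expect_equal(total_score(-3, 0.7, list(w_health = 0, w_behavior = 1)), 0.7)
  expect_equal(total_score(0, 0), 0)
  expect_error(total_score(1, 1, list(w_health = 0, w_behavior = 0)),
               "not both")
})

test_that("category counts tally conditions into their groups", {
  d <- empty_diagnoses()
  expect_equal(unlist(category_counts(d)), c(dental_count = 0,
               ocular_count = 0, dermal_count = 0, health_count = 0))
  d$supernumerary_teeth <- 1L
  d$distichiasis <- 1L
  cc <- category_counts(d)
  expect_identical(cc$dental_count, 1L)
  expect_identical(cc$ocular_count, 1L)
  expect_identical(cc$dermal_count, 0L)
  expect_identical(cc$health_count, 2L)
  # umbilical hernia counts toward the overall health count only
  d2 <- empty_diagnoses()
  d2$umbilical_hernia <- 1L
  cc2 <- category_counts(d2)
  expect_identical(unlist(cc2), c(dental_count = 0L, ocular_count = 0L,
                                  dermal_count = 0L, health_count = 1L))
  # health count dominates the sum of the three named groups
  d3 <- empty_diagnoses()
  d3[1, ] <- 1L
  cc3 <- category_counts(d3)
  expect_gte(cc3$health_count,
             cc3$dental_count + cc3$ocular_count + cc3$dermal_count)
  expect_identical(cc3$health_count, 20L)
  expect_identical(cc3$dental_count, 8L)
  expect_identical(cc3$ocular_count, 2L)
  expect_identical(cc3$dermal_count, 6L)
})

test_that("normalized behavior values stay inside the unit interval", {
  defs <- trait_definitions()
  behav <- defs[defs$kind == "ordinal_behavior" & defs$trait != "trainability", ]
  for (i in seq_len(nrow(behav))) {
    xs <- 0:behav$x_max[i]
    vals <- switch(behav$direction[i],
                   negative = normalize_negative(xs, behav$x_max[i]),
                   positive = normalize_positive(xs, behav$x_max[i]),
                   neutral = normalize_neutral(xs))
    expect_true(all(vals >= 0 & vals <= 1), info = behav$trait[i])
  }
})

test_that("score_dogs appends scores, counts, and parent averages", {
  pop <- simulate_population(sim_config(
    n_founders = 60, n_offspring = 40, n_trio_offspring = 20,
    n_snps = 300, n_causal_per_trait = 60, seed = 55))
  scored <- add_parent_scores(score_dogs(pop$pheno))
  expect_true(all(c("behavior_score", "health_score", "total_score",
                    "dental_count", "ocular_count", "dermal_count",
                    "health_count", "parent_total_score") %in% names(scored)))
  expect_true(all(scored$health_score <= 0))
  expect_equal(scored$total_score,
               0.02 * scored$health_score + 0.324 * scored$behavior_score)
  # trio offspring have parental scores; founders do not
  expect_true(all(!is.na(scored$parent_total_score[scored$is_trio])))
  expect_true(all(is.na(scored$parent_total_score[pop$pedigree$is_founder])))
  tr <- scored[scored$is_trio, ]
  i <- 1
  mid <- (scored$total_score[match(tr$sire[i], scored$id)] +
            scored$total_score[match(tr$dam[i], scored$id)]) / 2
  expect_equal(tr$parent_total_score[i], mid)
})
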