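test_that("confusion matrices tally correctly and conserve row sums", {
  perfect <- confusion_from_predictions(rep(1:3, each = 30), rep(1:3, each = 30))
  expect_equal(diag(perfect), c(`1` = 30, `2` = 30, `3` = 30))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_equal(confusion_accuracy(perfect), 1)

  collapsed <- confusion_from_predictions(rep(1:3, each = 30), rep(1, 90))
  expect_equal(unname(collapsed[, 1]), rep(30, 3))
  expect_equal(sum(collapsed[, 2:3]), 0)

  set.seed(17)
  true <- sample(1:3, 90, replace = TRUE)
  pred <- sample(1:3, 90, replace = TRUE)
  cm <- confusion_from_predictions(true, pred)
  # independent counting oracle
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm[i, j], sum(true == i & pred == j))
  expect_equal(unname(rowSums(cm)), as.vector(table(factor(true, levels = 1:3))))
  # summing subject matrices preserves row-sum conservation
  cm2 <- confusion_from_predictions(true, rev(pred))
  expect_equal(rowSums(unclass(cm) + unclass(cm2)), 2 * rowSums(cm))
  # row-stochastic view
  expect_equal(unname(rowSums(confusion_rates(cm))), rep(1, 3))

  expect_error(confusion_from_predictions(c(1, 2), c(1, 4)), "unknown label")
  expect_error(confusion_from_predictions(1:3, 1:2), "length")
})

test_that("direction comparison is null for copies and calibrated under the null", {
  set.seed(19)
  mats <- lapply(1:10, function(i)
    confusion_from_predictions(sample(1:3, 90, TRUE), sample(1:3, 90, TRUE)))
  same <- compare_directions(mats, mats)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_directions(mats[1:2], mats[1:2]), "3 subjects")

  # equal transfer in both directions: rejection close to the nominal rate
  rej <- mean(replicate(200, {
    m1 <- lapply(1:8, function(i)
      confusion_from_predictions(rep(1:3, each = 30), sample(1:3, 90, TRUE)))
    m2 <- lapply(1:8, function(i)
      confusion_from_predictions(rep(1:3, each = 30), sample(1:3, 90, TRUE)))
    compare_directions(m1, m2)$p < 0.05
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})

test_that("asymmetric transfer between directions is detected", {
  set.seed(29)
  detect <- mean(replicate(50, {
    good <- lapply(1:8, function(i) {
      pred <- rep(1:3, each = 30)
      flip <- sample(90, 15)                      # ~83% correct direction
      pred[flip] <- sample(1:3, 15, TRUE)
      confusion_from_predictions(rep(1:3, each = 30), pred)
    })
    chance <- lapply(1:8, function(i)
      confusion_from_predictions(rep(1:3, each = 30), sample(1:3, 90, TRUE)))
    compare_directions(good, chance)$p < 0.05
  }))
  expect_gte(detect, 0.9)
})

test_that("level ANOVA matches a hand computation and Tukey dominates raw p", {
  d <- data.frame(level = rep(1:3, each = 4),
                  rate = c(0.52, 0.48, 0.51, 0.49,
                           0.31, 0.29, 0.33, 0.27,
                           0.30, 0.32, 0.28, 0.30))
  res <- level_accuracy_anova(d)
  # hand one-way ANOVA
  grand <- mean(d$rate)
  ssb <- sum(tapply(d$rate, d$level, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(d$rate, d$level, function(x) sum((x - mean(x))^2)))
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$effects$F, f_hand, tolerance = 1e-10)
  expect_equal(c(res$effects$df_num, res$effects$df_den), c(2, 9))
  # level 1 vs 2 and 1 vs 3 separate; 2 vs 3 does not
  ph <- res$posthoc
  expect_lt(ph$p_adjusted[ph$pair == "2-1"], 0.05)
  expect_lt(ph$p_adjusted[ph$pair == "3-1"], 0.05)
  expect_gt(ph$p_adjusted[ph$pair == "3-2"], 0.5)
  # Tukey-adjusted p >= unadjusted pairwise p (same pooled error)
  mse <- ssw / 9
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    diffm <- abs(mean(d$rate[d$level == pair[1]]) -
                   mean(d$rate[d$level == pair[2]]))
    p_raw <- 2 * pt(-diffm / sqrt(2 * mse / 4), 9)
    p_tukey <- ph$p_adjusted[ph$pair == paste0(pair[2], "-", pair[1])]
    expect_gte(p_tukey + 1e-12, p_raw)
  }
  # flat rates: F near zero, nothing significant
  flat <- data.frame(level = rep(1:3, each = 3), rate = rep(c(0.3, 0.35, 0.4), 3))
  res_flat <- level_accuracy_anova(flat)
  expect_lt(res_flat$effects$F, 1e-10)
  expect_true(all(res_flat$posthoc$p_adjusted > 0.99))
})

test_that("behavioral RM-ANOVA has the design dfs and decomposes the SS", {
  d <- experiment_design(n_subjects = 18, seed = 4)
  ratings <- generate_ratings(d, rating_model(seed = 8))
  res <- behavioral_rm_anova(ratings)
  expect_equal(res$effects$df_num, c(1, 3, 3))
  expect_equal(res$effects$df_den, c(17, 51, 51))
  # SS decomposition: subject + effects + error strata account for the total
  ss_sum <- res$ss_subject + sum(res$effects$ss) + sum(res$effects$ss_error)
  expect_equal(ss_sum, res$ss_total, tolerance = 1e-10)
  # F statistics match a from-scratch two-way RM computation
  cell <- tapply(ratings$rating, list(ratings$condition, ratings$level), mean)
  subj <- tapply(ratings$rating, ratings$subject, mean)
  grand <- mean(ratings$rating)
  n_s <- 18
  ss_cond <- n_s * 4 * sum((rowMeans(cell) - grand)^2)
  sc <- tapply(ratings$rating, list(ratings$subject, ratings$condition), mean)
  ss_sc <- 4 * sum((sweep(sweep(sc, 1, subj), 2, colMeans(sc)) + grand)^2)
  f_cond_hand <- (ss_cond / 1) / (ss_sc / 17)
  expect_equal(res$effects$F[1], f_cond_hand, tolerance = 1e-8)
  # post hoc: one row per level, adjusted p in [0,1]
  expect_equal(nrow(res$posthoc), 4)
  expect_true(all(res$posthoc$p_adjusted >= 0 & res$posthoc$p_adjusted <= 1))
  # incomplete tables are rejected
  expect_error(behavioral_rm_anova(ratings[-1, ]), "complete")
})
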