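test_that("score tables are validated on construction", {
  expect_error(delphi_scores(matrix(c(1, 10), 1, 2)), "9-point")
  expect_error(delphi_scores(matrix(c(1, 0.5), 1, 2)), "9-point")
  expect_error(delphi_scores(matrix(c(1, NA), 1, 2)), "missing score")
  s <- delphi_scores(matrix(5L, 3, 2), dimension = "importance")
  expect_identical(colnames(s$scores), c("factor1", "factor2"))
})

test_that("medians use the midpoint convention and match a sort oracle", {
  s <- delphi_scores(matrix(9L, 5, 1), "importance")
  expect_equal(summarize_scores(s)$median, 9)

  s <- delphi_scores(matrix(c(4L, 5L, 6L, 7L), 4, 1), "importance")
  expect_equal(summarize_scores(s)$median, 5.5)

  set.seed(3)
  s <- rdelphi_scores(15, c(f1 = 3, f2 = 5, f3 = 8), noise_sd = 2)
  got <- summarize_scores(s)
  for (k in seq_len(3)) {
    srt <- as.numeric(sort(s$scores[, k]))
    oracle <- (srt[8] + srt[8]) / 2  # odd panel: middle order statistic
    expect_equal(got$median[k], oracle)
  }
})

test_that("band classification follows the selection rules incl. boundaries", {
  expect_equal(classify_factor(8, 8), "selected")
  expect_equal(classify_factor(5, 6), "advance")
  expect_equal(classify_factor(3, 8), "eliminated")
  expect_equal(classify_factor(8, 3), "eliminated")
  # medians of exactly 7 or exactly 4 advance rather than select/eliminate
  expect_equal(classify_factor(7, 9), "advance")
  expect_equal(classify_factor(4, 9), "advance")
  expect_equal(classify_factor(9, 7), "advance")
  expect_error(classify_factor(0.5, 5))
})

test_that("every half-integer median pair maps to the band oracle's decision", {
  grid <- seq(1, 9, by = 0.5)
  for (m1 in grid) for (m2 in grid) {
    expect_identical(classify_factor(m1, m2), band_oracle(m1, m2))
  }
})

test_that("agreement rate counts the median's Likert band", {
  s <- delphi_scores(matrix(8L, 15, 1, dimnames = list(NULL, "f")),
                     "importance")
  expect_equal(agreement_rate(s, "f"), 1)

  # 12 of 15 in the mid band around a median of 5
  scores <- matrix(c(rep(1L, 3), rep(5L, 12)), 15, 1,
                   dimnames = list(NULL, "f"))
  s <- delphi_scores(scores, "importance")
  expect_equal(agreement_rate(s, "f"), 0.8)
  expect_error(agreement_rate(s, "nope"), "unknown factor")

  set.seed(9)
  s <- rdelphi_scores(15, c(f1 = 4, f2 = 6, f3 = 9), noise_sd = 2.5)
  for (f in colnames(s$scores)) {
    col <- s$scores[, f]
    med <- sort(col)[8]
    band_of <- function(x) cut(x, c(0, 3.5, 7.5, 9.5), labels = FALSE)
    oracle <- sum(band_of(col) == band_of(med)) / length(col)
    expect_equal(agreement_rate(s, f), oracle)
  }
})

test_that("a round partitions factors and terminates on panel agreement", {
  set.seed(21)
  consensus <- c(keep1 = 9, keep2 = 8.5, mid1 = 6, mid2 = 5, drop1 = 2,
                 drop2 = 1.5)
  imp <- rdelphi_scores(15, consensus, noise_sd = 0.4,
                        dimension = "importance")
  mea <- rdelphi_scores(15, consensus, noise_sd = 0.4,
                        dimension = "measurement_capability")
  out <- run_round(imp, mea, round_number = 1)
  expect_setequal(out$decision[out$factor_id %in% c("keep1", "keep2")],
                  "selected")
  expect_setequal(out$decision[out$factor_id %in% c("mid1", "mid2")],
                  "advance")
  expect_setequal(out$decision[out$factor_id %in% c("drop1", "drop2")],
                  "eliminated")
  # partition: one decision per factor, counts sum to the input
  expect_equal(nrow(out), length(consensus))
  expect_true(all(out$decision %in% c("selected", "advance", "eliminated")))
  # tight panel: every live factor agrees, so the Delphi may stop
  expect_true(all(out$agreement_rate[out$decision != "eliminated"] >= 0.8))
  expect_true(attr(out, "terminated"))

  # per-factor decisions equal independent classification of the medians
  for (k in seq_len(nrow(out))) {
    expect_identical(out$decision[k],
                     band_oracle(out$median_importance[k],
                                 out$median_measurement[k]))
  }
})

test_that("a split panel below the agreement threshold keeps the Delphi open", {
  # 11 of 15 experts in the median's band: agreement 0.733 < 0.80
  split <- matrix(c(rep(8L, 4), rep(5L, 11)), 15, 1,
                  dimnames = list(NULL, "f"))
  imp <- delphi_scores(split, "importance")
  mea <- delphi_scores(matrix(5L, 15, 1, dimnames = list(NULL, "f")),
                       "measurement_capability")
  out <- run_round(imp, mea)
  expect_lt(out$agreement_rate, 0.8)
  expect_false(attr(out, "terminated"))
})

test_that("raising a score never demotes a factor", {
  set.seed(33)
  for (rep in 1:30) {
    imp <- rdelphi_scores(9, c(f1 = runif(1, 1, 9), f2 = runif(1, 1, 9)),
                          noise_sd = 2, dimension = "importance")
    mea <- rdelphi_scores(9, c(f1 = runif(1, 1, 9), f2 = runif(1, 1, 9)),
                          noise_sd = 2, dimension = "measurement_capability")
    before <- run_round(imp, mea)
    e <- sample(9, 1)
    imp$scores[e, "f1"] <- min(9L, imp$scores[e, "f1"] + 1L)
    after <- run_round(imp, mea)
    expect_gte(decision_rank[[after$decision[after$factor_id == "f1"]]],
               decision_rank[[before$decision[before$factor_id == "f1"]]])
  }
})

test_that("override selections are explicit, never silent", {
  imp <- delphi_scores(matrix(5L, 7, 2, dimnames = list(NULL, c("a", "b"))),
                       "importance")
  mea <- delphi_scores(matrix(5L, 7, 2, dimnames = list(NULL, c("a", "b"))),
                       "measurement_capability")
  out <- run_round(imp, mea, select_override = "b")
  expect_identical(out$decision, c("advance", "selected"))
  expect_identical(out$overridden, c(FALSE, TRUE))
})
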