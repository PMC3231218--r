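test_that("matched percentage counts decisions against the truth", {
  expect_equal(matchedPercentage(rep("accept_H0", 10), "true_class"),
               c(accept_pct = 100, correct_pct = 100))
  expect_equal(matchedPercentage(rep("accept_H0", 10), "false_class"),
               c(accept_pct = 100, correct_pct = 0))
  dec <- c(rep("reject_H0", 93), rep("accept_H0", 7))
  expect_equal(matchedPercentage(dec, "false_class")[["correct_pct"]], 93)
  expect_equal(matchedPercentage(dec, "true_class")[["correct_pct"]], 7)
  expect_error(matchedPercentage(character(0), "true_class"), "nonempty")
  expect_error(matchedPercentage(c("yes"), "true_class"), "accept_H0")
})

test_that("ROC/AUC agrees with exhaustive pair counting and behaves", {
  # tiny case against an exhaustive enumeration oracle (ties half credit)
  pos <- c(1, 2, 3); neg <- c(2, 3, 4)
  pairs <- expand.grid(p = pos, n = neg)
  oracle <- (sum(pairs$p < pairs$n) + 0.5 * sum(pairs$p == pairs$n)) /
    nrow(pairs)
  expect_equal(oracle, 7 / 9)
  r <- rocFromStatistics(pos, neg, higherIsPositive = FALSE)
  expect_equal(auc(r), oracle)

  # fully separated supports give AUC exactly 1
  expect_equal(auc(rocFromStatistics(c(5, 6, 7), c(1, 2, 3))), 1)

  # complement symmetry for tie-free inputs
  set.seed(13)
  a <- rnorm(40); b <- rnorm(40, 1)
  expect_equal(auc(rocFromStatistics(a, b)),
               1 - auc(rocFromStatistics(b, a)))

  # sweep curves are monotone and anchored at (0,0) and (1,1)
  expect_equal(r@tpr[1], 0); expect_equal(r@fpr[1], 0)
  expect_equal(r@tpr[length(r@tpr)], 1)
  expect_false(is.unsorted(r@tpr)); expect_false(is.unsorted(r@fpr))

  # no-signal case: AUC inside the 99% band around 0.5
  set.seed(14)
  x <- rnorm(100); y <- rnorm(100)
  sdMW <- sqrt((100 + 100 + 1) / (12 * 100 * 100))
  expect_lt(abs(auc(rocFromStatistics(x, y)) - 0.5),
            stats::qnorm(0.995) * sdMW)

  expect_error(rocFromStatistics(numeric(0), 1:3), "nonempty")
})
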