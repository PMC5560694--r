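test_that("fold assignment partitions instances into near-equal folds", {
  f <- make_folds(9172, 10, seed = 1)
  sizes <- as.integer(table(f))
  expect_equal(sort(sizes), sort(c(rep(917, 8), rep(918, 2))))
  expect_equal(length(f), 9172)
  expect_identical(make_folds(9172, 10, seed = 1), f)   # determinism
  expect_false(identical(make_folds(9172, 10, seed = 2), f))
  expect_error(make_folds(5, 10, seed = 1), "more folds")

  fs <- make_folds(100, 10, seed = 3, strata = rep(c("a", "b"), 50))
  expect_true(all(table(fs, rep(c("a", "b"), 50)) == 5))
})

test_that("cross-validation covers every instance once and is seed-deterministic", {
  spec <- random_kcf_model(4, k = 2, seed = 3, concentration = 0.5)
  tb <- as_tibble(sample_dataset(spec, 200))
  cv1 <- cross_validate(tb, "class", model = "nb", folds = 5, seed = 9)
  cv2 <- cross_validate(tb, "class", model = "nb", folds = 5, seed = 9)
  expect_equal(cv1$predictions, cv2$predictions)
  expect_equal(sort(cv1$predictions$row), 1:200)
  expect_equal(cv1$mean_accuracy, mean(cv1$folds$accuracy))
  expect_equal(tidy(cv1), cv1$folds)
  expect_equal(glance(cv1)$mean_accuracy, cv1$mean_accuracy)
  expect_error(cross_validate(tb, "class", model = "nb", folds = 5),
               "seed is required")
})

test_that("a majority-class predictor scores the majority fraction", {
  # one attribute carrying no signal: every classifier predicts the prior winner
  set.seed(4)
  df <- data.frame(x1 = sample(c("a", "b"), 300, TRUE),
                   class = rep(c("A", "B"), c(200, 100)))
  cv <- cross_validate(df, "class", model = "nb", folds = 5, seed = 2)
  expect_gt(cv$mean_accuracy, 0.55)   # near 2/3, fold noise aside
  expect_lt(cv$mean_accuracy, 0.78)
})

test_that("sensitivity, specificity and balanced accuracy follow their definitions", {
  expect_equal(
    sensitivity_specificity(list(TP = 10, FP = 0, TN = 10, FN = 0)),
    c(sensitivity = 1, specificity = 1))
  expect_equal(
    sensitivity_specificity(list(TP = 10, FP = 10, TN = 0, FN = 0)),
    c(sensitivity = 1, specificity = 0))
  expect_equal(
    unname(sensitivity_specificity(list(TP = 8, FN = 2, TN = 7, FP = 3))),
    c(0.8, 0.7))
  expect_error(sensitivity_specificity(list(TP = 0, FN = 0, TN = 5, FP = 5)),
               "no positive")
  expect_error(sensitivity_specificity(list(TP = 5, FN = 5, TN = 0, FP = 0)),
               "no negative")

  expect_equal(balanced_accuracy(0.6, 0.6), 0.6)
  expect_equal(balanced_accuracy(0.8, 0.7), 0.75)
  conf <- confusion_counts(c("p", "p", "n", "n"), c("p", "n", "n", "n"), "p")
  expect_equal(conf, list(TP = 1L, FP = 0L, TN = 2L, FN = 1L))
})

test_that("the Friedman statistic matches hand rank sums and closed forms", {
  # identical columns: all average ranks (t+1)/2 and F_r = 0
  same <- data.frame(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  ft <- friedman_rank_test(same)
  expect_equal(ft$statistic, 0)
  expect_true(all(ft$avg_ranks$avg_rank == 2))

  # 3 x 3 strict orderings, hand computation of Eq-style rank sums
  m <- data.frame(a = c(3, 3, 1), b = c(2, 1, 2), c = c(1, 2, 3))
  # ranks (higher value -> higher rank): rows (3,2,1), (3,1,2), (1,2,3)
  Rj <- c(3 + 3 + 1, 2 + 1 + 2, 1 + 2 + 3)
  Fr_hand <- 12 / (3 * 3 * 4) * sum(Rj^2) - 3 * 3 * 4
  ft2 <- friedman_rank_test(m)
  expect_equal(ft2$statistic, Fr_hand)
  expect_equal(ft2$avg_ranks$rank_sum, Rj)

  # agreement with the stats oracle when no ties exist
  set.seed(10)
  mm <- matrix(rnorm(28), 7, 4)
  expect_equal(friedman_rank_test(as.data.frame(mm))$statistic,
               unname(stats::friedman.test(mm)$statistic))

  expect_error(friedman_rank_test(data.frame(a = c(1, NA), b = c(1, 2))),
               "missing cells")
  expect_error(friedman_rank_test(data.frame(a = 1:3)), "at least 2")
})

test_that("Friedman ranks are invariant to monotone transforms and sum correctly", {
  set.seed(12)
  m <- as.data.frame(matrix(runif(40), 8, 5))
  f1 <- friedman_rank_test(m)
  f2 <- friedman_rank_test(exp(3 * m))
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(sum(f1$avg_ranks$rank_sum), 8 * 5 * 6 / 2)
})

test_that("the rank direction puts the best metric at the highest rank", {
  m <- data.frame(worse = c(0.1, 0.2), better = c(0.9, 0.8))
  ft <- friedman_rank_test(m)
  expect_gt(ft$avg_ranks$avg_rank[ft$avg_ranks$algorithm == "better"],
            ft$avg_ranks$avg_rank[ft$avg_ranks$algorithm == "worse"])
})

test_that("sign-test win/draw/loss counts and p-values match enumeration", {
  expect_equal(sign_test_wdl(c(1, 2, 3), c(1, 2, 3))[1:3],
               tibble::tibble(win = 0L, draw = 3L, loss = 0L)[1:3],
               ignore_attr = TRUE)
  expect_equal(unlist(sign_test_wdl(c(2, 3, 4), c(1, 2, 3))[1:3]),
               c(win = 3, draw = 0, loss = 0))

  # (3 wins, 0 losses): exhaustive enumeration of all 2^3 sign outcomes
  # gives two-tailed p = 2 * (1/2)^3 = 0.25
  rec <- sign_test_wdl(c(2, 3, 4), c(1, 2, 3))
  outcomes <- expand.grid(rep(list(c(0, 1)), 3))
  p_enum <- mean(rowSums(outcomes) >= 3) + mean(rowSums(outcomes) <= 0)
  expect_equal(rec$p_value, p_enum)
  expect_equal(rec$p_value, 0.25)
  expect_false(rec$significant)

  # draws are decided after rounding to the table precision
  rec2 <- sign_test_wdl(c(0.7294, 0.81), c(0.7291, 0.80), digits = 3)
  expect_equal(unlist(rec2[1:3]), c(win = 1, draw = 1, loss = 0))
  expect_error(sign_test_wdl(1:3, 1:2), "length")

  # matches the binomial-test oracle on an asymmetric record
  rec3 <- sign_test_wdl(c(2, 3, 4, 5, 1, 1), c(1, 2, 3, 4, 5, 9))
  expect_equal(rec3$p_value,
               stats::binom.test(4, 6, 0.5)$p.value)
})

test_that("BAC tracks accuracy on balanced symmetric synthetic data", {
  spec <- random_kcf_model(4, k = 1, seed = 31, domain_size = 2,
                           n_classes = 2, concentration = 2)
  # force an exactly balanced prior
  spec$prior <- c(0.5, 0.5)
  ds <- sample_dataset(spec, 2000)
  tb <- as_tibble(ds)
  fit <- fit_bnc(tb, model = "nb")
  pred <- predict(fit, tb)
  acc <- mean(pred$.pred_class == tb$class)
  conf <- confusion_counts(tb$class, pred$.pred_class, positive = "c1")
  ss <- sensitivity_specificity(conf)
  bac <- balanced_accuracy(ss[1], ss[2])
  expect_equal(unname(bac), acc, tolerance = 0.05)
})
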