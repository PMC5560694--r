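test_that("CPT estimation matches hand counts, smoothing limits and simplex constraints", {
  rows <- c("aaA", "abA", "baA", "aaA", "bbB", "abB", "baB", "bbB")
  ds <- ds_from_rows(rows, attrs = 2)
  nb <- bn_structure(list(integer(0), integer(0)), k = 0)

  # alpha = 0: raw MLE ratios (hand-counted)
  cp0 <- fit_cpts(ds, nb, alpha = 0)
  expect_equal(cp0$prior, c(0.5, 0.5))
  # class A: x1 = a in 3 of 4 instances
  expect_equal(cp0$tables[[1]][, 1], c(3 / 4, 1 / 4))
  expect_equal(cp0$tables[[1]][, 2], c(1 / 4, 3 / 4))
  # class A: x2 = a in 3 of 4 instances
  expect_equal(cp0$tables[[2]][, 1], c(0.75, 0.25))

  # Laplace: (count + 1) / (4 + 2)
  cp1 <- fit_cpts(ds, nb, alpha = 1)
  expect_equal(cp1$tables[[1]][, 1], c(4 / 6, 2 / 6))

  # unobserved parent configuration with alpha = 1 -> uniform conditional
  chain <- bn_structure(list(integer(0), 1L), k = 1)
  dsc <- ds_from_rows(c("aaA", "aaA", "abB", "baB"), attrs = 2,
                      class_levels = c("A", "B"))
  cpc <- fit_cpts(dsc, chain, alpha = 1)
  # parent config (class A, x1 = b) never observed: uniform conditional
  expect_equal(cpc$tables[[2]][, 1, 2], c(0.5, 0.5))

  # every conditional sums to one
  for (cp in list(cp0, cp1, cpc)) {
    for (tb in cp$tables) {
      sums <- apply(tb, seq_along(dim(tb))[-1], sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
  expect_error(fit_cpts(ds, nb, alpha = -1), "non-negative")
})

test_that("naive Bayes posteriors equal Bayes-theorem enumeration", {
  # symmetric single attribute: uniform posterior
  ds <- ds_from_rows(c("aA", "bB"), attrs = 1)
  nb <- bn_structure(list(integer(0)), k = 0)
  cp <- fit_cpts(ds, nb, alpha = 1)
  post <- posterior(cp, ds)
  expect_equal(rowSums(post), rep(1, 2))

  # 2-attribute 2-class toy vs full-joint oracle
  rows <- c("aaA", "abA", "baA", "aaA", "bbB", "abB", "baB", "abB")
  ds <- ds_from_rows(rows, attrs = 2)
  cp <- fit_cpts(ds, nb2 <- bn_structure(list(integer(0), integer(0)), k = 0),
                 alpha = 1)
  post <- posterior(cp, ds)
  for (r in seq_len(nrow(ds$x))) {
    expected <- oracle_joint_posterior(cp$prior, cp$tables,
                                       list(integer(0), integer(0)),
                                       c(2, 2), ds$x[r, ])
    expect_equal(post[r, ], expected, tolerance = 1e-12)
  }
})

test_that("structured posteriors reduce to NB and match joint enumeration", {
  rows <- c("aaA", "abA", "baA", "aaA", "bbB", "abB", "baB", "bbB")
  ds <- ds_from_rows(rows, attrs = 2)
  nb <- bn_structure(list(integer(0), integer(0)), k = 0)
  chain <- bn_structure(list(integer(0), 1L), k = 1)

  # empty parent sets: identical to NB path
  cp_nb <- fit_cpts(ds, nb, alpha = 1)
  expect_equal(posterior(cp_nb, ds), posterior(cp_nb, ds))

  # chain structure vs exhaustive joint
  cp <- fit_cpts(ds, chain, alpha = 1)
  post <- posterior(cp, ds)
  for (r in seq_len(nrow(ds$x))) {
    expected <- oracle_joint_posterior(cp$prior, cp$tables,
                                       chain$parents, c(2, 2), ds$x[r, ])
    expect_equal(post[r, ], expected, tolerance = 1e-12)
  }

  # missing/unseen value: factor skipped, still a proper distribution
  ds_na <- ds
  ds_na$x[1, 2] <- NA_integer_
  p_na <- posterior(cp, ds_na)
  expect_equal(rowSums(p_na), rep(1, nrow(ds$x)))
  # with x2 unobserved the posterior depends on x1 and the prior only
  cp_x1 <- fit_cpts(ds, bn_structure(list(integer(0), integer(0)), k = 0), 1)
  manual <- cp_x1$prior * cp_x1$tables[[1]][ds$x[1, 1], ]
  expect_equal(p_na[1, ], manual / sum(manual), tolerance = 1e-12)
})

test_that("the KCF ensemble averages normalized submodel posteriors", {
  spec <- random_kcf_model(4, k = 2, seed = 5, concentration = 0.5)
  ds <- sample_dataset(spec, 400)
  fit <- train_kcf(ds, k = 2, alpha = 1)
  expect_length(fit$structures, 4)
  post <- posterior_matrix(fit, ds)
  mats <- lapply(fit$cpts, posterior, ds = ds)
  expect_equal(post, (mats[[1]] + mats[[2]] + mats[[3]] + mats[[4]]) / 4)
  expect_equal(rowSums(post), rep(1, nrow(ds$x)))

  # per-submodel posterior equals the joint-enumeration oracle on a few rows
  for (r in c(1, 7, 13)) {
    for (s in 1:4) {
      cp <- fit$cpts[[s]]
      expected <- oracle_joint_posterior(cp$prior, cp$tables, cp$parents,
                                         spec$card, ds$x[r, ])
      expect_equal(mats[[s]][r, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("ensemble averaging is the plain arithmetic mean", {
  # two hand-built submodels with posteriors (0.8, 0.2) and (0.6, 0.4)
  p1 <- matrix(c(0.8, 0.2), 1)
  p2 <- matrix(c(0.6, 0.4), 1)
  expect_equal((p1 + p2) / 2, matrix(c(0.7, 0.3), 1))
})

test_that("single-attribute KCF and AODE reduce to naive Bayes", {
  df <- data.frame(x1 = rep(c("a", "b"), each = 6),
                   class = rep(c("A", "B", "A", "B"), each = 3))
  kcf <- fit_bnc(df, model = "kcf", k = 1)
  aode <- fit_bnc(df, model = "aode")
  nb <- fit_bnc(df, model = "nb")
  expect_equal(predict(kcf, df)[, 1:2], predict(nb, df)[, 1:2])
  expect_equal(predict(aode, df)[, 1:2], predict(nb, df)[, 1:2])
})

test_that("reduction chain: KCF(k=1) submodel equals TAN; KDB(k=0) equals NB", {
  spec <- random_kcf_model(5, k = 2, seed = 17, concentration = 0.5)
  ds <- sample_dataset(spec, 500)
  tb <- as_tibble(ds)

  tan <- fit_bnc(tb, model = "tan")
  kcf1 <- fit_bnc(tb, model = "kcf", k = 1)
  r <- tan$root
  expect_equal(kcf1$structures[[r]]$parents, tan$structures[[1]]$parents)
  expect_equal(posterior(kcf1$cpts[[r]], ds), posterior(tan$cpts[[1]], ds))

  kdb0 <- fit_bnc(tb, model = "kdb", k = 0)
  nb <- fit_bnc(tb, model = "nb")
  expect_equal(kdb0$structures[[1]]$parents, nb$structures[[1]]$parents)
  expect_equal(predict(kdb0, tb), predict(nb, tb))
})

test_that("TAN gives the non-root attribute the root as parent on two attributes", {
  df <- data.frame(x1 = rep(c("a", "b"), 10),
                   x2 = rep(c("u", "v"), 10),
                   class = rep(c("A", "B"), each = 10))
  tan <- fit_bnc(df, model = "tan")
  st <- tan$structures[[1]]
  expect_equal(lengths(st$parents)[tan$root], 0L)
  other <- setdiff(1:2, tan$root)
  expect_equal(st$parents[[other]], as.integer(tan$root))
})

test_that("AODE equals the SPODE-averaging oracle on a 3-attribute toy", {
  rows <- c("aauA", "abvA", "bauA", "aavA", "bbuB", "abvB", "bauB", "bbvB")
  ds <- ds_from_rows(rows, attrs = 3)
  fit <- fit_bnc(ds, model = "aode", alpha = 1)
  post <- posterior_matrix(fit, ds)
  oracle <- matrix(0, nrow(ds$x), 2)
  for (sp in 1:3) {
    parents <- rep(list(sp), 3); parents[[sp]] <- integer(0)
    st <- bn_structure(parents, k = 1)
    cp <- fit_cpts(ds, st, alpha = 1)
    for (r in seq_len(nrow(ds$x))) {
      oracle[r, ] <- oracle[r, ] +
        oracle_joint_posterior(cp$prior, cp$tables, st$parents,
                               c(2, 2, 2), ds$x[r, ])
    }
  }
  expect_equal(post, oracle / 3, tolerance = 1e-12)
})

test_that("posteriors are normalized for every classifier on random inputs", {
  spec <- random_kcf_model(5, k = 2, seed = 23, domain_size = 3, concentration = 1)
  ds <- sample_dataset(spec, 300)
  tb <- as_tibble(ds)
  for (m in c("nb", "tan", "kdb", "kcf", "aode")) {
    fit <- fit_bnc(tb, model = m, k = 2)
    p <- predict(fit, tb)
    probs <- as.matrix(p[, seq_along(fit$class_domain)])
    expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
    expect_true(all(probs >= 0 & probs <= 1))
  }
})

test_that("schema mismatches at prediction time are errors", {
  df <- data.frame(x1 = c("a", "b", "a", "b"), class = c("A", "B", "A", "B"))
  fit <- fit_bnc(df, model = "nb")
  other <- discrete_dataset(
    data.frame(z = c("q", "r"), class = c("A", "B")))
  expect_error(predict(fit, other), "schema")
})

test_that("tidy and glance summarize fitted models", {
  spec <- random_kcf_model(4, k = 2, seed = 2, concentration = 0.5)
  ds <- sample_dataset(spec, 200)
  fit <- train_kcf(ds, k = 2)
  arcs <- tidy(fit)
  expect_true(all(c("submodel_root", "child", "parent") %in% names(arcs)))
  expect_equal(sort(unique(arcs$submodel_root)), 1:4)
  g <- glance(fit)
  expect_equal(g$model, "kcf")
  expect_equal(g$n_submodels, 4L)
  expect_equal(g$n_arcs, nrow(arcs))
})
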