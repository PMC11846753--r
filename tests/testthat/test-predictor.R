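# Prediction framework: enumeration, logistic fit, LOO, AUC, bootstrap.

make_sep_table <- function(n = 16, seed = 1, noise = 0.01) {
  set.seed(seed)
  label <- rep(c("erosion", "no_erosion"), each = n / 2)
  tibble::tibble(
    label = label,
    a = as.numeric(label == "erosion") + rnorm(n, sd = noise),
    b = rnorm(n),
    c = rnorm(n)
  )
}

test_that("model enumeration yields the full subset counts", {
  tab <- fixture_predictor_table()
  specs <- enumerate_models(tab, predictors = fixture_predictors(), max_size = 3)
  sizes <- table(lengths(specs))
  expect_identical(unname(sizes[["1"]]), 10L)
  expect_identical(unname(sizes[["2"]]), as.integer(choose(10, 2)))
  expect_identical(unname(sizes[["3"]]), as.integer(choose(10, 3)))

  tab4 <- make_sep_table(40, seed = 2)
  tab4$d <- rnorm(40)
  specs4 <- enumerate_models(tab4, predictors = c("a", "b", "c", "d"), max_size = 2)
  expect_identical(length(specs4), 4L + 6L)

  expect_error(enumerate_models(tab4, predictors = c("a", "zz")), "zz")
})

test_that("correlation screening removes correlated pairs only from multi-models", {
  set.seed(3)
  tab <- tibble::tibble(
    label = rep(c("erosion", "no_erosion"), 20),
    a = rnorm(40)
  )
  tab$b <- tab$a + rnorm(40, sd = 1e-6)  # perfectly correlated
  tab$c <- rnorm(40)
  specs <- enumerate_models(tab, predictors = c("a", "b", "c"), max_size = 3,
                            correlation_screen = TRUE)
  has_ab <- vapply(specs, function(s) all(c("a", "b") %in% s), logical(1))
  expect_false(any(has_ab))
  # singles always retained
  expect_true(any(vapply(specs, function(s) identical(s, "a"), logical(1))))
  expect_true(any(vapply(specs, function(s) identical(s, "b"), logical(1))))
})

test_that("the ridge logistic fit separates, is scale-invariant, and is honest under the null", {
  tab <- make_sep_table(20, seed = 4)
  fit <- fit_logistic(tab, "a")
  p <- predict(fit, tab)
  expect_true(all(p[tab$label == "erosion"] > 0.5))
  expect_true(all(p[tab$label != "erosion"] < 0.5))

  # doubling the predictor scale leaves predicted probabilities unchanged
  tab2 <- dplyr::mutate(tab, a = 2 * a)
  fit2 <- fit_logistic(tab2, "a")
  expect_equal(predict(fit2, tab2), p, tolerance = 1e-9)

  # slope near zero for a label-independent predictor (vs glm reference)
  set.seed(9)
  big <- tibble::tibble(label = rep(c("erosion", "no_erosion"), 100), x = rnorm(200))
  fitn <- fit_logistic(big, "x")
  ref <- stats::glm(I(label == "erosion") ~ scale(x), data = big, family = binomial())
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(fitn$coefficients[["x"]]), 3 * se)
  # and matches glm closely away from separation
  expect_equal(unname(fitn$coefficients[["x"]]), unname(coef(ref)[2]), tolerance = 1e-3)

  one_class <- tibble::tibble(label = rep("erosion", 5), x = rnorm(5))
  expect_error(fit_logistic(one_class, "x"), "single class")
})

test_that("leave-one-out is leakage-free and handles degenerate folds", {
  tab <- make_sep_table(16, seed = 5)
  probs <- loo_predict(tab, "a")
  expect_length(probs, 16)
  expect_equal(auc(probs, tab$label), 1.0)

  # leakage-free: patient i's probability comes from a fit that never saw
  # row i (explicit refit check on three folds)
  for (i in c(1, 8, 16)) {
    fit_i <- fit_logistic(tab[-i, , drop = FALSE], "a")
    expect_equal(as.numeric(probs[i]),
                 as.numeric(predict(fit_i, tab[i, , drop = FALSE])), tolerance = 1e-12)
  }

  # constant predictor: every probability equals the training-fold
  # prevalence (4/9 when the held-out patient is a positive, 5/9 otherwise)
  tabc <- tibble::tibble(label = rep(c("erosion", "no_erosion"), each = 5), x = 1)
  pc <- loo_predict(tabc, "x")
  expect_equal(as.numeric(pc), rep(c(4 / 9, 5 / 9), each = 5), tolerance = 1e-6)
})

test_that("AUC equals brute-force pair counting everywhere", {
  brute <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 1))  # rounding forces ties
    expect_identical(auc(s, y), brute(s, y))
  }
  expect_equal(auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_error(auc(1:3, c(1, 1, 1)), "single class")

  # the printed eroded/non-eroded max FSS ranking
  t6 <- load_fixture("table6_biomech")
  expect_identical(auc(t6$max_fss_dyn_cm2, t6$label), 54 / 64)

  # cross-check against the reference ROC implementation
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(40); y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("ROC curves are monotone and anchored", {
  set.seed(8)
  s <- rnorm(30); y <- rep(0:1, 15)
  roc <- roc_points(s, y)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
})

test_that("bootstrap evaluation is seeded, bounded and sane on separators", {
  tab <- make_sep_table(16, seed = 10)
  r1 <- bootstrap_evaluate(tab, "a", n_boot = 30, seed = 21)
  r2 <- bootstrap_evaluate(tab, "a", n_boot = 30, seed = 21)
  expect_identical(r1$replicate_aucs, r2$replicate_aucs)
  expect_equal(r1$auc_average, 1.0)
  expect_equal(r1$ci90, c(1.0, 1.0))
  expect_true(all(r1$replicate_aucs >= 0 & r1$replicate_aucs <= 1))
  expect_error(bootstrap_evaluate(tab, "a", n_boot = 0), "n_boot")
})

test_that("model ranking is sorted with deterministic tie-breaks", {
  tab <- make_sep_table(16, seed = 12)
  specs <- list("a", "b", c("a", "b"), "c")
  rk <- rank_models(tab, specs, n_boot = 20, seed = 5)
  expect_identical(nrow(rk), 4L)
  expect_true(all(diff(rk$auc_average) <= 0))
  # the separating predictor tops the ranking, smaller model first on ties
  expect_identical(rk$model[1], "a")
  top_models <- rk$model[rk$auc_average == max(rk$auc_average)]
  expect_true(all(grepl("a", top_models)))

  rk1 <- rank_models(tab, list("b"), n_boot = 10, seed = 1)
  expect_identical(nrow(rk1), 1L)
})

test_that("tidy and glance methods return well-formed tibbles", {
  tab <- make_sep_table(16, seed = 13)
  fit <- fit_logistic(tab, c("a", "b"))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "a", "b"))
  expect_identical(glance(fit)$n, 16L)

  pr <- bootstrap_evaluate(tab, "a", n_boot = 10, seed = 2)
  expect_identical(tidy(pr)$model, "a")
  expect_identical(glance(pr)$n_boot, 10L)
  plt <- autoplot(pr)
  expect_s3_class(plt, "ggplot")
})
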