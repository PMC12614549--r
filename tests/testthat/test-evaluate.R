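separable_fixture <- function(n_pos = 10, n_neg = 6, seed = 55) {
  set.seed(seed)
  tibble::tibble(
    f1 = c(rnorm(n_pos, 5, 0.3), rnorm(n_neg, -5, 0.3)),
    f2 = c(rnorm(n_pos, 5, 0.3), rnorm(n_neg, -5, 0.3)),
    label = factor(rep(c("improved", "unimproved"), times = c(n_pos, n_neg)))
  )
}

test_that("confusion metrics use the improved-positive convention", {
  m <- confusion_metrics(tp = 11, fp = 0, tn = 4, fn = 0)
  expect_equal(as.numeric(m), c(100, 100, 100, 100))

  m <- confusion_metrics(tp = 2, fp = 1, tn = 0, fn = 0)
  expect_equal(m$f1, 80)
  expect_equal(m$spec, 0)
  # no predicted-or-true negatives at all: specificity undefined, not zero
  expect_true(is.na(confusion_metrics(tp = 2, fp = 0, tn = 0, fn = 1)$spec))

  # all-positive prediction over the full 11/4 cohort
  m <- confusion_metrics(tp = 11, fp = 4, tn = 0, fn = 0)
  expect_equal(m$acc, 100 * 11 / 15, tolerance = 1e-10)
  expect_equal(m$sens, 100)
  expect_equal(m$spec, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("stratified CV reaches 100 on a separable fixture", {
  d <- separable_fixture()
  for (fam in list(model_spec("svm", kernel = "linear", cost = 10),
                   model_spec("rf", n_trees = 25),
                   model_spec("edt", n_trees = 25),
                   model_spec("adaboost", learning_rate = 0.1),
                   model_spec("ann", hidden = 5))) {
    ev <- stratified_cv_eval(d[, c("f1", "f2")], d$label, fam, seed = 2)
    expect_equal(glance(ev)$acc, 100,
                 info = paste("family", fam$family))
  }
  expect_error(stratified_cv_eval(d[, 1:2], d$label, k = 20), "k must be")
})

test_that("undersampling evaluation is reproducible and separable-perfect", {
  d <- separable_fixture()
  ev1 <- undersample_eval(d[, 1:2], d$label, model_spec("svm"),
                          reps = 20, seed = 9)
  ev2 <- undersample_eval(d[, 1:2], d$label, model_spec("svm"),
                          reps = 20, seed = 9)
  expect_identical(tidy(ev1), tidy(ev2))
  expect_equal(glance(ev1)$acc, 100)
  expect_equal(nrow(tidy(ev1)), 20)
  expect_error(undersample_eval(d[, 1:2], d$label, per_class = 6), "minority")
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  d <- separable_fixture(n_pos = 9, n_neg = 4)
  bal <- smote_balance(d[, 1:2], d$label, k_neighbors = 2, seed = 3)
  expect_equal(as.integer(table(bal$labels)), c(9L, 9L))

  minority <- as.matrix(d[d$label == "unimproved", 1:2])
  for (r in seq_len(nrow(bal$synthetic))) {
    p <- as.numeric(bal$synthetic[r, ])
    # on a segment between two true minority points: for some pair (i, j),
    # p - xi is parallel to xj - xi with coefficient in [0, 1]
    on_segment <- FALSE
    for (i in seq_len(nrow(minority))) {
      for (j in seq_len(nrow(minority))) {
        if (i == j) next
        v <- minority[j, ] - minority[i, ]
        w <- p - minority[i, ]
        t1 <- sum(w * v) / sum(v * v)
        if (t1 >= -1e-9 && t1 <= 1 + 1e-9 &&
            sqrt(sum((w - t1 * v)^2)) < 1e-9) on_segment <- TRUE
      }
    }
    expect_true(on_segment)
  }
  # convex-hull containment along each coordinate
  expect_true(all(apply(bal$synthetic, 2, min) >= apply(minority, 2, min) - 1e-9))
  expect_true(all(apply(bal$synthetic, 2, max) <= apply(minority, 2, max) + 1e-9))

  expect_error(smote_balance(d[1:6, 1:2], d$label[1:6]), "both classes")
  expect_error(smote_balance(d[c(1:6, 10:11), 1:2], d$label[c(1:6, 10:11)],
                             k_neighbors = 5),
               "exceed")
})

test_that("SMOTE-augmented CV stays perfect on the separable fixture", {
  d <- separable_fixture(n_pos = 11, n_neg = 4)
  ev <- smote_cv_eval(d[, 1:2], d$label, model_spec("svm", kernel = "linear"),
                      seed = 8)
  expect_equal(glance(ev)$acc, 100)
  expect_equal(nrow(tidy(ev)), 5)
})

test_that("Mann-Whitney group test matches exact enumeration", {
  expect_equal(session_group_test(c(rep(2, 4), rep(2, 4)),
                                  rep(c("improved", "unimproved"), each = 4)),
               1)

  # complete separation, groups 4 and 11
  vals <- c(101:111, 1:4)
  labs <- rep(c("improved", "unimproved"), times = c(11, 4))
  expect_equal(session_group_test(vals, labs), 2 / choose(15, 4),
               tolerance = 1e-12)
  expect_equal(mw_exact_enumeration(vals[12:15], vals[1:11]), 2 / 1365,
               tolerance = 1e-12)

  # random untied case equals the enumeration oracle
  set.seed(12)
  a <- rnorm(5); b <- rnorm(6) + 0.8
  labs2 <- rep(c("improved", "unimproved"), times = c(5, 6))
  expect_equal(session_group_test(c(a, b), labs2),
               mw_exact_enumeration(a, b), tolerance = 1e-12)

  expect_error(session_group_test(1:3, rep("improved", 3)), "non-empty")
})

test_that("model grids stay inside the documented ranges", {
  svm_grid <- model_grid("svm")
  costs <- vapply(svm_grid, `[[`, numeric(1), "cost")
  expect_true(all(costs >= 0.1 & costs <= 10000))
  kernels <- unique(vapply(svm_grid, `[[`, character(1), "kernel"))
  expect_setequal(kernels, c("linear", "rbf", "poly3"))

  ada_grid <- model_grid("adaboost")
  lr <- vapply(ada_grid, `[[`, numeric(1), "learning_rate")
  nl <- vapply(ada_grid, `[[`, integer(1), "n_learners")
  expect_true(all(lr %in% c(0.001, 0.01, 0.1)))
  expect_true(all(nl %in% c(15L, 20L, 25L, 30L)))

  rf_grid <- model_grid("rf")
  expect_true(all(vapply(rf_grid, `[[`, integer(1), "min_leaf") %in%
                    c(1L, 5L, 10L)))
  ann <- model_spec("ann")
  expect_equal(ann$epochs, 1000L)
  expect_equal(ann$ridge, 0.01)
})
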