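test_that("fold plans partition records with balanced, stratified folds", {
  labels <- factor(rep(c("none", "2mm", "3mm", "4mm", "5mm", "6mm"),
                       times = c(750, 1350, 1350, 1350, 1350, 1350)))
  plan <- make_folds(7500, 10, labels, seed = 3)
  expect_identical(unname(table(plan$assignments)),
                   as.array(rep(750L, 10)), ignore_attr = TRUE)
  expect_length(plan$assignments, 7500)
  # stratification: per-fold class counts within 1 of n_c / k
  tab <- table(labels, plan$assignments)
  expect_true(all(abs(tab - rowSums(tab) / 10) <= 1))

  # singleton folds
  p1 <- make_folds(10, 10, factor(rep("a", 10)), seed = 1)
  expect_identical(sort(p1$assignments), 1:10)

  expect_error(make_folds(5, 10, seed = 1), "k <= n")
})

test_that("fold assignment is exhaustive and disjoint for odd sizes", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(23:97, 1)
    k <- sample(2:7, 1)
    labels <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    plan <- make_folds(n, k, labels, seed = i)
    expect_identical(sort(unique(plan$assignments)), seq_len(k))
    expect_length(plan$assignments, n)      # every record in exactly 1 fold
    sizes <- table(plan$assignments)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("PNN behaves as a kernel-density classifier", {
  # nearest-pattern limit: tiny spread predicts the matching training class
  train_X <- matrix(c(0, 0, 1, 1, 5, 5, 6, 6), 4, 2, byrow = TRUE)
  train_y <- factor(c("a", "a", "b", "b"))
  pred <- pnn_predict(train_X, train_y, train_X[c(1, 3), , drop = FALSE],
                      spread = 1e-3)
  expect_identical(as.character(pred), c("a", "b"))

  # well-separated Gaussian classes classify almost perfectly
  set.seed(62)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * 2, sd = 0.1), n, 2) +
    ifelse(y == "a", 0, 1)
  test_idx <- sample(n, 60)
  pred2 <- pnn_predict(x[-test_idx, ], y[-test_idx], x[test_idx, ],
                       spread = 0.1)
  expect_gte(mean(pred2 == y[test_idx]), 0.95)

  # scores match a double-loop kernel-sum oracle
  spread <- 0.3
  tr <- matrix(rnorm(20), 10, 2)
  ty <- factor(rep(c("a", "b"), 5))
  te <- matrix(rnorm(6), 3, 2)
  oracle_pred <- sapply(1:3, function(i) {
    sc <- sapply(levels(ty), function(cl) {
      idx <- which(ty == cl)
      mean(sapply(idx, function(j) {
        exp(-sum((te[i, ] - tr[j, ])^2) / (2 * spread^2))
      }))
    })
    names(sc)[which.max(sc)]
  })
  expect_identical(as.character(pnn_predict(tr, ty, te, spread)), oracle_pred)
})

test_that("the three classifiers fit separable data", {
  set.seed(63)
  n <- 120
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * 2, sd = 0.2), n, 2) + ifelse(y == "a", 0, 3)
  expect_identical(as.character(train_predict(x, y, x, "svm_linear")),
                   as.character(y))
  for (m in list("svm_linear", "gaussian_nb", list(name = "pnn", spread = 0.2))) {
    acc <- mean(train_predict(x, y, x, m) == y)
    expect_gte(acc, 0.99)
  }
  expect_error(train_predict(x[y == "a", ], y[y == "a"], x, "svm_linear"),
               "single class")
})

test_that("Gaussian NB places its boundary near the analytic midpoint", {
  set.seed(64)
  n <- 4000
  y <- factor(rep(c("lo", "hi"), each = n / 2))
  x <- matrix(rnorm(n, mean = ifelse(y == "lo", 0, 2)), ncol = 1)
  grid <- matrix(seq(0, 2, by = 0.01), ncol = 1)
  pred <- train_predict(x, y, grid, "gaussian_nb")
  # equal priors, equal variances: analytic threshold at the midpoint 1
  boundary <- grid[max(which(pred == "lo")), 1]
  expect_lt(abs(boundary - 1), 0.1)   # within 5% of the class separation
})

test_that("confusion metrics match the counting oracle", {
  # binary worked example: TP = 9, FN = 2, FP = 1, TN = 8
  cm <- matrix(c(9, 2, 1, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  sc <- score_confusion(as.table(cm))
  pos <- sc$per_class[sc$per_class$class == "pos", ]
  expect_equal(pos$accuracy, 85)
  expect_equal(pos$sensitivity, 81.82, tolerance = 1e-3)
  expect_equal(pos$specificity, 88.89, tolerance = 1e-3)

  # perfect diagonal: all macro metrics 100
  perf <- diag(c(5, 7, 9))
  sc2 <- score_confusion(perf)
  expect_equal(sc2$accuracy, 100)
  expect_equal(sc2$macro_accuracy, 100)
  expect_equal(sc2$sensitivity, 100)
  expect_equal(sc2$specificity, 100)

  # random 6 x 6 tables against the element-by-element oracle
  set.seed(65)
  for (i in 1:5) {
    t6 <- matrix(rpois(36, 5) + 1, 6, 6)
    sc6 <- score_confusion(t6)
    want <- t(sapply(1:6, function(ci) oracle_metrics(t6, ci)))
    expect_equal(sc6$per_class$accuracy, want[, "accuracy"], tolerance = 1e-10)
    expect_equal(sc6$per_class$sensitivity, want[, "sensitivity"],
                 tolerance = 1e-10)
    expect_equal(sc6$per_class$specificity, want[, "specificity"],
                 tolerance = 1e-10)
    expect_equal(sc6$accuracy, 100 * sum(diag(t6)) / sum(t6),
                 tolerance = 1e-10)
    expect_equal(sc6$macro_accuracy, mean(want[, "accuracy"]),
                 tolerance = 1e-10)
    expect_equal(sc6$sensitivity, mean(want[, "sensitivity"]),
                 tolerance = 1e-10)
  }

  # absent class excluded from the macro-average
  absent <- matrix(c(4, 0, 0, 0, 0, 0, 1, 0, 5), 3, 3, byrow = TRUE)
  sc3 <- score_confusion(absent)
  expect_identical(sc3$excluded, "2") # row 2 empty
})

test_that("cross-validation emits one confusion per fold and is fold-stable", {
  set.seed(66)
  n <- 300
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  x <- matrix(rnorm(n * 2, sd = 0.4), n, 2) + as.integer(y)
  rep1 <- cross_validate(x, y, "gaussian_nb", k = 10, seed = 5)
  expect_length(rep1$folds, 10)
  expect_true(all(vapply(rep1$folds,
                         function(f) sum(f$confusion) == 30, logical(1))))
  expect_true(all(rep1$average >= 0 & rep1$average <= 100))
  expect_equal(rep1$average["accuracy"],
               mean(rep1$per_fold$accuracy), ignore_attr = TRUE)

  # permuting the records together with the fold plan leaves every
  # (deterministic) classifier's averaged metrics exactly unchanged
  plan <- make_folds(n, 10, y, seed = 5)
  perm <- sample(n)
  plan_perm <- plan
  plan_perm$assignments <- plan$assignments[perm]
  for (m in list("svm_linear", "gaussian_nb", list(name = "pnn", spread = 0.5))) {
    a <- cross_validate(x, y, m, folds = plan)
    b <- cross_validate(x[perm, ], y[perm], m, folds = plan_perm)
    expect_equal(a$average, b$average, tolerance = 1e-10)
  }
})

test_that("label-permuted data classifies at chance level", {
  set.seed(67)
  accs <- replicate(20, {
    n <- 360
    x <- matrix(rnorm(n * 3), n, 3)
    y <- factor(sample(rep(1:6, each = n / 6)))
    cross_validate(x, y, "gaussian_nb", k = 10,
                   seed = sample.int(1e6, 1))$average["accuracy"]
  })
  # six balanced classes: chance correct-classification rate is 1/6
  expect_gte(mean(accs), 10)
  expect_lte(mean(accs), 24)
})
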