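test_that("confusion matrices count correctly and reject unseen labels", {
  lev <- c("A", "B", "C")
  true <- factor(c("A", "A", "B", "C"), levels = lev)
  cm <- confusion(true, c("A", "A", "B", "C"), lev)
  expect_equal(unname(diag(cm)), c(2L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_error(confusion(true, c("A", "A", "B", "D"), lev), "class_order")
  withr::with_seed(14, {
    for (i in 1:5) {
      t <- sample(lev, 30, replace = TRUE)
      p <- sample(lev, 30, replace = TRUE)
      cm <- confusion(t, p, lev)
      expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(t, lev)))))
      expect_equal(sum(cm), 30L)
    }
  })
})

test_that("accuracy equals one minus the off-diagonal fraction", {
  withr::with_seed(15, {
    for (i in 1:5) {
      lev <- c("A", "B", "C", "D")
      t <- factor(sample(lev, 40, replace = TRUE), levels = lev)
      t[1:4] <- lev
      p <- sample(lev, 40, replace = TRUE)
      cm <- confusion(t, p, lev)
      m <- metrics(cm)
      expect_equal(m$accuracy, 1 - (sum(cm) - sum(diag(cm))) / sum(cm))
    }
  })
})

test_that("a perfect confusion matrix gives unit metrics", {
  cm <- confusion(rep(c("FC", "COUNTERFEIT"), c(6, 4)),
                  rep(c("FC", "COUNTERFEIT"), c(6, 4)),
                  c("FC", "COUNTERFEIT"))
  m <- metrics(cm, positive_class = "FC")
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity, m$precision),
               rep(1, 4))
})

test_that("macro metrics warn about empty classes and drop them", {
  cm <- confusion(factor(c("A", "A", "B"), levels = c("A", "B", "C")),
                  factor(c("A", "B", "B"), levels = c("A", "B", "C")),
                  c("A", "B", "C"))
  expect_warning(m <- metrics(cm), "C")
  expect_false(is.na(m$sensitivity))
})

test_that("ROC separates perfectly when scores do, and AUC matches pair counting", {
  r <- roc_auc(c(5, 4, 3, 0.2, 0.1), rep(c("P", "N"), c(3, 2)), positive = "P")
  expect_equal(r$auc, 1)
  withr::with_seed(16, {
    for (i in 1:20) {
      n <- 25
      truth <- factor(sample(c("P", "N"), n, replace = TRUE))
      truth[1:2] <- c("P", "N")
      sc <- round(rnorm(n), 1)  # coarse scores force ties
      got <- roc_auc(sc, truth, positive = "P")$auc
      expect_equal(got, auc_pairs_oracle(sc, truth, "P"), tolerance = 1e-12)
      # invariance under strictly monotone transforms
      expect_equal(roc_auc(exp(sc), truth, positive = "P")$auc, got,
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:4, rep("P", 4)), "two classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  withr::with_seed(18, {
    truth <- factor(rep(c("P", "N"), c(12, 13)))
    sc <- rnorm(25) + (truth == "P") * 1.2
  })
  got <- roc_auc(sc, truth, positive = "P")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = sc,
                                        levels = c("N", "P"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("the Welch t-test matches the textbook formula and has power", {
  v1 <- c(1, 2, 3, 4); v2 <- c(2, 4, 6, 9)
  got <- group_ttest(c(v1, v2), rep(c("A", "B"), each = 4))
  ora <- welch_oracle(v1, v2)
  expect_equal(got$statistic, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  same <- group_ttest(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_ttest(rep(c(0, 1), each = 3), rep(c("A", "B"), each = 3)),
               "zero variance")
  sig <- vapply(1:20, function(s) {
    withr::with_seed(500 + s,
      group_ttest(c(rnorm(20), rnorm(20, 3)),
                  rep(c("A", "B"), each = 20))$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("LOOCV refits per fold and is permutation-equivariant", {
  withr::with_seed(19, {
    x <- cbind(rep(c(0, 10), each = 6) + rnorm(12, sd = 0.1),
               rnorm(12))
    y <- factor(rep(c("A", "B"), each = 6))
  })
  cv <- loocv(x, y, list(method = "plsda", n_lv = 1))
  expect_equal(mean(cv$pred == y), 1)
  # n = 4 two-class case: exactly 4 predictions, order equivariance
  x4 <- x[c(1, 2, 7, 8), ]; y4 <- y[c(1, 2, 7, 8)]
  cv4 <- loocv(x4, y4, list(method = "plsda", n_lv = 1))
  expect_length(cv4$pred, 4L)
  perm <- c(3, 1, 4, 2)
  cvp <- loocv(x4[perm, ], y4[perm], list(method = "plsda", n_lv = 1))
  expect_identical(as.character(cvp$pred), as.character(cv4$pred)[perm])
  expect_equal(cvp$scores, cv4$scores[perm, ])
})

test_that("the LOOCV driver equals an independently coded leave-one-out loop", {
  withr::with_seed(20, {
    x <- matrix(rnorm(20 * 8), 20, 8)
    y <- factor(rep(c("A", "B"), 10))
    x[y == "B", 1] <- x[y == "B", 1] + 2
  })
  cv <- loocv(x, y, list(method = "plsda", n_lv = 3))
  manual <- character(20)
  for (i in 1:20) {
    fit <- fit_plsda(x[-i, ], y[-i], n_lv = 3, levels = levels(y))
    manual[i] <- as.character(predict(fit, x[i, , drop = FALSE])$class)
  }
  expect_identical(as.character(cv$pred), manual)
})

test_that("a fold that loses a class names the offending sample", {
  x <- matrix(rnorm(8), 4, 2,
              dimnames = list(paste0("S", 1:4), NULL))
  y <- factor(c("A", "A", "A", "B"))
  expect_error(loocv(x, y, list(method = "plsda", n_lv = 1)), "S4")
})
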