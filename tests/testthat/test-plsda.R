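test_that("class encoding produces indicator columns that decode back", {
  enc <- encode_classes(c("A", "B", "A"))
  expect_equal(unname(enc$Y), matrix(c(1, 0, 1, 0, 1, 0), 3, 2))
  enc4 <- encode_classes(c("A", "B", "C", "D"))
  expect_equal(ncol(enc4$Y), 4L)
  expect_equal(unname(rowSums(enc4$Y)), rep(1, 4))
  expect_error(encode_classes(rep("A", 3)), "at least 2 classes")
  withr::with_seed(8, {
    for (i in 1:10) {
      lab <- sample(LETTERS[1:4], 12, replace = TRUE)
      lab[1:4] <- LETTERS[1:4]  # all classes present
      enc <- encode_classes(lab)
      expect_identical(as.character(decode_classes(enc$Y, enc$levels)), lab)
    }
  })
  # tie goes to the first class in coding order
  expect_equal(as.character(decode_classes(matrix(c(0.5, 0.5), 1, 2,
                                                  dimnames = list(NULL, c("A", "B"))))),
               "A")
})

test_that("a perfect single-variable predictor is recovered with one component", {
  d <- make_two_class(n = 16, p = 4, delta = 50, seed = 21)
  m <- fit_plsda(d$x, d$y, n_lv = 1)
  pr <- predict(m, d$x)
  expect_equal(as.character(pr$class), as.character(d$y))
  expect_equal(which.max(rowSums(abs(m$B))), 1L)
})

test_that("full-rank PLS equals multi-output least squares from the normal equations", {
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- matrix(rnorm(20 * 8), 20, 8)
      y <- factor(sample(c("A", "B", "C"), 20, replace = TRUE,
                         prob = c(0.4, 0.3, 0.3)))
      while (nlevels(droplevels(y)) < 3)
        y <- factor(sample(c("A", "B", "C"), 20, replace = TRUE))
      m <- fit_plsda(x, y, n_lv = 8)
      B_ls <- ls_coef_oracle(x, encode_classes(y)$Y)
      expect_lt(max(abs(m$B - B_ls)), 1e-6)
    }
  })
})

test_that("single-predictor coefficients reduce to cov(x, y)/var(x)", {
  withr::with_seed(13, {
    x <- matrix(rnorm(30), 30, 1)
    y <- factor(rep(c("A", "B"), 15))
  })
  m <- fit_plsda(x, y, n_lv = 1)
  Yc <- scale(encode_classes(y)$Y, scale = FALSE)
  xc <- x - mean(x)
  expected <- crossprod(xc, Yc) / sum(xc^2)
  expect_equal(unname(m$B), unname(expected), tolerance = 1e-10)
})

test_that("scores are orthogonal and explained variance accumulates to one", {
  withr::with_seed(17, {
    x <- matrix(rnorm(15 * 6), 15, 6)
    y <- factor(rep(c("A", "B", "C"), 5))
  })
  m <- fit_plsda(x, y, n_lv = 6)
  g <- crossprod(m$T)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
  expect_true(all(diff(cumsum(m$explained_x)) >= -1e-12))
  expect_equal(sum(m$explained_x), 1, tolerance = 1e-8)
  expect_true(all(m$explained_x >= -1e-12 & m$explained_x <= 1 + 1e-12))
  # B identity: W (P'W)^-1 Q'
  expect_equal(m$B, m$W %*% solve(crossprod(m$P, m$W), t(m$Q)),
               tolerance = 1e-8)
})

test_that("latent-variable selection maximizes LOOCV accuracy with parsimony", {
  d <- make_two_class(n = 18, p = 5, delta = 6, seed = 9)
  one <- select_n_lv(d$x, d$y, max_lv = 1)
  expect_equal(one$n_lv, 1L)
  expect_length(one$accuracy, 1L)
  sl <- select_n_lv(d$x, d$y, max_lv = 4)
  expect_length(sl$accuracy, 4L)
  expect_equal(sl$accuracy[sl$n_lv], max(sl$accuracy))
  expect_true(all(sl$accuracy[seq_len(sl$n_lv - 1)] < max(sl$accuracy)))
  expect_warning(capped <- select_n_lv(d$x, d$y, max_lv = 17), "capped")
  expect_lte(length(capped$accuracy), 16L)
})

test_that("one-informative-variable data selects a single component in most seeds", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      x <- matrix(rnorm(24 * 5), 24, 5)
      y <- factor(ifelse(x[, 1] > 0, "A", "B"), levels = c("A", "B"))
      x[, 1] <- x[, 1] + sign(x[, 1]) * 3
    })
    if (nlevels(droplevels(y)) < 2) return(NA)
    select_n_lv(x, y, max_lv = 3)$n_lv == 1L
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("VIP satisfies its normalization and matches a step-by-step oracle", {
  withr::with_seed(23, {
    x <- matrix(rnorm(18 * 5), 18, 5)
    y <- factor(rep(c("A", "B"), 9))
    x[y == "B", 2] <- x[y == "B", 2] + 3
  })
  m <- fit_plsda(x, y, n_lv = 3)
  v <- compute_vip(m)
  p <- ncol(x)
  expect_equal(sum(v$scores^2), p, tolerance = 1e-6)
  # independent element-by-element evaluation of the SSY-weighted formula
  ssy <- vapply(1:3, function(a)
    sum(m$T[, a]^2) * sum(m$Q[, a]^2), numeric(1))
  vip_manual <- vapply(seq_len(p), function(j) {
    num <- 0
    for (a in 1:3)
      num <- num + ssy[a] * (m$W[j, a] / sqrt(sum(m$W[, a]^2)))^2
    sqrt(p * num / sum(ssy))
  }, numeric(1))
  expect_equal(unname(v$scores), vip_manual, tolerance = 1e-8)
  # p = 1 forces VIP = 1
  m1 <- fit_plsda(x[, 2, drop = FALSE], y, n_lv = 1)
  expect_equal(unname(compute_vip(m1)$scores), 1, tolerance = 1e-10)
})

test_that("prediction rejects mismatched widths and separable data is perfect", {
  d <- make_two_class(n = 20, p = 3, delta = 5, seed = 33)
  m <- fit_plsda(d$x, d$y, n_lv = 2)
  expect_error(predict(m, d$x[, 1:2]), "mismatch")
  expect_equal(mean(predict(m, d$x)$class == d$y), 1)
})
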