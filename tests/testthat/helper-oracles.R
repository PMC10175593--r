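# Independent oracles and small fixture builders used across the test files.

# multi-output least squares on centered data (normal equations)
ls_coef_oracle <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  solve(crossprod(xc), crossprod(xc, yc))
}

# direct pooled-covariance LDA on the raw variables (explicit scatter
# inversion), returning classes and discriminant scores for newdata
lda_oracle <- function(x, labels, newdata) {
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  n <- nrow(x); g <- length(lev)
  mu <- do.call(rbind, lapply(lev, function(k)
    colMeans(x[labels == k, , drop = FALSE])))
  Sp <- matrix(0, ncol(x), ncol(x))
  for (k in lev) {
    xk <- scale(x[labels == k, , drop = FALSE], scale = FALSE)
    Sp <- Sp + crossprod(xk)
  }
  Sp <- Sp / (n - g)
  Si <- solve(Sp)
  priors <- as.numeric(table(labels)) / n
  delta <- newdata %*% Si %*% t(mu)
  delta <- sweep(delta, 2, -0.5 * rowSums((mu %*% Si) * mu) + log(priors), "+")
  colnames(delta) <- lev
  list(class = factor(lev[max.col(delta, ties.method = "first")], levels = lev),
       scores = delta)
}

# AUC by brute-force pair counting (ties count one half)
auc_pairs_oracle <- function(scores, truth, positive) {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Welch t statistic written out from the textbook formula
welch_oracle <- function(v1, v2) {
  se2 <- var(v1) / length(v1) + var(v2) / length(v2)
  t <- (mean(v1) - mean(v2)) / sqrt(se2)
  df <- se2^2 / ((var(v1) / length(v1))^2 / (length(v1) - 1) +
                   (var(v2) / length(v2))^2 / (length(v2) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small labeled matrix with one separating direction
make_two_class <- function(n = 20, p = 4, delta = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("A", "B"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    x[y == "B", 1] <- x[y == "B", 1] + delta
    list(x = x, y = factor(y, levels = c("A", "B")))
  })
}

# the study-sized label table: FU S1-S20, FP S21-S22+S25-S40, FD S41-S42+
# S44-S60, FUS S23+S24+S43+S61-S80 (57 authentic / 23 counterfeit)
study_labels <- function() {
  species <- rep("FUS", 80)
  species[1:20] <- "FU"
  species[c(21:22, 25:40)] <- "FP"
  species[c(41:42, 44:60)] <- "FD"
  label_table(paste0("S", 1:80),
              authenticity = ifelse(species == "FUS", "COUNTERFEIT", "FC"),
              species = species)
}

# per-class predictions from a misclassification count table:
# `errors[[true]]` is a named vector of counts sent to other classes;
# 20 samples per class, four species
species_pred_from_errors <- function(errors) {
  lev <- c("FU", "FP", "FD", "FUS")
  true <- factor(rep(lev, each = 20), levels = lev)
  pred <- as.character(true)
  for (k in names(errors)) {
    idx <- which(true == k)
    wrong <- rep(names(errors[[k]]), times = errors[[k]])
    pred[idx[seq_along(wrong)]] <- wrong
  }
  list(true = true, pred = factor(pred, levels = lev))
}
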