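#' Univariate Wilks' lambda of one variable across groups
#'
#' \eqn{\Lambda = SSW / SST}: within-group sum of squares over total sum of
#' squares. Lies in \[0, 1\]; smaller values mean stronger between-group
#' separation, so variables with large \eqn{\Lambda} are the first candidates
#' for elimination. Invariant to shifting/rescaling the variable.
#'
#' @param values numeric vector, one value per sample.
#' @param groups group tags, >= 2 groups each with >= 1 sample.
#' @return scalar \eqn{\Lambda}.
#' @examples
#' wilks_lambda(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # 0.2
#' @export
wilks_lambda <- function(values, groups) {
  values <- as.numeric(values)
  groups <- as_class_factor(groups)
  if (length(values) != length(groups)) abort("length mismatch")
  if (nlevels(groups) < 2) abort("need >= 2 groups")
  sst <- sum((values - mean(values))^2)
  if (sst <= 0) abort("zero total variance; Wilks' lambda undefined")
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  ssw / sst
}

# vectorized over matrix columns; sst == 0 columns get lambda 1 when
# na_one = TRUE (undiscriminating), else error via wilks_lambda
wilks_lambda_mat_ <- function(x, groups, na_one = TRUE) {
  groups <- as_class_factor(groups)
  center_all <- colMeans(x)
  sst <- colSums(sweep(x, 2, center_all)^2)
  ssw <- numeric(ncol(x))
  for (g in levels(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    ssw <- ssw + colSums(sweep(xg, 2, colMeans(xg))^2)
  }
  lam <- ifelse(sst > 0, ssw / sst, if (na_one) 1 else NA_real_)
  names(lam) <- colnames(x)
  lam
}

# ---- pooled-covariance linear discriminant on score space ------------------
lda_fit_ <- function(scores, labels, priors = c("proportional", "uniform")) {
  priors <- match.arg(priors)
  labels <- droplevels(labels)
  g <- nlevels(labels)
  n <- nrow(scores)
  counts <- table(labels)
  if (any(counts < 1)) abort("empty class in LDA fit")
  mu <- do.call(rbind, lapply(levels(labels),
                function(k) colMeans(scores[labels == k, , drop = FALSE])))
  rownames(mu) <- levels(labels)
  Sp <- matrix(0, ncol(scores), ncol(scores))
  for (k in levels(labels)) {
    sk <- scores[labels == k, , drop = FALSE]
    sk <- sweep(sk, 2, colMeans(sk))
    Sp <- Sp + crossprod(sk)
  }
  Sp <- Sp / (n - g)
  cov_inv <- tryCatch(solve(Sp), error = function(e)
    abort("singular pooled within-class covariance; use a smaller n_pc"))
  pi_k <- if (priors == "uniform") rep(1 / g, g) else as.numeric(counts) / n
  list(means = mu, cov_inv = cov_inv, priors = pi_k, levels = levels(labels))
}

# discriminant scores delta_k(s) = s' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k
lda_delta_ <- function(fit, scores) {
  lin <- scores %*% fit$cov_inv %*% t(fit$means)
  const <- -0.5 * rowSums((fit$means %*% fit$cov_inv) * fit$means) +
    log(fit$priors)
  sweep(lin, 2, const, "+")
}

#' Fit a PCA-DA model (principal components + linear discriminant analysis)
#'
#' Principal component analysis on the pretreated data, then a linear
#' discriminant classifier with pooled within-class covariance on the first
#' `n_pc` score dimensions. Class priors are proportional to class sizes by
#' default (`priors = "uniform"` is available; note that proportional priors
#' make leave-one-out estimates on signal-free data pessimistic, because the
#' held-out sample's class always has the smallest training prior).
#' With `n_pc = "auto"` the component count is picked to maximize the
#' leave-one-out accuracy (smallest count on ties); the accuracy curve is
#' kept on the model.
#'
#' @param x numeric matrix (samples x variables).
#' @param labels class tags (>= 2 classes, each with >= 2 samples).
#' @param n_pc number of retained components, or `"auto"`.
#' @param pretreatment `"center"` (default), `"autoscale"` or `"none"`.
#' @param max_pc cap on the component count searched/allowed (default 10);
#'   additionally capped at `n - g - 1` and at the matrix rank.
#' @param priors `"proportional"` (to class sizes, default) or `"uniform"`.
#' @param levels optional class order.
#' @return A `pcada` model: `rotation` (p x n_pc PCA loadings), discriminant
#'   `means`, `cov_inv`, `priors`, the stored centering model, and (for
#'   auto selection) `cv_accuracy`.
#' @export
fit_pcada <- function(x, labels, n_pc = "auto",
                      pretreatment = c("center", "autoscale", "none"),
                      max_pc = 10, priors = c("proportional", "uniform"),
                      levels = NULL) {
  pretreatment <- match.arg(pretreatment)
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as_class_factor(labels, levels)
  if (length(labels) != nrow(x)) abort("labels length != number of rows")
  g <- nlevels(labels)
  if (g < 2) abort("need >= 2 classes")
  cv_acc <- NULL
  cap <- npc_cap_(nrow(x), ncol(x), g, max_pc)
  if (identical(n_pc, "auto")) {
    cv <- pcada_cv_(x, labels, cap, pretreatment, priors)
    n_pc <- cv$n_pc
    cv_acc <- cv$accuracy
  } else {
    n_pc <- as.integer(n_pc)
    if (n_pc < 1 || n_pc > cap)
      abort("n_pc must be in 1..", cap, " (n - g - 1 / rank / max_pc cap)")
  }
  pre <- pretreat_(x, pretreatment)
  pca <- stats::prcomp(pre$x, center = FALSE)
  rotation <- pca$rotation[, seq_len(n_pc), drop = FALSE]
  scores <- pre$x %*% rotation
  ld <- lda_fit_(scores, labels, priors)
  structure(list(n_pc = n_pc, rotation = rotation,
                 means = ld$means, cov_inv = ld$cov_inv, priors = ld$priors,
                 centering = pre$model, levels = ld$levels,
                 pretreatment = pretreatment, cv_accuracy = cv_acc,
                 var_names = colnames(x)),
            class = "pcada")
}

npc_cap_ <- function(n, p, g, max_pc) {
  cap <- min(n - g - 1, p, n - 1, max_pc)
  if (cap < 1) abort("too few samples for PCA-DA (n - g - 1 < 1)")
  cap
}

#' @export
print.pcada <- function(x, ...) {
  cat(sprintf("<pcada: %d principal components, classes: %s>\n",
              x$n_pc, paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict classes from a PCA-DA model
#'
#' Projects new rows onto the retained principal components and assigns the
#' class maximizing the linear discriminant score
#' \eqn{\delta_k(s) = s^\top \Sigma^{-1}\mu_k - \frac12 \mu_k^\top
#' \Sigma^{-1}\mu_k + \ln \pi_k}. Every sample is assigned a class (no
#' "unclassified" outcome); exact ties go to the first class in label order
#' and are counted in the `n_ties` attribute.
#'
#' @param object a `pcada` model.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return list with `class` (factor) and `scores` (n x g discriminant
#'   score matrix).
#' @export
predict.pcada <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$rotation))
    abort("column count mismatch: model has ", nrow(object$rotation),
          " variables, newdata has ", ncol(newdata))
  sc <- apply_center(object$centering, newdata) %*% object$rotation
  delta <- lda_delta_(object, sc)
  colnames(delta) <- object$levels
  rownames(delta) <- rownames(newdata)
  cls <- decode_classes(delta, object$levels)
  rmax <- apply(delta, 1, max)
  n_ties <- sum(rowSums(abs(delta - rmax) < 1e-12) > 1)
  structure(list(class = cls, scores = delta), n_ties = n_ties)
}

# LOOCV accuracy curve over n_pc = 1..cap; one PCA per fold, all candidate
# counts evaluated from its scores. Candidates whose pooled covariance is
# singular in some fold get NA accuracy.
pcada_cv_ <- function(x, labels, cap, pretreatment,
                      priors = "proportional") {
  n <- nrow(x)
  preds <- matrix(NA_character_, n, cap)
  for (i in seq_len(n)) {
    pre <- pretreat_(x[-i, , drop = FALSE], pretreatment)
    pca <- stats::prcomp(pre$x, center = FALSE)
    cap_i <- min(cap, ncol(pca$rotation))
    sc_tr <- pre$x %*% pca$rotation[, seq_len(cap_i), drop = FALSE]
    sc_te <- apply_center(pre$model, x[i, , drop = FALSE]) %*%
      pca$rotation[, seq_len(cap_i), drop = FALSE]
    for (a in seq_len(cap_i)) {
      fit <- tryCatch(lda_fit_(sc_tr[, seq_len(a), drop = FALSE], labels[-i],
                               priors),
                      error = function(e) NULL)
      if (is.null(fit)) next
      d <- lda_delta_(fit, sc_te[, seq_len(a), drop = FALSE])
      preds[i, a] <- fit$levels[which.max(d[1, ])]
    }
  }
  acc <- colMeans(preds == as.character(labels))  # NA if any fold failed
  if (all(is.na(acc))) abort("PCA-DA cross-validation failed at every n_pc")
  best <- which.max(acc)  # first maximum = smallest n_pc
  list(n_pc = unname(best), accuracy = unname(acc),
       best_accuracy = unname(acc[best]))
}

#' Backward variable elimination by Wilks' lambda
#'
#' Repeatedly removes the remaining variable with the largest univariate
#' Wilks' lambda (the least discriminating one), refits PCA-DA with automatic
#' component choice, and tracks the leave-one-out accuracy. A removal that
#' drops the accuracy below the best seen so far is undone and the loop
#' stops; the remaining variables are the selected set. The loop also stops
#' when a single variable remains.
#'
#' @inheritParams fit_pcada
#' @param max_pc cap on the PCA-DA component search at each refit.
#' @return A `lambda_table`: `lambda` (initial per-variable \eqn{\Lambda}),
#'   `selected` (indices of retained variables), `elimination_order`
#'   (indices in removal order), `trace` (data.frame with one row per
#'   evaluated model: variables remaining, candidate removed, accuracy,
#'   committed flag).
#' @export
stepwise_eliminate <- function(x, labels, max_pc = 10,
                               pretreatment = c("center", "autoscale", "none"),
                               levels = NULL) {
  pretreatment <- match.arg(pretreatment)
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("need >= 2 variables for stepwise elimination")
  labels <- as_class_factor(labels, levels)
  p <- ncol(x)
  var_names <- colnames(x) %||% paste0("V", seq_len(p))
  lambda0 <- wilks_lambda_mat_(x, labels)
  names(lambda0) <- var_names

  acc_of <- function(idx) {
    cap <- npc_cap_(nrow(x), length(idx), nlevels(labels), max_pc)
    pcada_cv_(x[, idx, drop = FALSE], labels, cap, pretreatment)$best_accuracy
  }

  remaining <- seq_len(p)
  best <- acc_of(remaining)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      n_remaining = p, accuracy = best, committed = TRUE,
                      stringsAsFactors = FALSE)
  order_removed <- integer(0)
  step <- 0L
  while (length(remaining) > 1) {
    lam <- wilks_lambda_mat_(x[, remaining, drop = FALSE], labels)
    cand <- remaining[which.max(lam)]
    tentative <- setdiff(remaining, cand)
    acc <- acc_of(tentative)
    step <- step + 1L
    committed <- acc >= best
    trace <- rbind(trace, data.frame(
      step = step, removed = var_names[cand],
      n_remaining = length(tentative), accuracy = acc,
      committed = committed, stringsAsFactors = FALSE))
    if (!committed) break
    remaining <- tentative
    best <- max(best, acc)
    order_removed <- c(order_removed, cand)
  }
  eliminated_at <- rep(NA_integer_, p)
  eliminated_at[order_removed] <- seq_along(order_removed)
  structure(list(lambda = lambda0, selected = remaining,
                 elimination_order = order_removed,
                 eliminated_at = stats::setNames(eliminated_at, var_names),
                 accuracy = best, trace = trace, var_names = var_names),
            class = "lambda_table")
}

#' @export
print.lambda_table <- function(x, ...) {
  cat(sprintf("<lambda_table: %d/%d variables retained, LOOCV accuracy %.3f>\n",
              length(x$selected), length(x$lambda), x$accuracy))
  invisible(x)
}
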