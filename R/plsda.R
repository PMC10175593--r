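#' Indicator (dummy) coding of class labels
#'
#' One indicator column per class (also for two classes), entries in
#' \{0, 1\}, each row summing to 1. The column order is the class coding
#' order used for argmax prediction and tie-breaking throughout.
#'
#' @param labels vector/factor of class tags (>= 2 classes).
#' @param levels optional explicit class order; defaults to factor levels or
#'   order of first appearance.
#' @return list with `Y` (n x m indicator matrix, columns named by class)
#'   and `levels`.
#' @export
encode_classes <- function(labels, levels = NULL) {
  f <- as_class_factor(labels, levels)
  if (nlevels(f) < 2) abort("need at least 2 classes, got ", nlevels(f))
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  rownames(Y) <- NULL
  attributes(Y)[c("assign", "contrasts")] <- NULL
  list(Y = Y, levels = levels(f))
}

#' Decode an indicator (or predicted-indicator) matrix back to labels
#' @param Y numeric matrix, one column per class.
#' @param levels class names in column order (default: column names).
#' @return factor of per-row argmax classes (ties to the first class in
#'   coding order).
#' @export
decode_classes <- function(Y, levels = colnames(Y)) {
  factor(levels[max.col(Y, ties.method = "first")], levels = levels)
}

# ---- NIPALS PLS2 core ------------------------------------------------------
# X, Y already centered. X-deflation only; deterministic start from the Y
# column of maximal variance. Returns weights/loadings/scores and the
# per-component sums of squares needed for explained variance and VIP.
nipals_pls_ <- function(X, Y, n_lv, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n_lv < 1) abort("n_lv must be >= 1")
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); Tm <- matrix(0, n, n_lv)
  ssx_comp <- numeric(n_lv); ssy_comp <- numeric(n_lv)
  ssx_total <- sum(X^2); ssy_total <- sum(Y^2)
  if (ssx_total <= 0) abort("X has zero variance after centering")
  if (ssy_total <= 0) abort("Y has zero variance after centering")
  Xa <- X
  for (a in seq_len(n_lv)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    t_old <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw <= 1e-300)
        abort("NIPALS component ", a, ": X carries no covariance with Y ",
              "(rank exhausted); reduce n_lv")
      w <- w / nw
      tvec <- (Xa %*% w)[, 1]
      tt <- sum(tvec^2)
      if (tt <= 1e-300)
        abort("NIPALS component ", a, ": degenerate score vector; reduce n_lv")
      q <- crossprod(Y, tvec)[, 1] / tt
      if (!is.null(t_old) &&
          sqrt(sum((tvec - t_old)^2)) <= tol * sqrt(tt)) {
        converged <- TRUE
        break
      }
      t_old <- tvec
      u <- (Y %*% q)[, 1] / sum(q^2)
      if (m == 1L) { converged <- TRUE; break }  # single response: closed form
    }
    # near-tied eigendirections of X'YY'X converge only geometrically; the
    # component is accepted at the iteration cap (any vector in the tied
    # subspace yields an equivalent fit)
    pvec <- crossprod(Xa, tvec)[, 1] / sum(tvec^2)
    Xa <- Xa - tcrossprod(tvec, pvec)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; Tm[, a] <- tvec
    ssx_comp[a] <- sum(tvec^2) * sum(pvec^2)
    ssy_comp[a] <- sum(tvec^2) * sum(q^2)
  }
  list(W = W, P = P, Q = Q, T = Tm,
       explained_x = ssx_comp / ssx_total,
       explained_y = ssy_comp / ssy_total,
       ssy_comp = ssy_comp)
}

# regression coefficients from the first a components: B = W (P'W)^-1 Q'
pls_coef_ <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS-DA model (NIPALS PLS2 on indicator-coded classes)
#'
#' Partial least squares regression of the mean-centered class indicator
#' matrix on the (pretreated) data matrix, extracting `n_lv` latent variables
#' by NIPALS with X-deflation. Used as a classifier through the argmax of the
#' predicted indicators.
#'
#' @param x numeric matrix (samples x variables).
#' @param labels class tags (>= 2 classes).
#' @param n_lv number of latent variables (<= min(n-1, p)).
#' @param pretreatment `"center"` (default), `"autoscale"` or `"none"`.
#' @param levels optional class coding order.
#' @return A `plsda` model: latent-structure matrices `W`, `P`, `Q`, `T`,
#'   coefficients `B`, per-component `explained_x`/`explained_y` fractions,
#'   the stored centering models for X and Y, and the class coding.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- rep(c("A", "B"), each = 10)
#' x[y == "B", 1] <- x[y == "B", 1] + 4
#' m <- fit_plsda(x, y, n_lv = 1)
#' table(predict(m, x)$class, y)
#' @export
fit_plsda <- function(x, labels, n_lv,
                      pretreatment = c("center", "autoscale", "none"),
                      levels = NULL) {
  pretreatment <- match.arg(pretreatment)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  labels <- as_class_factor(labels, levels)
  if (length(labels) != n) abort("labels length != number of rows")
  if (n_lv > min(n - 1, p))
    abort("n_lv = ", n_lv, " exceeds min(n-1, p) = ", min(n - 1, p))
  pre <- pretreat_(x, pretreatment)
  enc <- encode_classes(labels)
  y_means <- colMeans(enc$Y)
  Yc <- sweep(enc$Y, 2, y_means)
  fit <- nipals_pls_(pre$x, Yc, n_lv)
  structure(list(n_lv = n_lv, W = fit$W, P = fit$P, Q = fit$Q, T = fit$T,
                 B = pls_coef_(fit, n_lv),
                 explained_x = fit$explained_x,
                 explained_y = fit$explained_y,
                 ssy_comp = fit$ssy_comp,
                 centering = pre$model, y_means = y_means,
                 levels = enc$levels, pretreatment = pretreatment,
                 var_names = colnames(x)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda: %d latent variables, %d variables, classes: %s>\n",
              x$n_lv, nrow(x$B), paste(x$levels, collapse = "/")))
  cat(sprintf("  cumulative explained X-variance: %.1f%%, Y-variance: %.1f%%\n",
              100 * sum(x$explained_x), 100 * sum(x$explained_y)))
  invisible(x)
}

#' Predict classes from a PLS-DA model
#'
#' The predicted class is the argmax over predicted indicator columns; exact
#' ties go to the first class in coding order and are counted in the
#' `n_ties` attribute of the result. The continuous per-class scores
#' (predicted indicators) are returned for ROC analysis.
#'
#' @param object a `plsda` model.
#' @param newdata matrix with the same variables the model was fit on.
#' @param ... unused.
#' @return list with `class` (factor) and `scores` (n x m matrix of
#'   predicted indicators, columns named by class).
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$B))
    abort("column count mismatch: model has ", nrow(object$B),
          " variables, newdata has ", ncol(newdata))
  Xc <- apply_center(object$centering, newdata)
  scores <- sweep(Xc %*% object$B, 2, object$y_means, "+")
  colnames(scores) <- object$levels
  rownames(scores) <- rownames(newdata)
  cls <- decode_classes(scores, object$levels)
  rmax <- apply(scores, 1, max)
  n_ties <- sum(rowSums(abs(scores - rmax) < 1e-12) > 1)
  structure(list(class = cls, scores = scores), n_ties = n_ties)
}

#' Choose the number of latent variables by leave-one-out accuracy
#'
#' Computes the LOOCV classification accuracy for every component count
#' `1..max_lv` (one NIPALS fit per left-out sample, evaluated at all counts)
#' and returns the smallest count attaining the maximum accuracy (parsimony
#' tie-break).
#'
#' @inheritParams fit_plsda
#' @param max_lv largest component count to consider; capped at `n - 2`
#'   (with a warning) and at the number of variables.
#' @return list with `n_lv` (chosen count) and `accuracy` (LOOCV accuracy
#'   per candidate count).
#' @export
select_n_lv <- function(x, labels, max_lv,
                        pretreatment = c("center", "autoscale", "none"),
                        levels = NULL) {
  pretreatment <- match.arg(pretreatment)
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as_class_factor(labels, levels)
  if (max_lv < 1) abort("max_lv must be >= 1")
  cap <- min(max_lv, ncol(x))
  if (max_lv > n - 2) {
    warning("max_lv capped at n - 2 = ", n - 2, call. = FALSE)
    cap <- min(cap, n - 2)
  }
  cap <- min(cap, n - 2)
  if (cap < 1) abort("too few samples to cross-validate any component count")
  preds <- matrix(NA_character_, n, cap)
  for (i in seq_len(n)) {
    a_i <- min(cap, nrow(x) - 2)
    fit <- fit_plsda(x[-i, , drop = FALSE], labels[-i], n_lv = a_i,
                     pretreatment = pretreatment, levels = levels(labels))
    Xc <- apply_center(fit$centering, x[i, , drop = FALSE])
    for (a in seq_len(a_i)) {
      sc <- Xc %*% pls_coef_(fit, a)
      sc <- sweep(sc, 2, fit$y_means, "+")
      preds[i, a] <- fit$levels[which.max(sc[1, ])]
    }
  }
  acc <- colMeans(preds == as.character(labels), na.rm = TRUE)
  list(n_lv = unname(which.max(acc)), accuracy = unname(acc))
}

#' Variable importance in projection (VIP)
#'
#' VIP summarizes each variable's contribution to the PLS latent structure,
#' weighting the squared normalized weights of each component by the Y sum of
#' squares that component explains (multi-response form):
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a = (t_a^\top t_a)\,\|q_a\|^2}. The squared VIPs sum to `p`,
#' so VIP > 1 flags variables contributing more than average; those are the
#' selected set.
#'
#' @param model a fitted `plsda` model.
#' @param threshold selection threshold (default 1.0).
#' @return A `vip_result`: `scores` (named per-variable VIPs), `threshold`,
#'   `selected` (integer indices with VIP > threshold).
#' @export
compute_vip <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$ssy_comp
  if (sum(ssy) <= 0) abort("model explains no Y variance; VIP undefined")
  p <- nrow(model$W)
  wnorm2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  vip <- sqrt(p * as.vector(wnorm2 %*% ssy) / sum(ssy))
  names(vip) <- model$var_names %||% paste0("V", seq_len(p))
  structure(list(scores = vip, threshold = threshold,
                 selected = which(vip > threshold)),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result: %d/%d variables with VIP > %g>\n",
              length(x$selected), length(x$scores), x$threshold))
  invisible(x)
}
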