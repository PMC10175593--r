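#' Leave-one-out cross-validation of a classifier specification
#'
#' For each sample, refits the pretreatment and classifier on the remaining
#' `n - 1` samples with the fixed hyperparameters in `model_spec` and
#' predicts the held-out sample. Variable selection is *not* refit here —
#' nested selection is orchestrated by [run_pipeline()] when requested.
#'
#' @param x numeric matrix (samples x variables), e.g. a fused feature
#'   matrix.
#' @param labels per-sample class tags.
#' @param model_spec list with `method` (`"plsda"` or `"pcada"`) plus the
#'   hyperparameters of the corresponding fit function (`n_lv` or `n_pc`,
#'   `max_pc`, `priors`, `pretreatment`).
#' @return A `loocv_result`: `pred` (factor of held-out predictions),
#'   `scores` (n x g matrix of continuous per-class scores), `labels`.
#' @export
loocv <- function(x, labels, model_spec) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as_class_factor(labels)
  if (n < nlevels(labels) + 1) abort("need n >= number of classes + 1")
  method <- match.arg(model_spec$method, c("plsda", "pcada"))
  pre <- model_spec$pretreatment %||% "center"
  lev <- levels(labels)
  pred <- character(n)
  scores <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (method == "plsda") {
        fit <- fit_plsda(x[-i, , drop = FALSE], labels[-i],
                         n_lv = model_spec$n_lv, pretreatment = pre,
                         levels = lev)
      } else {
        fit <- fit_pcada(x[-i, , drop = FALSE], labels[-i],
                         n_pc = model_spec$n_pc %||% "auto",
                         pretreatment = pre,
                         max_pc = model_spec$max_pc %||% 10,
                         priors = model_spec$priors %||% "proportional",
                         levels = lev)
      }
      predict(fit, x[i, , drop = FALSE])
    }, error = function(e)
      abort("LOOCV fold for sample ", rownames(x)[i] %||% i,
            " failed: ", conditionMessage(e)))
    if (is.null(scores))
      scores <- matrix(NA_real_, n, ncol(res$scores),
                       dimnames = list(rownames(x), colnames(res$scores)))
    pred[i] <- as.character(res$class)
    scores[i, ] <- res$scores[1, ]
  }
  structure(list(pred = factor(pred, levels = lev), scores = scores,
                 labels = labels),
            class = "loocv_result")
}

#' Confusion matrix (rows = true class, columns = predicted)
#'
#' @param true,pred equal-length class vectors; every value must appear in
#'   `class_order`.
#' @param class_order class names fixing the row/column order (default:
#'   levels of `true`).
#' @return integer g x g matrix of class `confusion`.
#' @export
confusion <- function(true, pred, class_order = NULL) {
  if (length(true) != length(pred)) abort("true and pred lengths differ")
  if (is.null(class_order))
    class_order <- if (is.factor(true)) levels(true) else unique(as.character(true))
  bad <- setdiff(unique(c(as.character(true), as.character(pred))), class_order)
  if (length(bad) > 0) abort("label(s) not in class_order: ",
                             paste(bad, collapse = ", "))
  t_f <- factor(as.character(true), levels = class_order)
  p_f <- factor(as.character(pred), levels = class_order)
  cm <- unclass(table(true = t_f, predicted = p_f))
  structure(cm, class = c("confusion", class(cm)))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. For two classes with a declared
#' positive class, sensitivity is the positive-class recall, specificity the
#' negative-class recall and precision the positive predictive value. For
#' more classes the three are macro-averaged one-vs-rest values; classes
#' with an empty row have undefined recall and are dropped from the macro
#' mean with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @param positive_class positive class for the binary definitions
#'   (default: first class when there are exactly two).
#' @return A `metrics_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `n`, `per_class` data.frame.
#' @export
metrics <- function(cm, positive_class = NULL) {
  cm <- unclass(cm)
  g <- nrow(cm)
  n <- sum(cm)
  if (n <= 0) abort("empty confusion matrix")
  classes <- rownames(cm)
  acc <- sum(diag(cm)) / n
  rec <- diag(cm) / rowSums(cm)            # per-class recall (NaN if empty row)
  prec <- diag(cm) / colSums(cm)
  spec <- vapply(seq_len(g), function(k) {
    tn <- sum(cm[-k, -k]); fp <- sum(cm[-k, k])
    tn / (tn + fp)
  }, numeric(1))
  per_class <- data.frame(class = classes, recall = as.numeric(rec),
                          precision = as.numeric(prec), specificity = spec,
                          n = rowSums(cm), row.names = NULL)
  if (g == 2) {
    pos <- positive_class %||% classes[1]
    if (!pos %in% classes) abort("positive_class not in confusion matrix")
    k <- match(pos, classes)
    se <- rec[k]; sp <- rec[-k]; pre <- prec[k]
  } else {
    if (any(rowSums(cm) == 0))
      warning("class(es) with no true samples dropped from macro averages: ",
              paste(classes[rowSums(cm) == 0], collapse = ", "), call. = FALSE)
    ok <- rowSums(cm) > 0
    se <- mean(rec[ok])
    sp <- mean(spec[ok])
    pre <- mean(prec[ok], na.rm = TRUE)    # classes never predicted: undefined
  }
  structure(list(accuracy = unname(acc), sensitivity = unname(se),
                 specificity = unname(sp), precision = unname(pre),
                 n = n, per_class = per_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Ac = %.4f  Se = %.4f  Sp = %.4f  Pre = %.4f  (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$n))
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps a threshold over the unique score values (predict positive when
#' score >= threshold) and integrates the resulting curve by the trapezoid
#' rule, which equals the Mann-Whitney pair statistic (ties counted 1/2).
#'
#' @param scores numeric per-sample scores, larger = more positive.
#' @param truth per-sample labels containing exactly two classes.
#' @param positive the positive class (default: first level of `truth`).
#' @return list with `points` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  truth <- as_class_factor(truth)
  if (nlevels(truth) != 2)
    abort("truth must contain exactly two classes (both present)")
  positive <- positive %||% levels(truth)[1]
  if (!positive %in% levels(truth)) abort("positive class not in truth")
  is_pos <- truth == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) abort("one class absent")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Welch two-sample t-test between two groups of responses
#'
#' Used for model explanation: tests whether a sensor's response differs
#' between (for instance) authentic and counterfeit samples. Unequal
#' variances assumed (Welch), two-sided.
#'
#' @param values numeric per-sample responses.
#' @param groups two-group tags, each group with >= 2 samples.
#' @return list with `statistic`, `p_value`, `df`, group means.
#' @export
group_ttest <- function(values, groups) {
  groups <- as_class_factor(groups)
  if (nlevels(groups) != 2) abort("need exactly two groups")
  if (any(table(groups) < 2)) abort("each group needs >= 2 samples")
  v1 <- values[groups == levels(groups)[1]]
  v2 <- values[groups == levels(groups)[2]]
  if (stats::var(v1) + stats::var(v2) <= 0)
    abort("zero variance in both groups; t-test undefined")
  ht <- stats::t.test(v1, v2, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       means = stats::setNames(c(mean(v1), mean(v2)), levels(groups)))
}
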