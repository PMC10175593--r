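#' CARS configuration
#'
#' Settings for competitive adaptive reweighted sampling: `N` Monte-Carlo
#' sampling runs (default 100), `folds`-fold RMSECV (default 10), the
#' fraction `ratio` of samples drawn as the calibration set of each run
#' (default 0.8), a cap `max_lv` on the inner PLS component count, and the
#' seed driving all randomness.
#'
#' @param N number of Monte-Carlo runs (>= 2).
#' @param folds cross-validation folds for RMSECV (>= 2).
#' @param ratio calibration sampling fraction in (0, 1].
#' @param max_lv cap on the inner PLS latent-variable count.
#' @param seed integer seed.
#' @return a `cars_config` list.
#' @export
cars_config <- function(N = 100L, folds = 10L, ratio = 0.8, max_lv = 10L,
                        seed = 1L) {
  if (N < 2) abort("N must be >= 2")
  if (folds < 2) abort("folds must be >= 2")
  if (ratio <= 0 || ratio > 1) abort("ratio must be in (0, 1]")
  structure(list(N = as.integer(N), folds = as.integer(folds), ratio = ratio,
                 max_lv = as.integer(max_lv), seed = as.integer(seed)),
            class = "cars_config")
}

#' Exponentially decreasing retention ratio (EDF)
#'
#' Fraction of wavelengths force-retained at Monte-Carlo run `i` of `N`:
#' \eqn{r_i = a e^{-k i}} with \eqn{a = (p/2)^{1/(N-1)}} and
#' \eqn{k = \ln(p/2)/(N-1)}, so that \eqn{r_1 = 1} (all `p` variables) and
#' \eqn{r_N = 2/p} (two variables).
#'
#' @param i run index (vectorized), 1..N.
#' @param N total runs.
#' @param p number of variables (>= 2).
#' @return retention ratio(s) in (0, 1].
#' @export
edf_ratio <- function(i, N, p) {
  if (p < 2) abort("p must be >= 2")
  if (any(i < 1 | i > N)) abort("run index out of 1..N")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

# centered PLS fit + prediction on held-out rows (internal, used by rmsecv)
pls_fold_pred_ <- function(xtr, ytr, xte, n_lv) {
  cm_x <- colMeans(xtr); cm_y <- colMeans(ytr)
  fit <- nipals_pls_(sweep(xtr, 2, cm_x), sweep(ytr, 2, cm_y), n_lv)
  B <- pls_coef_(fit, n_lv)
  sweep(sweep(xte, 2, cm_x) %*% B, 2, cm_y, "+")
}

rmsecv_folds_ <- function(x, y, n_lv, fold_list) {
  sq <- 0; m <- 0
  for (te in fold_list) {
    if (nrow(x) - length(te) < 2)
      abort("a fold leaves fewer than 2 training samples; cannot center")
    a <- min(n_lv, nrow(x) - length(te) - 1, ncol(x))
    pred <- pls_fold_pred_(x[-te, , drop = FALSE], y[-te, , drop = FALSE],
                           x[te, , drop = FALSE], a)
    sq <- sq + sum((pred - y[te, , drop = FALSE])^2)
    m <- m + length(te) * ncol(y)
  }
  sqrt(sq / m)
}

#' Root mean squared error of cross-validation of a PLS model
#'
#' K-fold cross-validated RMSE of predicting `y` (the task's indicator
#' matrix; multiple columns are pooled into one error) from `x` with a
#' mean-centered PLS model of `n_lv` components. Centering is refit inside
#' every training fold; folds are assigned by a seeded shuffle, so the value
#' is invariant to the sample order given the same assignment. `folds = n`
#' reduces to leave-one-out.
#'
#' @param x numeric matrix.
#' @param y numeric response matrix/vector (e.g. from [encode_classes()]).
#' @param n_lv PLS component count (capped per fold at the training rank).
#' @param folds number of folds.
#' @param seed seed for the fold shuffle.
#' @return nonnegative scalar RMSECV.
#' @export
rmsecv <- function(x, y, n_lv, folds = 10, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("x and y row counts differ")
  rmsecv_folds_(x, y, n_lv, make_folds(nrow(x), folds, seed))
}

# inner component count: minimize K-fold RMSECV over 1..max_lv on full data.
# Component counts at which NIPALS fails to converge (noise-dominated
# deflated data with near-tied eigenvalues) are skipped.
pick_n_lv_rmsecv_ <- function(x, y, max_lv, fold_list) {
  cap <- min(max_lv, nrow(x) - max(lengths(fold_list)) - 1, ncol(x))
  errs <- vapply(seq_len(cap), function(a)
    tryCatch(rmsecv_folds_(x, y, a, fold_list),
             error = function(e) Inf), numeric(1))
  if (all(!is.finite(errs))) abort("RMSECV failed at every component count")
  list(n_lv = which.min(errs), errors = errs)
}

# NIPALS with graceful fallback: on convergence failure retry with one
# component fewer (down to 1)
nipals_retry_ <- function(X, Y, n_lv) {
  for (a in rev(seq_len(n_lv))) {
    fit <- tryCatch(nipals_pls_(X, Y, a), error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, n_lv = a))
  }
  abort("PLS fit failed at every component count")
}

#' Competitive adaptive reweighted sampling for wavelength selection
#'
#' Each of `N` Monte-Carlo runs draws a calibration subset, fits a
#' mean-centered PLS model on the currently retained wavelengths, and weights
#' each wavelength by the magnitude of its regression coefficient (row norm
#' across indicator columns). Two elimination forces act per run: forced
#' retention of the top-weight wavelengths down to the exponentially
#' decreasing count `round(r_i * p)` ([edf_ratio()]), then adaptive
#' reweighted sampling — `round(r_i * p)` draws with replacement with
#' probability proportional to weight, the retained set being the union of
#' the draws. The RMSECV of a PLS model on all samples restricted to each
#' run's retained set is recorded; the selected wavelengths are the retained
#' set of the run with minimal RMSECV (earliest run on ties).
#'
#' The inner PLS component count is chosen once on the full data by
#' `folds`-fold RMSECV and then held fixed; the fold assignment is likewise
#' fixed across runs so RMSECV values are comparable.
#'
#' @param x NIR matrix (samples x wavelengths, >= 2 wavelengths).
#' @param labels class tags driving the indicator response.
#' @param config a [cars_config()].
#' @return A `cars_trace`: `runs` data.frame (run, ratio, n_retained,
#'   rmsecv), `retained` (list of per-run index sets), `best_run`,
#'   `selected` (indices), `selected_names`, `full_rmsecv` (all-wavelength
#'   baseline at the same component count), `n_lv`, `config`.
#' @export
cars_select <- function(x, labels, config = cars_config()) {
  stopifnot(inherits(config, "cars_config"))
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) abort("need >= 2 wavelengths")
  enc <- encode_classes(labels)
  y <- enc$Y
  var_names <- colnames(x) %||% paste0("V", seq_len(p))

  run_seeded(config$seed, {
    fold_list <- make_folds(n, min(config$folds, n), seed = NULL)
    inner <- pick_n_lv_rmsecv_(x, y, config$max_lv, fold_list)
    n_lv <- inner$n_lv
    full_rmsecv <- inner$errors[n_lv]

    n_cal <- ceiling(config$ratio * n)
    retained <- seq_len(p)
    runs <- data.frame(run = integer(0), ratio = numeric(0),
                       n_retained = integer(0), rmsecv = numeric(0))
    retained_sets <- vector("list", config$N)
    for (i in seq_len(config$N)) {
      r_i <- edf_ratio(i, config$N, p)
      cal <- sample.int(n, n_cal)
      a <- min(n_lv, n_cal - 1, length(retained))
      cm_x <- colMeans(x[cal, retained, drop = FALSE])
      cm_y <- colMeans(y[cal, , drop = FALSE])
      fr <- nipals_retry_(sweep(x[cal, retained, drop = FALSE], 2, cm_x),
                          sweep(y[cal, , drop = FALSE], 2, cm_y), a)
      B <- pls_coef_(fr$fit, fr$n_lv)
      w <- sqrt(rowSums(B^2))
      k_i <- max(1L, round(r_i * p))
      # forced retention of the top-weight wavelengths
      if (k_i < length(retained)) {
        keep <- order(w, decreasing = TRUE)[seq_len(k_i)]
      } else keep <- seq_along(retained)
      forced <- retained[keep]
      wk <- w[keep]
      # adaptive reweighted sampling: union of weight-proportional draws
      prob <- if (sum(wk) > 0) wk / sum(wk) else NULL
      draws <- forced[sample.int(length(forced), size = k_i, replace = TRUE,
                                 prob = prob)]
      new_retained <- sort(unique(draws))
      if (length(new_retained) < 1) {
        warning("retained set collapsed at run ", i, "; trace truncated",
                call. = FALSE)
        retained_sets <- retained_sets[seq_len(i - 1)]
        break
      }
      retained <- new_retained
      a_cv <- min(n_lv, length(retained))
      rms <- Inf
      while (a_cv >= 1 && !is.finite(rms)) {  # shrink A if NIPALS stalls
        rms <- tryCatch(rmsecv_folds_(x[, retained, drop = FALSE], y, a_cv,
                                      fold_list),
                        error = function(e) Inf)
        a_cv <- a_cv - 1L
      }
      runs <- rbind(runs, data.frame(run = i, ratio = r_i,
                                     n_retained = length(retained),
                                     rmsecv = rms))
      retained_sets[[i]] <- retained
    }
    best <- runs$run[which.min(runs$rmsecv)]  # earliest run on ties
    selected <- retained_sets[[best]]
    structure(list(runs = runs, retained = retained_sets, best_run = best,
                   selected = selected, selected_names = var_names[selected],
                   full_rmsecv = full_rmsecv, n_lv = n_lv, config = config),
              class = "cars_trace")
  })
}

#' @export
print.cars_trace <- function(x, ...) {
  cat(sprintf(
    "<cars_trace: %d runs, best run %d, %d wavelengths selected (RMSECV %.4g, full %.4g)>\n",
    nrow(x$runs), x$best_run, length(x$selected),
    min(x$runs$rmsecv), x$full_rmsecv))
  invisible(x)
}
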