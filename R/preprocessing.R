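#' Average replicate measurements into one row per sample
#'
#' Instruments measure each sample several times (e.g. three gas-sensor
#' replicates, three spectral scans); the analysis matrix holds the
#' arithmetic mean of the replicates. `replicate_map` names the groups: one
#' entry per output sample, each giving the rows (indices or row ids of
#' `block`) that belong to it. Groups must partition the block's rows.
#'
#' @param block a [sensor_block()] whose rows are replicate measurements.
#' @param replicate_map named list mapping output sample id to the member
#'   rows (integer indices or sample ids of `block`).
#' @return A [sensor_block()] with one row per group, in `replicate_map`
#'   order.
#' @export
average_replicates <- function(block, replicate_map) {
  stopifnot(inherits(block, "sensor_block"))
  if (is.null(names(replicate_map)) || any(names(replicate_map) == ""))
    abort("replicate_map must be a fully named list")
  rows <- lapply(replicate_map, function(g) {
    if (length(g) == 0) abort("empty replicate group")
    if (is.character(g)) {
      idx <- match(g, block$sample_ids)
      if (anyNA(idx)) abort("unknown replicate row id: ",
                            paste(g[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(g)
  })
  flat <- unlist(rows, use.names = FALSE)
  if (anyDuplicated(flat))
    abort("row referenced by more than one replicate group: ",
          paste(unique(block$sample_ids[flat[duplicated(flat)]]), collapse = ", "))
  if (length(flat) != nrow(block$values))
    abort("replicate groups must partition the rows (",
          length(flat), " referenced, ", nrow(block$values), " present)")
  out <- do.call(rbind, lapply(rows, function(idx)
    colMeans(block$values[idx, , drop = FALSE])))
  sensor_block(out, block$source, sample_ids = names(replicate_map),
               var_names = block$var_names)
}

#' Fit a centering (optionally autoscaling) transform
#'
#' Stores per-variable means (and standard deviations when `scale = TRUE`)
#' from the rows it is fit on. Inside cross-validation the transform must be
#' fit on the training fold only; [apply_center()] then reuses the stored
#' statistics, never recomputing them from new data.
#'
#' @param x numeric matrix (samples x variables).
#' @param scale if `TRUE`, also divide by the training standard deviation
#'   (autoscaling); zero-variance columns are then an error.
#' @param source optional block tag recorded on the model.
#' @return A `centering_model` with fields `means`, `sds` (or `NULL`),
#'   `source`.
#' @export
fit_center <- function(x, scale = FALSE, source = NULL) {
  x <- as.matrix(x)
  means <- colMeans(x)
  sds <- NULL
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    zero <- which(sds <= 0 | !is.finite(sds))
    if (length(zero) > 0)
      abort("zero-variance column(s), cannot autoscale: ",
            paste(colnames(x)[zero] %||% zero, collapse = ", "))
  }
  structure(list(means = means, sds = sds, source = source),
            class = "centering_model")
}

#' Apply a fitted centering transform
#' @param model a `centering_model` from [fit_center()].
#' @param x numeric matrix with the same variables as the fit data.
#' @return the transformed matrix.
#' @export
apply_center <- function(model, x) {
  stopifnot(inherits(model, "centering_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$means))
    abort("column count mismatch: model has ", length(model$means),
          " variables, data has ", ncol(x))
  out <- sweep(x, 2, model$means, "-")
  if (!is.null(model$sds)) out <- sweep(out, 2, model$sds, "/")
  out
}

# fit+apply in one step per a pretreatment keyword; returns list(x, model)
pretreat_ <- function(x, pretreatment = c("center", "autoscale", "none"),
                      source = NULL) {
  pretreatment <- match.arg(pretreatment)
  if (pretreatment == "none") {
    model <- structure(list(means = rep(0, ncol(x)), sds = NULL, source = source),
                       class = "centering_model")
    return(list(x = as.matrix(x), model = model))
  }
  model <- fit_center(x, scale = pretreatment == "autoscale", source = source)
  list(x = apply_center(model, x), model = model)
}
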