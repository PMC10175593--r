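#' Pipeline configuration
#'
#' Settings for the two mid-level fusion workflows: authenticity (PLS-DA
#' with VIP > threshold selection per sensor block) and species (PCA-DA with
#' Wilks' lambda backward elimination per block). The NIR block is always
#' selected by CARS. Fused features are autoscaled by default because the
#' instrument blocks live on very different scales (histogram counts vs
#' absorbance); set `fused_pretreatment = "center"` to mimic raw
#' concatenation.
#'
#' @param task `"authenticity"` or `"species"`.
#' @param blocks sources to include (subset of EN/ET/EE/NIR).
#' @param vip_threshold VIP selection threshold (default 1.0).
#' @param max_lv latent-variable search cap for PLS-DA.
#' @param max_pc component search cap for PCA-DA.
#' @param block_pretreatment pretreatment used inside per-block selection.
#' @param fused_pretreatment pretreatment for the fused classifier.
#' @param cars a [cars_config()] for the NIR block.
#' @param cars_labels which labeling drives the CARS response:
#'   `"species"` (default) or `"task"` (the active task's classes).
#' @param lambda_report_threshold report-level flag: fused variables with
#'   Wilks' lambda below this are marked high-contribution (default 0.3).
#' @param seed integer seed (drives CARS and fold shuffles).
#' @param nested if `TRUE`, refit the per-block variable selection inside
#'   every LOOCV fold (slow, but removes the selection bias of the default).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(task = c("authenticity", "species"),
                            blocks = BLOCK_SOURCES,
                            vip_threshold = 1.0,
                            max_lv = 10L, max_pc = 10L,
                            block_pretreatment = "center",
                            fused_pretreatment = "autoscale",
                            cars = NULL, cars_labels = c("species", "task"),
                            lambda_report_threshold = 0.3,
                            seed = 1L, nested = FALSE) {
  task <- match.arg(task)
  blocks <- match.arg(blocks, BLOCK_SOURCES, several.ok = TRUE)
  if (vip_threshold < 0) abort("vip_threshold must be >= 0")
  structure(list(task = task, blocks = blocks, vip_threshold = vip_threshold,
                 max_lv = as.integer(max_lv), max_pc = as.integer(max_pc),
                 block_pretreatment = block_pretreatment,
                 fused_pretreatment = fused_pretreatment,
                 cars = cars %||% cars_config(seed = seed),
                 cars_labels = match.arg(cars_labels),
                 lambda_report_threshold = lambda_report_threshold,
                 seed = as.integer(seed), nested = isTRUE(nested)),
            class = "pipeline_config")
}

# labels driving CARS for this dataset/config
cars_response_labels_ <- function(dataset, config) {
  if (config$cars_labels == "species") droplevels(dataset$labels$species)
  else dataset_classes(dataset)
}

#' Per-block feature selection
#'
#' Applies the task's selector to every included block: VIP > threshold from
#' a PLS-DA fit (authenticity), Wilks' lambda backward elimination
#' (species), and always CARS for the NIR block. An empty VIP selection
#' falls back to the single top-VIP variable with a warning.
#'
#' @param dataset a `fusion_dataset` from [assemble_dataset()].
#' @param config a [pipeline_config()].
#' @return A `selection_result`: per-block list with `indices`, `names`,
#'   `method`, `criterion` (VIP scores, lambda table or CARS trace).
#' @export
select_features <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  classes <- dataset_classes(dataset)
  use <- intersect(config$blocks, names(dataset$blocks))
  if (length(use) == 0) abort("no configured block present in dataset")
  out <- lapply(use, function(src) {
    b <- dataset$blocks[[src]]
    tryCatch(
      select_block_(b, classes, dataset, config),
      error = function(e) abort("feature selection failed for block ", src,
                                ": ", conditionMessage(e)))
  })
  names(out) <- use
  structure(out, class = "selection_result")
}

select_block_ <- function(block, classes, dataset, config) {
  x <- block$values
  if (block$source == "NIR") {
    tr <- cars_select(x, cars_response_labels_(dataset, config), config$cars)
    return(list(indices = tr$selected, names = block$var_names[tr$selected],
                method = "CARS", criterion = tr))
  }
  if (config$task == "authenticity") {
    sel_lv <- select_n_lv(x, classes, config$max_lv,
                          pretreatment = config$block_pretreatment)
    fit <- fit_plsda(x, classes, sel_lv$n_lv,
                     pretreatment = config$block_pretreatment)
    vip <- compute_vip(fit, config$vip_threshold)
    idx <- vip$selected
    if (length(idx) == 0) {
      warning("no variable with VIP > ", config$vip_threshold, " in block ",
              block$source, "; falling back to the top-VIP variable",
              call. = FALSE)
      idx <- which.max(vip$scores)
    }
    list(indices = idx, names = block$var_names[idx], method = "VIP",
         criterion = vip, n_lv = sel_lv$n_lv)
  } else {
    st <- stepwise_eliminate(x, classes, max_pc = config$max_pc,
                             pretreatment = config$block_pretreatment)
    list(indices = st$selected, names = block$var_names[st$selected],
         method = "lambda", criterion = st)
  }
}

#' Concatenate selected features across blocks (mid-level fusion)
#'
#' Column-binds the selected columns of each block in the fixed order EN,
#' ET, EE, NIR, and records per-column provenance (source block and original
#' variable name). Scaling of the fused matrix is left to the classifier's
#' pretreatment so that cross-validation remains honest.
#'
#' @param dataset a `fusion_dataset`.
#' @param selection a `selection_result` covering the blocks to fuse.
#' @return list with `values` (n x total selected matrix) and `provenance`
#'   (data.frame: block, variable, fused column name).
#' @export
fuse_blocks <- function(dataset, selection) {
  stopifnot(inherits(dataset, "fusion_dataset"),
            inherits(selection, "selection_result"))
  use <- intersect(BLOCK_SOURCES, names(selection))
  use <- intersect(use, names(dataset$blocks))
  if (length(use) == 0) abort("selection covers no block of the dataset")
  pieces <- lapply(use, function(src) {
    b <- dataset$blocks[[src]]
    idx <- selection[[src]]$indices
    if (length(idx) == 0) abort("empty selection for block ", src)
    if (any(idx < 1 | idx > ncol(b$values)))
      abort("selection indices out of range for block ", src)
    v <- b$values[, idx, drop = FALSE]
    colnames(v) <- paste(src, b$var_names[idx], sep = ".")
    v
  })
  values <- do.call(cbind, pieces)
  rownames(values) <- dataset$labels$sample_id
  provenance <- do.call(rbind, lapply(use, function(src) {
    idx <- selection[[src]]$indices
    data.frame(block = src,
               variable = dataset$blocks[[src]]$var_names[idx],
               fused_name = paste(src, dataset$blocks[[src]]$var_names[idx],
                                  sep = "."),
               stringsAsFactors = FALSE)
  }))
  list(values = values, provenance = provenance)
}

#' Run the full mid-level fusion workflow
#'
#' Select features per block, fuse, choose the classifier's dimensionality
#' by leave-one-out accuracy, fit the final model on all samples, evaluate
#' by LOOCV, and build the explanation tables (VIP of the fused model for
#' the authenticity task; per-variable Wilks' lambda with the
#' high-contribution flag for the species task; Welch t-tests per fused
#' variable for binary tasks).
#'
#' By default the per-block variable selection is done once on all samples
#' and held fixed during LOOCV (the sequential procedure this class of study
#' uses); `nested = TRUE` in the config refits selection in every fold,
#' removing the optimistic bias at substantial cost.
#'
#' @param dataset a `fusion_dataset`.
#' @param config a [pipeline_config()] with the same task as the dataset.
#' @return A `fusion_report`: selection, provenance, fitted `model`,
#'   `cv` (loocv_result), `confusion`, `metrics`, `roc` (binary tasks),
#'   `explanation` data.frame, hyperparameters and config.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  if (dataset$task != config$task)
    abort("dataset task (", dataset$task, ") != config task (", config$task, ")")
  classes <- dataset_classes(dataset)

  selection <- select_features(dataset, config)
  fused <- fuse_blocks(dataset, selection)
  x <- fused$values

  if (config$task == "authenticity") {
    sel <- select_n_lv(x, classes, config$max_lv,
                       pretreatment = config$fused_pretreatment)
    spec <- list(method = "plsda", n_lv = sel$n_lv,
                 pretreatment = config$fused_pretreatment)
    model <- fit_plsda(x, classes, sel$n_lv,
                       pretreatment = config$fused_pretreatment)
    hyper <- list(n_lv = sel$n_lv, accuracy_curve = sel$accuracy)
  } else {
    cap <- npc_cap_(nrow(x), ncol(x), nlevels(classes), config$max_pc)
    cv0 <- pcada_cv_(x, classes, cap, config$fused_pretreatment)
    spec <- list(method = "pcada", n_pc = cv0$n_pc, max_pc = config$max_pc,
                 pretreatment = config$fused_pretreatment)
    model <- fit_pcada(x, classes, n_pc = cv0$n_pc,
                       pretreatment = config$fused_pretreatment,
                       max_pc = config$max_pc)
    hyper <- list(n_pc = cv0$n_pc, accuracy_curve = cv0$accuracy)
  }

  cv <- if (config$nested) nested_loocv_(dataset, config, spec)
        else loocv(x, classes, spec)
  pos <- if (config$task == "authenticity") "FC" else NULL
  cm <- confusion(classes, cv$pred, levels(classes))
  met <- metrics(cm, positive_class = pos)
  roc <- if (nlevels(classes) == 2)
    roc_auc(cv$scores[, pos], classes, positive = pos) else NULL

  explanation <- explain_(x, classes, model, fused$provenance, config)

  structure(list(task = config$task, selection = selection,
                 provenance = fused$provenance, fused = x, model = model,
                 hyper = hyper, cv = cv, confusion = cm, metrics = met,
                 roc = roc, explanation = explanation, config = config),
            class = "fusion_report")
}

# explanation table: per fused variable, VIP (authenticity) or lambda
# (species) with the report-level flags, plus Welch t-test p for binary tasks
explain_ <- function(x, classes, model, provenance, config) {
  out <- provenance
  if (config$task == "authenticity") {
    vip <- compute_vip(model, config$vip_threshold)
    out$vip <- as.numeric(vip$scores)
    out$high_contribution <- out$vip > config$vip_threshold
  } else {
    lam <- wilks_lambda_mat_(x, classes)
    out$lambda <- as.numeric(lam)
    out$high_contribution <- out$lambda < config$lambda_report_threshold
  }
  if (nlevels(classes) == 2) {
    out$t_p_value <- vapply(seq_len(ncol(x)), function(j) {
      tryCatch(group_ttest(x[, j], classes)$p_value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out[order(out[[if (config$task == "authenticity") "vip" else "lambda"]],
            decreasing = config$task == "authenticity"), , drop = FALSE]
}

# nested LOOCV: refit per-block selection + classifier inside every fold
nested_loocv_ <- function(dataset, config, spec) {
  n <- nrow(dataset$labels)
  classes <- dataset_classes(dataset)
  lev <- levels(classes)
  pred <- character(n)
  scores <- NULL
  for (i in seq_len(n)) {
    lab_i <- dataset$labels[-i, , drop = FALSE]
    ds_i <- assemble_dataset(
      lapply(dataset$blocks, function(b)
        sensor_block(b$values[-i, , drop = FALSE], b$source,
                     sample_ids = b$sample_ids[-i], var_names = b$var_names)),
      label_table(lab_i$sample_id, lab_i$authenticity, lab_i$species),
      task = dataset$task)
    sel_i <- select_features(ds_i, config)
    fused_i <- fuse_blocks(ds_i, sel_i)
    xi <- fused_i$values
    if (spec$method == "plsda") {
      sl <- select_n_lv(xi, classes[-i], config$max_lv,
                        pretreatment = config$fused_pretreatment,
                        levels = lev)
      fit <- fit_plsda(xi, classes[-i], sl$n_lv,
                       pretreatment = config$fused_pretreatment, levels = lev)
    } else {
      fit <- fit_pcada(xi, classes[-i], n_pc = "auto",
                       pretreatment = config$fused_pretreatment,
                       max_pc = config$max_pc, levels = lev)
    }
    # project held-out sample onto this fold's selected columns
    test_piece <- do.call(cbind, lapply(
      intersect(BLOCK_SOURCES, names(sel_i)), function(src)
        dataset$blocks[[src]]$values[i, sel_i[[src]]$indices, drop = FALSE]))
    res <- predict(fit, test_piece)
    if (is.null(scores))
      scores <- matrix(NA_real_, n, length(lev),
                       dimnames = list(dataset$labels$sample_id, lev))
    pred[i] <- as.character(res$class)
    scores[i, colnames(res$scores)] <- res$scores[1, ]
  }
  structure(list(pred = factor(pred, levels = lev), scores = scores,
                 labels = classes),
            class = "loocv_result")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("<fusion_report: task=%s, blocks: %s>\n", x$task,
              paste(names(x$selection), collapse = "+")))
  hp <- if (x$task == "authenticity") sprintf("%d latent variables", x$hyper$n_lv)
        else sprintf("%d principal components", x$hyper$n_pc)
  cat(sprintf("  fused width %d (%s); LOOCV: ", ncol(x$fused), hp))
  print(x$metrics)
  if (!is.null(x$roc)) cat(sprintf("  AUC = %.4f\n", x$roc$auc))
  invisible(x)
}
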