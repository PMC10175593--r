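#' Sensor block: one instrument's sample-by-variable matrix
#'
#' A `sensor_block` bundles the numeric response matrix of one instrument
#' (rows = samples, columns = variables) with its sample identifiers, variable
#' names and a source tag. The four sources supported are `"EN"` (electronic
#' nose, gas-sensor channels), `"ET"` (electronic tongue, taste sensors),
#' `"EE"` (electronic eye, color-number histogram bins) and `"NIR"`
#' (near-infrared spectra; variable names are wavenumbers in cm^-1).
#'
#' @param values numeric matrix, samples in rows.
#' @param source one of `"EN"`, `"ET"`, `"EE"`, `"NIR"`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix row names.
#' @param var_names character vector of unique variable names; defaults to the
#'   matrix column names.
#' @return An object of class `sensor_block` with fields `source`,
#'   `sample_ids`, `var_names` and `values`.
#' @examples
#' b <- sensor_block(matrix(1:6, 2, 3), "EN",
#'                   sample_ids = c("S1", "S2"),
#'                   var_names = c("W1C", "W1S", "W2S"))
#' dim(b$values)
#' @export
sensor_block <- function(values, source, sample_ids = rownames(values),
                         var_names = colnames(values)) {
  source <- match.arg(source, BLOCK_SOURCES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) abort("sample_ids required (no row names on values)")
  if (is.null(var_names)) abort("var_names required (no column names on values)")
  sample_ids <- as.character(sample_ids)
  var_names <- as.character(var_names)
  if (nrow(values) != length(sample_ids))
    abort("row count (", nrow(values), ") != number of sample ids (",
          length(sample_ids), ")")
  if (ncol(values) != length(var_names))
    abort("column count (", ncol(values), ") != number of variable names (",
          length(var_names), ")")
  if (anyDuplicated(sample_ids))
    abort("duplicate sample ID: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(var_names))
    abort("duplicate variable name in block ", source, ": ",
          paste(unique(var_names[duplicated(var_names)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    abort("block ", source, " contains missing or non-finite values")
  dimnames(values) <- list(sample_ids, var_names)
  structure(list(source = source, sample_ids = sample_ids,
                 var_names = var_names, values = values),
            class = "sensor_block")
}

#' @export
print.sensor_block <- function(x, ...) {
  cat(sprintf("<sensor_block %s: %d samples x %d variables>\n",
              x$source, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.sensor_block <- function(x) dim(x$values)

#' Read a sensor block from delimited text
#'
#' Expects a comma-separated file with a header row of variable names and a
#' first column of sample identifiers; the body must be fully numeric
#' (dot-decimal, locale independent). Any non-numeric cell (including `NA`)
#' is an error naming the offending row and column.
#'
#' @param path path to a CSV file.
#' @param source block source tag, see [sensor_block()].
#' @return A [sensor_block()].
#' @seealso [write_block()] for the inverse operation.
#' @export
load_block <- function(path, source) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) abort("block file needs an id column and >=1 variable")
  ids <- raw[[1]]
  var_names <- colnames(raw)[-1]
  body <- as.matrix(raw[-1])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell '%s' at row %d (sample %s), column '%s' in %s",
                  body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                  var_names[bad[1, 2]], path))
  }
  rownames(vals) <- ids
  colnames(vals) <- var_names
  sensor_block(vals, source)
}

#' Write a sensor block to delimited text
#'
#' @param block a [sensor_block()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "sensor_block"))
  df <- data.frame(id = block$sample_ids, block$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample label table
#'
#' Holds per-sample authenticity (`FC` = authentic Fritillariae cirrhosae,
#' `COUNTERFEIT`) and species (`FU`, `FP`, `FD` are the authentic species,
#' `FUS` the counterfeit). The two columns must be mutually consistent:
#' `FUS` implies `COUNTERFEIT` and the three authentic species imply `FC`.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param authenticity character/factor in `{FC, COUNTERFEIT}`.
#' @param species character/factor in `{FU, FP, FD, FUS}`.
#' @return A `label_table` (a data.frame with columns `sample_id`,
#'   `authenticity`, `species`).
#' @export
label_table <- function(sample_ids, authenticity, species) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    abort("duplicate sample ID in labels: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  authenticity <- as_class_factor(authenticity, AUTH_LEVELS)
  species <- as_class_factor(species, SPECIES_LEVELS)
  if (anyNA(authenticity) || anyNA(species)) abort("missing label values")
  n <- length(sample_ids)
  if (length(authenticity) != n || length(species) != n)
    abort("label columns must all have length ", n)
  bad <- (species == "FUS") != (authenticity == "COUNTERFEIT")
  if (any(bad))
    abort("inconsistent labels for sample(s) ",
          paste(sample_ids[bad], collapse = ", "),
          ": species FUS must be COUNTERFEIT and FU/FP/FD must be FC")
  structure(data.frame(sample_id = sample_ids, authenticity = authenticity,
                       species = species, row.names = NULL),
            class = c("label_table", "data.frame"))
}

#' Read a sample label table from delimited text
#'
#' Expects columns `id`, `authenticity`, `species`. The species/authenticity
#' consistency invariant is enforced on load.
#'
#' @param path CSV path.
#' @return A [label_table()].
#' @export
load_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("id", "authenticity", "species")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0)
    abort("label file lacks column(s): ", paste(missing_cols, collapse = ", "))
  label_table(df$id, df$authenticity, df$species)
}

#' Write a label table to delimited text
#' @param labels a [label_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_table"))
  df <- data.frame(id = labels$sample_id,
                   authenticity = as.character(labels$authenticity),
                   species = as.character(labels$species))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble aligned multi-block dataset for one classification task
#'
#' Reorders every block to the label table's sample order and drops samples
#' that are missing from any block (with a warning). The result is the unit
#' all downstream modeling operates on.
#'
#' @param blocks list of [sensor_block()]s (at most one per source).
#' @param labels a [label_table()].
#' @param task `"authenticity"` (FC vs counterfeit) or `"species"`
#'   (FU/FP/FD/FUS).
#' @return A `fusion_dataset`: list with `blocks` (named by source, in
#'   EN/ET/EE/NIR order), `labels`, `task`.
#' @export
assemble_dataset <- function(blocks, labels, task = c("authenticity", "species")) {
  task <- match.arg(task)
  stopifnot(inherits(labels, "label_table"))
  if (inherits(blocks, "sensor_block")) blocks <- list(blocks)
  if (length(blocks) < 1) abort("need at least one block")
  srcs <- vapply(blocks, function(b) b$source, character(1))
  if (anyDuplicated(srcs)) abort("more than one block with the same source")
  names(blocks) <- srcs
  blocks <- blocks[order(match(srcs, BLOCK_SOURCES))]

  keep_ids <- labels$sample_id
  for (b in blocks) {
    missing <- setdiff(keep_ids, b$sample_ids)
    if (length(missing) > 0) {
      warning("dropping sample(s) absent from block ", b$source, ": ",
              paste(missing, collapse = ", "), call. = FALSE)
      keep_ids <- setdiff(keep_ids, missing)
    }
  }
  if (length(keep_ids) == 0) abort("no samples left after alignment")
  lab <- labels[match(keep_ids, labels$sample_id), , drop = FALSE]
  lab <- label_table(lab$sample_id, lab$authenticity, lab$species)
  blocks <- lapply(blocks, function(b) {
    sensor_block(b$values[match(keep_ids, b$sample_ids), , drop = FALSE],
                 b$source, sample_ids = keep_ids, var_names = b$var_names)
  })
  cls <- dataset_classes_(lab, task)
  if (nlevels(droplevels(cls)) < 2)
    abort("fewer than 2 classes present for task '", task, "' after alignment")
  structure(list(blocks = blocks, labels = lab, task = task),
            class = "fusion_dataset")
}

# class factor for the dataset's active task (canonical level order, dropped
# to the levels present)
dataset_classes_ <- function(labels, task) {
  droplevels(if (task == "authenticity") labels$authenticity else labels$species)
}

#' Class labels of a dataset's active task
#' @param dataset a `fusion_dataset`.
#' @return factor of per-sample class labels.
#' @export
dataset_classes <- function(dataset) {
  stopifnot(inherits(dataset, "fusion_dataset"))
  dataset_classes_(dataset$labels, dataset$task)
}

#' @export
print.fusion_dataset <- function(x, ...) {
  cat(sprintf("<fusion_dataset: task=%s, n=%d, blocks: %s>\n", x$task,
              nrow(x$labels),
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, function(b) ncol(b$values), 1L)),
                    collapse = ", ")))
  invisible(x)
}
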