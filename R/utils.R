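`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# K-fold assignment by seeded shuffle; returns list of index vectors
make_folds <- function(n, k, seed = NULL) {
  if (k < 2L) abort("need at least 2 folds")
  if (k > n) abort("more folds than samples")
  idx <- run_seeded(seed, sample.int(n))
  split(idx, cut(seq_len(n), breaks = k, labels = FALSE))
}

# canonical class level orders used throughout
AUTH_LEVELS <- c("FC", "COUNTERFEIT")
SPECIES_LEVELS <- c("FU", "FP", "FD", "FUS")
BLOCK_SOURCES <- c("EN", "ET", "EE", "NIR")

as_class_factor <- function(labels, levels = NULL) {
  if (is.factor(labels) && is.null(levels)) return(droplevels(labels))
  if (is.null(levels)) levels <- unique(as.character(labels))
  x <- as.character(labels)
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0)
    abort("unknown class label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = levels)
}
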