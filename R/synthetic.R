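#' Configuration of the synthetic multi-sensor panel generator
#'
#' The generator emulates the statistical structure the fusion analysis
#' assumes: four instrument blocks over the same samples, a handful of
#' class-discriminative ("planted") variables per block whose class means are
#' spread by `delta` noise standard deviations, nonnegative sensor
#' responses, sparse color-histogram counts for the electronic eye, smooth
#' peaked NIR spectra on a 12,000 to 4,000 cm^-1 grid, and replicate
#' measurements that are averaged into the analysis matrix.
#'
#' Defaults mirror the study design this toolkit targets: 20 samples per
#' species (FU/FP/FD/FUS, n = 80), blocks of 10 (EN), 6 (ET), 65 (EE) and
#' 2075 (NIR) variables, 3 replicates per sample.
#'
#' @param n_per_class samples per class (default 20).
#' @param classes class tags; `FUS` is the counterfeit (default the four
#'   species).
#' @param p_en,p_et,p_ee,p_nir block widths.
#' @param planted named list: number of informative variables per sensor
#'   block and of class-dependent NIR peaks. Each planted variable is a
#'   marker for exactly one authentic species (cycling FU, FP, FD): that
#'   species' mean is elevated by `delta` noise sd, all other classes sit at
#'   the baseline. The counterfeit FUS is therefore low on every marker, and
#'   no marker is redundant: dropping one collapses its species onto FUS.
#' @param delta effect size: the elevated class sits `delta` noise standard
#'   deviations above the other classes on a planted variable (default 3).
#' @param noise_sd named list of per-block noise standard deviations.
#' @param replicates replicate measurements per sample (default 3).
#' @param nir_peaks total number of spectral peaks (class-dependent ones are
#'   the first `planted$NIR` of them).
#' @param nir_peak_sd Gaussian peak width (sd, cm^-1).
#' @param seed integer seed; config + seed fully determine the panel.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_class = 20L, classes = SPECIES_LEVELS,
                       p_en = 10L, p_et = 6L, p_ee = 65L, p_nir = 2075L,
                       planted = list(EN = 3L, ET = 3L, EE = 3L, NIR = 3L),
                       delta = 3,
                       noise_sd = list(EN = 0.5, ET = 0.5, EE = 0.3,
                                       NIR = 0.01),
                       replicates = 3L,
                       nir_peaks = 8L, nir_peak_sd = 60,
                       seed = 1L) {
  if (delta < 0) abort("delta must be >= 0")
  if (replicates < 1) abort("replicates must be >= 1")
  if (nir_peak_sd <= 0) abort("peak width must be > 0")
  p <- list(EN = p_en, ET = p_et, EE = p_ee, NIR = p_nir)
  for (src in names(planted))
    if (planted[[src]] > p[[src]])
      abort("more planted variables than block width for ", src)
  if (planted$NIR > nir_peaks) abort("more class-dependent peaks than peaks")
  structure(list(n_per_class = as.integer(n_per_class), classes = classes,
                 p = p, planted = planted, delta = delta, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 nir_peaks = as.integer(nir_peaks), nir_peak_sd = nir_peak_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# cycle of elevated classes for the planted markers: only authentic species
# carry markers, so FUS stays low on all of them
marker_classes_ <- function(n_planted, levels) {
  auth <- setdiff(levels, "FUS")
  if (length(auth) == 0) auth <- levels
  auth[(seq_len(n_planted) - 1) %% length(auth) + 1]
}

# one intelligent-sensor block (EN/ET/EE) with replicates; returns the
# replicate-level block plus planted indices and the class mean table
gen_sensor_block_ <- function(src, p, planted, classes_vec, config) {
  g <- length(levels(classes_vec))
  sd <- config$noise_sd[[src]]
  baseline <- if (src == "EE") {
    # sparse histogram mimic: most bins near zero, planted bins populated
    rep(0, p)
  } else stats::runif(p, 2, 8)
  idx <- sort(sample.int(p, planted))
  mu <- matrix(rep(baseline, each = g), g, p,
               dimnames = list(levels(classes_vec), NULL))
  marker_of <- marker_classes_(planted, levels(classes_vec))
  for (k in seq_along(idx)) {
    j <- idx[k]
    base_j <- if (src == "EE") 1 else baseline[j]
    mu[, j] <- base_j
    mu[marker_of[k], j] <- base_j + config$delta * sd
  }
  n <- length(classes_vec)
  rep_rows <- n * config$replicates
  vals <- mu[as.integer(classes_vec), , drop = FALSE][
    rep(seq_len(n), each = config$replicates), , drop = FALSE] +
    matrix(stats::rnorm(rep_rows * p, sd = sd), rep_rows, p)
  vals[vals < 0] <- 0  # sensor responses are nonnegative
  list(values = vals, informative = idx, class_means = mu)
}

#' Generate a synthetic NIR spectral block
#'
#' Each spectrum is a gentle linear baseline (common to all samples) plus a
#' sum of Gaussian peaks plus i.i.d. noise; a subset of peaks has
#' class-dependent amplitudes.
#' Informative wavelengths are the grid points within one FWHM of a
#' class-dependent peak center.
#'
#' @param config a [sim_config()].
#' @param classes_vec factor of per-replicate-group class labels (one entry
#'   per sample).
#' @return list with `values` (replicate-level matrix), `grid` (wavenumbers,
#'   descending 12,000 to 4,000 cm^-1), `informative` (indices),
#'   `peak_centers` (class-dependent centers, cm^-1).
#' @export
generate_nir <- function(config, classes_vec) {
  p <- config$p$NIR
  g <- length(levels(classes_vec))
  grid <- seq(12000, 4000, length.out = p)
  # peak centers spread over the information-rich range, away from the edges
  centers <- stats::runif(config$nir_peaks, 4300, 11600)
  if (any(centers < min(grid) | centers > max(grid)))
    abort("peak center outside the wavenumber grid")
  base_amp <- stats::runif(config$nir_peaks, 0.3, 0.8)
  sdp <- config$nir_peak_sd
  noise <- config$noise_sd$NIR
  class_dep <- seq_len(config$planted$NIR)
  amp <- matrix(rep(base_amp, each = g), g, config$nir_peaks,
                dimnames = list(levels(classes_vec), NULL))
  marker_of <- marker_classes_(config$planted$NIR, levels(classes_vec))
  for (k in class_dep)
    amp[marker_of[k], k] <- base_amp[k] + config$delta * noise

  shapes <- vapply(centers, function(c0) exp(-(grid - c0)^2 / (2 * sdp^2)),
                   numeric(p))                      # p x n_peaks
  n <- length(classes_vec)
  rep_rows <- n * config$replicates
  slope <- stats::runif(1, -0.02, 0.02)
  intercept <- stats::runif(1, 0.1, 0.2)
  xt <- (grid - mean(grid)) / (max(grid) - min(grid))
  vals <- matrix(0, rep_rows, p)
  for (i in seq_len(n)) {
    spec <- intercept + slope * xt +
      as.vector(shapes %*% amp[as.integer(classes_vec)[i], ])
    rows <- (i - 1) * config$replicates + seq_len(config$replicates)
    vals[rows, ] <- matrix(rep(spec, each = config$replicates),
                           config$replicates, p) +
      matrix(stats::rnorm(config$replicates * p, sd = noise),
             config$replicates, p)
  }
  fwhm <- 2 * sqrt(2 * log(2)) * sdp
  informative <- sort(unique(unlist(lapply(centers[class_dep], function(c0)
    which(abs(grid - c0) <= fwhm)))))
  list(values = vals, grid = grid, informative = informative,
       peak_centers = centers[class_dep])
}

#' Generate a four-block synthetic panel with ground truth
#'
#' Draws replicate-level measurements for all four blocks, averages the
#' replicates through [average_replicates()] into the analysis matrices, and
#' assembles a [assemble_dataset()] for the requested task together with the
#' generating ground truth (planted variable indices per block).
#'
#' @param config a [sim_config()].
#' @param task task of the returned dataset (default `"species"`).
#' @return list with `dataset` (a `fusion_dataset`), `truth` (per-block
#'   informative indices, NIR peak centers and grid, seed), and
#'   `replicate_blocks` (the raw replicate-level [sensor_block()]s).
#' @export
generate_panel <- function(config = sim_config(),
                           task = c("species", "authenticity")) {
  task <- match.arg(task)
  stopifnot(inherits(config, "sim_config"))
  run_seeded(config$seed, {
    g <- length(config$classes)
    n <- g * config$n_per_class
    cls <- factor(rep(config$classes, each = config$n_per_class),
                  levels = config$classes)
    ids <- paste0("S", seq_len(n))
    rep_ids <- paste0(rep(ids, each = config$replicates), "_",
                      rep(seq_len(config$replicates), n))
    rep_map <- stats::setNames(
      split(rep_ids, rep(seq_len(n), each = config$replicates)), ids)

    var_names <- list(
      EN = c("W1C", "W5S", "W3C", "W6S", "W5C", "W1S", "W1W", "W2S", "W2W",
             "W3S")[seq_len(min(10, config$p$EN))],
      ET = c("AftertasteA", "H-bitterness", "Bitterness", "Astringency",
             "B-bitterness2", "Umami")[seq_len(min(6, config$p$ET))],
      EE = paste0("cnv", seq_len(config$p$EE)))
    if (config$p$EN > 10)
      var_names$EN <- c(var_names$EN, paste0("ENx", seq_len(config$p$EN - 10)))
    if (config$p$ET > 6)
      var_names$ET <- c(var_names$ET, paste0("ETx", seq_len(config$p$ET - 6)))

    truth <- list(seed = config$seed, informative = list())
    blocks <- list()
    rep_blocks <- list()
    for (src in c("EN", "ET", "EE")) {
      gb <- gen_sensor_block_(src, config$p[[src]], config$planted[[src]],
                              cls, config)
      rb <- sensor_block(gb$values, src, sample_ids = rep_ids,
                         var_names = var_names[[src]])
      rep_blocks[[src]] <- rb
      blocks[[src]] <- average_replicates(rb, rep_map)
      truth$informative[[src]] <- gb$informative
      truth$class_means[[src]] <- gb$class_means
    }
    nir <- generate_nir(config, cls)
    rb <- sensor_block(nir$values, "NIR", sample_ids = rep_ids,
                       var_names = formatC(nir$grid, format = "f", digits = 2))
    rep_blocks$NIR <- rb
    blocks$NIR <- average_replicates(rb, rep_map)
    truth$informative$NIR <- nir$informative
    truth$nir_peak_centers <- nir$peak_centers
    truth$nir_grid <- nir$grid

    labels <- label_table(
      ids,
      authenticity = ifelse(cls == "FUS", "COUNTERFEIT", "FC"),
      species = as.character(cls))
    list(dataset = assemble_dataset(blocks, labels, task), truth = truth,
         replicate_blocks = rep_blocks)
  })
}
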