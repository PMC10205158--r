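#' Framewise displacement from realignment parameters
#'
#' FD at volume t is the sum of the absolute values of the differentiated six
#' realignment parameters, with the three rotations (radians) converted to arc
#' length on a sphere of the configured radius. The first volume has FD = 0 by
#' convention.
#'
#' @param motion matrix or data frame with one row per volume and six columns:
#'   three translations in mm followed by three rotations in radians.
#' @param rotation_radius_mm sphere radius used to convert rotations to mm
#'   (default 50 mm, the common convention).
#' @return tibble with columns `volume` and `fd` (mm).
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  M <- as.matrix(as.data.frame(motion))
  if (ncol(M) != 6L) abort("`motion` must have 6 columns (3 translations mm, 3 rotations rad).")
  if (nrow(M) < 2L) abort("At least 2 volumes are required.")
  if (!all(is.finite(M))) abort("Motion parameters must be finite.")
  D <- abs(diff(M))
  D[, 4:6] <- D[, 4:6] * rotation_radius_mm
  tibble(volume = seq_len(nrow(M)), fd = c(0, rowSums(D)))
}

#' Run-level motion quality control
#'
#' Flags runs whose maximum framewise displacement exceeds the threshold and
#' summarises how many runs are excluded overall.
#'
#' @param runs data frame with one row per run. Must contain `max_fd` (mm);
#'   any identifier columns (subject, run) are carried through.
#' @param threshold_mm exclusion threshold on the run-maximum FD (default
#'   1 mm). A run is excluded when `max_fd > threshold_mm` (strict).
#' @return a `qc_report`: the input tibble plus logical `excluded`, with
#'   attributes `n_total`, `n_excluded`, `pct_excluded` (percentage, one
#'   decimal); see [glance()].
#' @export
#' @examples
#' qc_runs(tibble::tibble(run = 1:3, max_fd = c(0.4, 1.2, 0.9)))
qc_runs <- function(runs, threshold_mm = 1) {
  runs <- as_tibble(runs)
  if (!"max_fd" %in% names(runs)) abort("`runs` must contain a `max_fd` column.")
  if (nrow(runs) < 1L) abort("At least one run is required.")
  out <- dplyr::mutate(runs, excluded = .data$max_fd > threshold_mm)
  n_total <- nrow(out)
  n_excluded <- sum(out$excluded)
  structure(out,
            threshold_mm = threshold_mm,
            n_total = n_total,
            n_excluded = n_excluded,
            pct_excluded = round(100 * n_excluded / n_total, 1),
            class = c("qc_report", class(out)))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Motion QC: %d of %d runs excluded (%.1f%%) at max FD > %g mm\n",
              attr(x, "n_excluded"), attr(x, "n_total"),
              attr(x, "pct_excluded"), attr(x, "threshold_mm")))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble(n_runs = attr(x, "n_total"), n_excluded = attr(x, "n_excluded"),
         pct_excluded = attr(x, "pct_excluded"),
         threshold_mm = attr(x, "threshold_mm"))
}

#' Trial-wise BOLD area-under-the-curve activation maps
#'
#' For every trial, each voxel's time series is baseline-corrected by
#' subtracting its (linearly interpolated) value at trial onset and then
#' integrated by the trapezoidal rule over the window `onset + window[1]` to
#' `onset + window[2]` seconds, sampled on the acquisition grid (TR spacing)
#' with linear interpolation at the window edges. Trials whose window runs
#' past the end of the run are dropped with a warning.
#'
#' @param bold 4D numeric array (x, y, z, t); volume t is acquired at time
#'   `(t - 1) * tr` seconds.
#' @param events data frame with at least `onset` (s) and `word`; typical
#'   columns also include `modality`, `task`, `trial_type`.
#' @param tr repetition time in seconds.
#' @param window integration window in seconds relative to trial onset.
#' @return a `trial_activation` list: `auc`, a voxels-by-trials matrix (AUC
#'   units, signal x s); `events`, the retained trials; `dim`, the spatial
#'   grid.
#' @export
trial_auc_maps <- function(bold, events, tr = 1, window = c(2, 8)) {
  if (length(dim(bold)) != 4L) abort("`bold` must be a 4D array (x, y, z, t).")
  events <- as_tibble(events)
  if (!all(c("onset", "word") %in% names(events))) {
    abort("`events` must contain `onset` and `word` columns.")
  }
  if (window[2] <= window[1]) abort("`window` must be increasing.")
  d <- dim(bold)
  n_t <- d[4L]
  t_max <- (n_t - 1) * tr
  ok <- events$onset >= 0 & (events$onset + window[2]) <= t_max
  if (any(!ok)) {
    warn(sprintf("Dropping %d trial(s) whose AUC window exceeds the run end.", sum(!ok)))
  }
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0L) abort("No trial window fits inside the run.")

  # One sparse weight column per trial over the volume index: trapezoid
  # weights at the (interpolated) window samples minus the integrated
  # baseline at onset. AUCs are then a single matrix product.
  W <- matrix(0, n_t, nrow(events))
  for (i in seq_len(nrow(events))) {
    o <- events$onset[i]
    tq <- seq(o + window[1], o + window[2], by = tr)
    wq <- rep(tr, length(tq)); wq[c(1L, length(tq))] <- tr / 2
    col <- numeric(n_t)
    add_interp <- function(col, time, weight) {
      pos <- time / tr + 1
      lo <- floor(pos); hi <- ceiling(pos); fr <- pos - lo
      col[lo] <- col[lo] + weight * (1 - fr)
      if (hi != lo) col[hi] <- col[hi] + weight * fr
      col
    }
    for (q in seq_along(tq)) col <- add_interp(col, tq[q], wq[q])
    col <- add_interp(col, o, -sum(wq))  # subtract onset baseline x window length
    W[, i] <- col
  }
  V <- prod(d[1:3])
  auc <- matrix(bold, V, n_t) %*% W
  structure(list(auc = auc, events = events, dim = d[1:3]),
            class = "trial_activation")
}

#' @export
print.trial_activation <- function(x, ...) {
  cat(sprintf("<trial_activation> %d trials on a %s grid\n",
              ncol(x$auc), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Pool trial activation maps into per-word condition patterns
#'
#' Word trials (trial_type `"word"` when present) are averaged voxelwise per
#' word across all retained replications, pooling over runs, tasks and
#' modalities. Control trials are excluded.
#'
#' @param trials a `trial_activation` (from [trial_auc_maps()]) or a list of
#'   them (e.g. one per retained run).
#' @param words character vector fixing the row order of the output; every
#'   word must have at least one retained trial.
#' @return matrix with one row per word (in `words` order) and one column per
#'   voxel, with the spatial grid in attribute `dim`.
#' @export
pool_condition_patterns <- function(trials, words) {
  if (inherits(trials, "trial_activation")) trials <- list(trials)
  dims <- unique(lapply(trials, `[[`, "dim"))
  if (length(dims) != 1L) abort("All runs must share the same spatial grid.")
  auc <- do.call(cbind, lapply(trials, `[[`, "auc"))
  ev <- dplyr::bind_rows(lapply(trials, `[[`, "events"))
  if ("trial_type" %in% names(ev)) {
    keep <- ev$trial_type == "word"
    auc <- auc[, keep, drop = FALSE]
    ev <- ev[keep, , drop = FALSE]
  }
  counts <- table(factor(ev$word, levels = words))
  if (any(counts == 0L)) {
    abort(paste0("Word(s) with zero retained trials: ",
                 paste(names(counts)[counts == 0L], collapse = ", ")))
  }
  G <- vapply(words, function(w) {
    rowMeans(auc[, ev$word == w, drop = FALSE])
  }, numeric(nrow(auc)))
  P <- t(G)
  rownames(P) <- words
  attr(P, "dim3") <- dims[[1L]]
  P
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise mean of the (residual) time series divided by its standard
#' deviation. Voxels with zero temporal SD are flagged `NA`.
#'
#' @param series 4D numeric array (x, y, z, t) with at least 2 time points.
#' @return 3D array of tSNR values.
#' @export
tsnr_map <- function(series) {
  if (length(dim(series)) != 4L) abort("`series` must be a 4D array.")
  d <- dim(series)
  if (d[4L] < 2L) abort("At least 2 time points are required.")
  M <- matrix(series, prod(d[1:3]), d[4L])
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (d[4L] - 1))
  out <- mu / s
  out[s == 0] <- NA_real_
  array(out, d[1:3])
}

#' Grey-matter mask from a probability map
#'
#' Binarises a grey-matter probability volume at a strict threshold
#' (`probability > threshold`; a voxel exactly at the threshold is excluded).
#'
#' @param prob 3D array of probabilities in \[0, 1\].
#' @param threshold probability threshold (default 0.3).
#' @return logical 3D array of class `gm_mask` with attributes `threshold`
#'   and `n_voxels`.
#' @export
grey_matter_mask <- function(prob, threshold = 0.3) {
  if (length(dim(prob)) != 3L) abort("`prob` must be a 3D array.")
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) abort("Probabilities must lie in [0, 1].")
  mask <- !is.na(prob) & prob > threshold
  if (!any(mask)) abort("Empty grey-matter mask.")
  structure(mask, threshold = threshold, n_voxels = sum(mask),
            class = c("gm_mask", "array"))
}
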