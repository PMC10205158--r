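#' Canonical haemodynamic response kernel
#'
#' A smooth unimodal gamma-shaped response peaking near 4 s, tapered by a
#' raised cosine so that it returns exactly to baseline within one 8.25 s
#' interstimulus interval. The analysis pipeline never fits this kernel (it
#' integrates the raw signal), so any plausible shape suffices; the compact
#' support keeps successive trial responses from overlapping, which makes the
#' planted representational geometry exactly recoverable at zero noise. Real
#' BOLD responses overlap across trials at this trial pacing; that source of
#' contamination is deliberately absent here.
#'
#' @param t time in seconds (vector).
#' @param support duration in seconds after which the response is exactly 0.
#' @return response values (unit peak), 0 outside `[0, support)`.
#' @export
canonical_hrf <- function(t, support = 8.25) {
  g <- ifelse(t < 0 | t >= support, 0,
              t^5 * exp(-t) / gamma(6) * cos(pi * t / (2 * support))^2)
  g / max(canonical_hrf_peak(support), 1e-12)
}

canonical_hrf_peak <- function(support) {
  tt <- seq(0, support, by = 0.01)
  max(tt^5 * exp(-tt) / gamma(6) * cos(pi * tt / (2 * support))^2)
}

# Internal: everything fixed per subject before runs are drawn.
synth_subject_plan <- function(word_set, models, config, seed, subject) {
  words <- word_set$words$word
  for (m in models) {
    if (!identical(sm_labels(m), words)) abort("Model RDMs must share the word set.")
  }
  gm_prob <- make_gm_prob(config$dim)
  mask <- gm_prob > 0.3
  region_masks <- lapply(config$regions, function(rg) {
    make_region_mask(config$dim, rg$center, rg$radius_vox)
  })
  for (nm in names(region_masks)) {
    if (any(region_masks[[nm]] & !mask)) {
      abort(sprintf("Region `%s` extends outside the grey-matter mask.", nm))
    }
  }
  master <- as.integer(seed) + 104729L * as.integer(subject)
  withr::with_seed(master, {
    run_seeds <- sample.int(.Machine$integer.max, config$n_runs)
    # subject-specific voxel arrangement of the planted geometry
    patterns <- lapply(seq_along(config$regions), function(ri) {
      rg <- config$regions[[ri]]
      wts <- rg$weights
      if (!all(names(wts) %in% names(models))) {
        abort("Region weights must name planted models.")
      }
      S_t <- Reduce(`+`, Map(function(w, nm) w * unclass(models[[nm]]),
                             wts, names(wts)))
      diag(S_t) <- max(abs(S_t))
      U <- psd_scores(S_t)
      n_r <- sum(region_masks[[ri]])
      if (n_r < ncol(U)) {
        abort(sprintf("Region `%s` (%d voxels) is too small to carry %d pattern dimensions.",
                      names(config$regions)[ri], n_r, ncol(U)))
      }
      Q <- qr.Q(qr(matrix(rnorm(n_r * ncol(U)), n_r, ncol(U))))
      P <- U %*% t(Q) * sqrt(n_r)   # rows ~ unit RMS over region voxels
      rownames(P) <- words
      P
    })
  })
  viol <- config$fd_violating[[as.character(subject)]] %||% integer(0)
  list(words = words, config = config, gm_prob = gm_prob, mask = mask,
       region_masks = region_masks, patterns = patterns,
       run_seeds = run_seeds, fd_violating = as.integer(viol),
       subject = subject)
}

make_gm_prob <- function(dim) {
  ctr <- (dim + 1) / 2
  ax <- (dim / 2) * 0.92
  g <- expand.grid(x = seq_len(dim[1L]), y = seq_len(dim[2L]), z = seq_len(dim[3L]))
  r2 <- ((g$x - ctr[1L]) / ax[1L])^2 + ((g$y - ctr[2L]) / ax[2L])^2 +
    ((g$z - ctr[3L]) / ax[3L])^2
  array(ifelse(r2 <= 1, 0.85, 0.02), dim)
}

make_region_mask <- function(dim, center, radius_vox) {
  if (is.null(center)) center <- round((dim + 1) / 2 + c(-3, -2, 1))
  g <- expand.grid(x = seq_len(dim[1L]), y = seq_len(dim[2L]), z = seq_len(dim[3L]))
  r2 <- (g$x - center[1L])^2 + (g$y - center[2L])^2 + (g$z - center[3L])^2
  array(r2 <= radius_vox^2, dim)
}

# Internal: one synthetic run for a planned subject.
synth_run <- function(plan, run) {
  cf <- plan$config
  withr::with_seed(plan$run_seeds[run], {
    n_trials <- length(plan$words) + cf$n_controls
    order_idx <- sample.int(n_trials)
    trial_word <- c(plan$words, rep(NA_character_, cf$n_controls))[order_idx]
    events <- tibble(
      onset = cf$start_offset + (seq_len(n_trials) - 1) * cf$isi,
      word = ifelse(is.na(trial_word), "control", trial_word),
      modality = if (run <= cf$n_runs / 2) "visual" else "auditory",
      task = sample(c("overt", "covert"), n_trials, replace = TRUE),
      trial_type = ifelse(is.na(trial_word), "control", "word"))

    t_end <- cf$start_offset + n_trials * cf$isi + cf$tail
    n_t <- ceiling(t_end / cf$tr) + 1L
    times <- (seq_len(n_t) - 1) * cf$tr

    in_idx <- which(plan$mask)
    sig <- matrix(rnorm(length(in_idx) * n_t, sd = cf$noise_sd),
                  length(in_idx), n_t) + cf$baseline
    # trial-locked responses in the signal regions
    for (ri in seq_along(plan$region_masks)) {
      reg_idx <- which(plan$region_masks[[ri]])
      reg_pos <- match(reg_idx, in_idx)
      P <- plan$patterns[[ri]]
      for (tr_i in which(events$trial_type == "word")) {
        o <- events$onset[tr_i]
        t0 <- ceiling(o / cf$tr) + 1L
        t1 <- min(n_t, floor((o + cf$isi) / cf$tr) + 1L)
        h <- canonical_hrf(times[t0:t1] - o)
        amp <- cf$amplitude * P[events$word[tr_i], ]
        sig[reg_pos, t0:t1] <- sig[reg_pos, t0:t1] + outer(amp, h)
      }
    }
    bold <- array(0, c(cf$dim, n_t))
    full <- matrix(bold, prod(cf$dim), n_t)
    full[in_idx, ] <- sig
    bold <- array(full, c(cf$dim, n_t))

    motion <- vapply(1:6, function(j) {
      cumsum(c(0, rnorm(n_t - 1L, sd = if (j <= 3L) 0.02 else 4e-4)))
    }, numeric(n_t))
    if (run %in% plan$fd_violating) {
      jump_at <- sample(seq.int(10L, n_t - 10L), 1L)
      motion[jump_at:n_t, 1L] <- motion[jump_at:n_t, 1L] + 1.5
    }
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    list(bold = bold, events = events, motion = motion)
  })
}

#' Generate synthetic per-subject fMRI material with planted geometry
#'
#' For each requested subject, produces preprocessed-looking 4D runs in which
#' the condition-similarity structure inside each configured signal region
#' equals the configured mixture of model RDMs: the mixture matrix is factored
#' by eigendecomposition (negative eigenvalues truncated) into condition
#' scores, rotated onto the region voxels by a random orthonormal basis (so
#' the planted Gram matrix is preserved exactly at zero noise), and each
#' word's pattern scales a canonical response at its trial onsets. White voxel
#' noise, a constant baseline, motion traces (with FD violations exactly in
#' the configured runs) and a grey-matter probability map complete the bundle.
#'
#' @param word_set a [generate_word_set()] result.
#' @param models named list of [similarity_matrix()] objects on the word set;
#'   region weights in `config$regions` refer to these names.
#' @param config a [synth_config()].
#' @param seed master seed; per-subject/run streams are derived from it.
#' @param subjects integer vector of subject indices to generate.
#' @return list with one element per subject: `runs` (each `bold`, `events`,
#'   `motion`), `gm_prob`, and `ground_truth` (region masks, weights, planted
#'   patterns, FD-violating runs).
#' @export
generate_brain_data <- function(word_set, models, config = word_set$config,
                                seed = 1, subjects = seq_len(config$n_subjects)) {
  out <- lapply(subjects, function(s) {
    plan <- synth_subject_plan(word_set, models, config, seed, s)
    runs <- lapply(seq_len(config$n_runs), function(r) synth_run(plan, r))
    list(subject = s, runs = runs, gm_prob = plan$gm_prob,
         ground_truth = list(region_masks = plan$region_masks,
                             weights = lapply(config$regions, `[[`, "weights"),
                             patterns = plan$patterns,
                             fd_violating = plan$fd_violating))
  })
  names(out) <- paste0("sub", subjects)
  out
}

#' Run the activation-extraction pipeline on one synthetic subject
#'
#' Streams the subject's runs one at a time (generate, motion-QC, trial AUC
#' extraction, discard), then pools retained word trials into per-word
#' condition patterns. This is the memory-friendly entry point used by the
#' end-to-end recovery analyses.
#'
#' @inheritParams generate_brain_data
#' @param subject single subject index.
#' @param fd_threshold_mm run-exclusion threshold on maximum FD.
#' @return list: `patterns` (words x voxels, full grid), `mask`
#'   (grey-matter mask), `gm_prob`, `qc` (the run [qc_runs()] report),
#'   `ground_truth`.
#' @export
simulate_subject_patterns <- function(word_set, models, config = word_set$config,
                                      seed = 1, subject = 1,
                                      fd_threshold_mm = 1) {
  plan <- synth_subject_plan(word_set, models, config, seed, subject)
  trials <- list()
  fd_rows <- list()
  for (r in seq_len(config$n_runs)) {
    run <- synth_run(plan, r)
    fd <- framewise_displacement(run$motion)
    fd_rows[[r]] <- tibble(subject = subject, run = r, max_fd = max(fd$fd))
    if (max(fd$fd) <= fd_threshold_mm) {
      trials[[length(trials) + 1L]] <- trial_auc_maps(run$bold, run$events,
                                                      tr = config$tr)
    }
    rm(run)
  }
  qc <- qc_runs(dplyr::bind_rows(fd_rows), threshold_mm = fd_threshold_mm)
  if (!length(trials)) abort("All runs were excluded by motion QC.")
  patterns <- pool_condition_patterns(trials, plan$words)
  list(patterns = patterns, mask = plan$mask, gm_prob = plan$gm_prob, qc = qc,
       ground_truth = list(region_masks = plan$region_masks,
                           weights = lapply(config$regions, `[[`, "weights"),
                           patterns = plan$patterns,
                           fd_violating = plan$fd_violating))
}
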