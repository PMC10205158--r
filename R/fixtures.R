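#' Named fixture presets
#'
#' `fixture_preset()` returns the [synth_config()] behind a named preset:
#' * `"paper-like-small"`: the full emulated design (66 words, 8 runs of 77
#'   trials) for 4 subjects on the desk-scale 20 x 20 x 22 grid.
#' * `"smoke-tiny"`: 1 subject, 2 runs on a 12 x 12 x 12 grid, for fast I/O
#'   smoke testing of the on-disk bundle.
#'
#' @param name preset name.
#' @return a `synth_config`.
#' @export
fixture_preset <- function(name) {
  switch(name,
    "paper-like-small" = synth_config(n_subjects = 4),
    "smoke-tiny" = synth_config(n_subjects = 1, n_runs = 2,
                                dim = c(12, 12, 12),
                                regions = list(signal = list(center = c(6, 6, 6),
                                                             radius_vox = 3,
                                                             weights = c(affective = 1)))),
    abort(sprintf("Unknown preset `%s`.", name))
  )
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates a word set and per-subject fMRI material for a named preset and
#' writes everything the pipeline consumes: word/ratings/embedding/phonology
#' tables and the taxonomy as TSV, per-run 4D volumes as NIfTI with TSV event
#' and motion tables, grey-matter probability and region-mask volumes, and a
#' JSON manifest holding the seed, configuration and ground truth. Re-running
#' with the same preset and seed reproduces byte-identical tabular content.
#'
#' @param name preset name (see [fixture_preset()]).
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return (invisibly) the manifest as a list.
#' @export
make_fixture <- function(name, dir, seed = 1) {
  config <- fixture_preset(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ws <- generate_word_set(config, seed)
  models <- list(affective = affective_similarity(ws$ratings),
                 embedding = embedding_similarity(ws$embeddings))

  write_tsv_plain(ws$words, file.path(dir, "words.tsv"))
  write_tsv_plain(ws$ratings, file.path(dir, "ratings.tsv"))
  write_tsv_plain(ws$embeddings, file.path(dir, "embeddings.tsv"))
  write_tsv_plain(ws$phonology, file.path(dir, "phonology.tsv"))
  write_tsv_plain(ws$taxonomy$nodes, file.path(dir, "taxonomy_nodes.tsv"))
  write_tsv_plain(ws$taxonomy$mapping, file.path(dir, "taxonomy_mapping.tsv"))
  for (nm in names(models)) {
    write_similarity_tsv(models[[nm]], file.path(dir, sprintf("model_%s.tsv", nm)))
  }

  subj_entries <- list()
  for (s in seq_len(config$n_subjects)) {
    sd_dir <- file.path(dir, sprintf("sub%02d", s))
    dir.create(sd_dir, showWarnings = FALSE)
    dat <- generate_brain_data(ws, models, config, seed, subjects = s)[[1L]]
    write_volume(dat$gm_prob, file.path(sd_dir, "gm_prob.nii.gz"), config$voxel_size)
    for (rn in names(dat$ground_truth$region_masks)) {
      write_volume(dat$ground_truth$region_masks[[rn]] * 1,
                   file.path(sd_dir, sprintf("region_%s.nii.gz", rn)),
                   config$voxel_size)
    }
    run_files <- character(config$n_runs)
    for (r in seq_len(config$n_runs)) {
      run <- dat$runs[[r]]
      base <- sprintf("run%02d", r)
      write_volume(run$bold, file.path(sd_dir, paste0(base, "_bold.nii.gz")),
                   config$voxel_size)
      write_tsv_plain(run$events, file.path(sd_dir, paste0(base, "_events.tsv")))
      write_tsv_plain(as.data.frame(run$motion),
                      file.path(sd_dir, paste0(base, "_motion.tsv")))
      run_files[r] <- base
    }
    subj_entries[[s]] <- list(subject = s, dir = basename(sd_dir),
                              runs = config$n_runs,
                              trials_per_run = length(ws$words$word) + config$n_controls,
                              fd_violating = dat$ground_truth$fd_violating)
    rm(dat)
  }

  manifest <- list(preset = name, seed = as.integer(seed),
                   n_words = config$n_words,
                   runs_per_subject = config$n_runs,
                   trials_per_run = config$n_words + config$n_controls,
                   realized_model_cor = ws$realized_model_cor,
                   config = config[setdiff(names(config), "regions")],
                   regions = lapply(config$regions, function(rg) {
                     list(radius_vox = rg$radius_vox,
                          weights = as.list(rg$weights))
                   }),
                   subjects = subj_entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read/write similarity matrices as labelled TSV
#'
#' The matrix is stored with word labels as the first row and column; metric
#' and orientation travel in a one-line `# metric orientation` header comment.
#'
#' @param m a [similarity_matrix()].
#' @param path file path.
#' @return `write_similarity_tsv()` returns `path` invisibly;
#'   `read_similarity_tsv()` returns a [similarity_matrix()].
#' @export
write_similarity_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", attr(m, "metric"), sm_orientation(m)), con)
  utils::write.table(as.data.frame(unclass(m)), con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1L)), " ")[[1L]]
  S <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, skip = 1L, check.names = FALSE))
  similarity_matrix(S, metric = hdr[1L],
                    orientation = hdr[2L], tol = 1e-6)
}

#' Read/write volumes in NIfTI format
#'
#' Thin wrappers around RNifti keeping the package's array-plus-voxel-size
#' convention.
#'
#' @param x 3D or 4D numeric array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel dimensions in mm.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   the array with a `voxel_size` attribute.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(unclass(x))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  out
}
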