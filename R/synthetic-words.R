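#' Configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults mirror
#' the emulated study design: 66 nouns in three valence classes of 22, eight
#' runs per subject of 77 trials each (66 word + 11 control), an 8.25 s
#' interstimulus interval, TR = 1 s, and a desk-scale 20 x 20 x 22 volume.
#'
#' @param n_words total number of words.
#' @param class_sizes named integer vector (positive, neutral, negative).
#' @param n_runs runs per subject.
#' @param n_controls control trials per run (no planted signal).
#' @param isi interstimulus interval in seconds.
#' @param tr repetition time in seconds.
#' @param start_offset seconds before the first trial onset.
#' @param tail seconds of rest appended after the last trial window.
#' @param dim spatial grid (3 integers).
#' @param voxel_size voxel dimensions in mm.
#' @param embedding_dim embedding dimensionality.
#' @param target_model_cor target Pearson correlation between the embedding
#'   cosine RDM and the affective RDM (the generator tunes a mixture to reach
#'   it within +/- 0.02).
#' @param n_subjects number of subjects.
#' @param regions named list of region definitions, each a list with
#'   `center` (voxel index, `NULL` for the default placement), `radius_vox`,
#'   and `weights` (named weights over the planted model RDMs).
#' @param amplitude response amplitude scaling the planted patterns.
#' @param noise_sd SD of the white voxel noise added to in-mask time series.
#' @param baseline constant signal offset inside the mask.
#' @param fd_violating named list mapping subject index (as character) to the
#'   run indices whose motion trace must violate the 1 mm FD criterion.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_words = 66,
                         class_sizes = c(positive = 22, neutral = 22, negative = 22),
                         n_runs = 8, n_controls = 11, isi = 8.25, tr = 1,
                         start_offset = 10, tail = 20,
                         dim = c(20, 20, 22), voxel_size = c(2, 2, 2),
                         embedding_dim = 300, target_model_cor = 0.065,
                         n_subjects = 22,
                         regions = list(signal = list(center = NULL,
                                                      radius_vox = 3.5,
                                                      weights = c(affective = 1))),
                         amplitude = 1, noise_sd = 1, baseline = 100,
                         fd_violating = list()) {
  if (sum(class_sizes) != n_words) abort("`class_sizes` must sum to `n_words`.")
  if (any(c(n_runs, n_controls, isi, tr, n_subjects) <= 0)) {
    abort("Rates and durations must be positive.")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic word set with ratings, embeddings, phonology, taxonomy
#'
#' Emulates the structure of the stimulus material: pseudoword tokens in three
#' valence classes; valence/dominance/arousal ratings on the 1-7 scale with a
#' U-shaped valence-arousal relationship (neutral words least arousing);
#' embedding vectors whose cosine RDM correlates with the affective RDM at a
#' configurable target level (a random matrix is mixed with an
#' affective-aligned component, the mixture tuned by bisection to within
#' +/- 0.02 of the target); random phonological transcriptions over a small
#' phoneme alphabet with Poisson neighbourhood densities; and a random rooted
#' tree taxonomy.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `word_set`: `words`, `ratings`, `embeddings`,
#'   `phonology`, `taxonomy`, plus `realized_model_cor` and `mix_lambda`.
#' @export
generate_word_set <- function(config = synth_config(), seed = 1) {
  withr::with_seed(as.integer(seed), {
    classes <- rep(names(config$class_sizes), config$class_sizes)
    words <- make_pseudowords(config$n_words)
    v_mean <- c(positive = 5.6, neutral = 4.0, negative = 2.4)[classes]
    v_sd <- c(positive = 0.45, neutral = 0.35, negative = 0.45)[classes]
    valence <- clip17(rnorm(config$n_words, v_mean, v_sd))
    dominance <- clip17(rnorm(config$n_words, 4, 0.8))
    arousal <- clip17(3.95 - 0.06 * (valence - 4) + 0.12 * (valence - 4)^2 +
                        rnorm(config$n_words, 0, 0.55))
    ratings <- tibble(word = words, valence = valence,
                      dominance = dominance, arousal = arousal)
    aff <- affective_similarity(ratings)

    emb <- make_embeddings(aff, config$embedding_dim, config$target_model_cor)
    E <- emb$E
    embeddings <- as_tibble(as.data.frame(E), .name_repair = "minimal")
    names(embeddings) <- paste0("e", seq_len(ncol(E)))
    embeddings <- dplyr::bind_cols(tibble(word = words), embeddings)

    phonology <- tibble(word = words, transcription = words,
                        density = rpois(config$n_words, 8))

    n_nodes <- 40L
    node <- sprintf("n%02d", seq_len(n_nodes))
    parent <- c(NA_character_,
                vapply(2:n_nodes, function(i) node[sample.int(i - 1L, 1L)],
                       character(1)))
    taxonomy <- list(nodes = tibble(node = node, parent = parent),
                     mapping = tibble(word = words,
                                      node = sample(node, config$n_words,
                                                    replace = TRUE)))

    structure(list(words = tibble(word = words,
                                  valence_class = factor(classes,
                                                         c("positive", "neutral", "negative"))),
                   ratings = ratings, embeddings = embeddings,
                   phonology = phonology, taxonomy = taxonomy,
                   realized_model_cor = emb$realized,
                   mix_lambda = emb$lambda,
                   config = config, seed = as.integer(seed)),
              class = "word_set")
  })
}

#' @export
print.word_set <- function(x, ...) {
  cat(sprintf("<word_set> %d words (%s), embedding-affective RDM r = %.3f (target %.3f)\n",
              nrow(x$words),
              paste(table(x$words$valence_class), collapse = "/"),
              x$realized_model_cor, x$config$target_model_cor))
  invisible(x)
}

clip17 <- function(x) pmin(7, pmax(1, x))

make_pseudowords <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  repeat {
    w <- vapply(seq_len(n), function(i) {
      syl <- sample(2:3, 1L)
      paste0(vapply(seq_len(syl), function(s)
        paste0(sample(cons, 1L), sample(vow, 1L)), character(1)), collapse = "")
    }, character(1))
    if (!anyDuplicated(w)) return(w)
  }
}

# Mix a random Gaussian embedding with an affective-aligned factor so that the
# cosine RDM hits the target correlation with the affective RDM.
make_embeddings <- function(aff, dim, target) {
  if (target < 0) abort("`target_model_cor` must be nonnegative.")
  n <- nrow(aff)
  a_vec <- rdm_vector(aff)
  Y <- psd_scores(unclass(aff))                 # n x q, Y Y' ~ aff
  R <- qr.Q(qr(matrix(rnorm(dim * ncol(Y)), dim, ncol(Y))))
  Ya <- Y %*% t(R)                              # rotated into embedding space
  Z <- matrix(rnorm(n * dim), n, dim)
  Z <- Z / sqrt(rowSums(Z^2))
  f <- function(lambda) {
    E <- (1 - lambda) * Z + lambda * Ya
    cor(rdm_vector(cosine_rows(E, rownames(aff))), a_vec)
  }
  hi <- f(1)
  if (hi < target - 0.02) {
    abort(sprintf("Target model correlation %.3f unattainable (max %.3f).", target, hi))
  }
  lo_l <- 0; hi_l <- 1
  lambda <- 0; realized <- f(0)
  for (i in seq_len(40L)) {
    if (abs(realized - target) <= 0.005) break
    lambda <- (lo_l + hi_l) / 2
    realized <- f(lambda)
    if (realized < target) lo_l <- lambda else hi_l <- lambda
  }
  E <- (1 - lambda) * Z + lambda * Ya
  list(E = E, lambda = lambda, realized = realized)
}

# Factor a symmetric similarity matrix into condition scores U with
# U U' = S after truncating negative eigenvalues.
psd_scores <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > 1e-10
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
}
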