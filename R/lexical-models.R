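#' Affective similarity from valence, dominance and arousal ratings
#'
#' Words are placed in the three-dimensional affective space spanned by
#' valence, dominance and arousal (each rated on a 1-7 scale). Pairwise
#' Euclidean distances d are computed, normalised by the maximum pairwise
#' distance within the word set (so the most distant pair sits at d = 1), and
#' converted to similarities s = 1 - d. The diagonal is exactly 1 and the most
#' distant pair has similarity exactly 0.
#'
#' @param ratings data frame with one row per word, a word column, and numeric
#'   rating columns (defaults `valence`, `dominance`, `arousal`), all in
#'   \[1, 7\].
#' @param word_col name of the word column.
#' @param cols names of the rating columns spanning the affective space.
#' @return a [similarity_matrix()] with metric `"affective"`, values in
#'   \[0, 1\].
#' @export
#' @examples
#' r <- tibble::tibble(word = c("a", "b", "c"),
#'                     valence = c(1, 7, 4), dominance = c(1, 7, 4),
#'                     arousal = c(1, 7, 4))
#' affective_similarity(r)
affective_similarity <- function(ratings, word_col = "word",
                                 cols = c("valence", "dominance", "arousal")) {
  ratings <- as.data.frame(ratings)
  check_word_table(ratings, word_col, cols)
  words <- as.character(ratings[[word_col]])
  X <- as.matrix(ratings[cols])
  if (!all(is.finite(X))) abort("Affective ratings must be finite.")
  if (any(X < 1 | X > 7)) abort("Affective ratings must lie on the 1-7 scale.")
  if (length(words) < 2L) abort("At least 2 words are required.")
  d <- as.matrix(dist(X, method = "euclidean"))
  dmax <- max(d)
  if (dmax == 0) {
    abort("Degenerate input: all words are identical in (valence, dominance, arousal); the distance normaliser is zero.")
  }
  S <- 1 - d / dmax
  diag(S) <- 1
  dimnames(S) <- list(words, words)
  similarity_matrix(S, metric = "affective")
}

#' Cosine similarity between word embedding vectors
#'
#' @param embeddings data frame with a word column and numeric embedding
#'   dimension columns, or a numeric matrix with words as row names.
#' @param word_col name of the word column (ignored for matrix input).
#' @return a [similarity_matrix()] with metric `"cosine"`, diagonal exactly 1.
#' @export
embedding_similarity <- function(embeddings, word_col = "word") {
  if (is.matrix(embeddings)) {
    words <- rownames(embeddings)
    if (is.null(words)) abort("Matrix input must carry words as row names.")
    E <- embeddings
  } else {
    embeddings <- as.data.frame(embeddings)
    if (!word_col %in% names(embeddings)) {
      abort(sprintf("Column `%s` not found in `embeddings`.", word_col))
    }
    words <- as.character(embeddings[[word_col]])
    E <- as.matrix(embeddings[setdiff(names(embeddings), word_col)])
  }
  if (anyDuplicated(words)) abort("Words must be unique.")
  storage.mode(E) <- "double"
  if (!all(is.finite(E))) abort("Embedding values must be finite.")
  S <- cosine_rows(E, words)
  if (anyNA(S)) {
    bad <- words[rowSums(is.finite(E) & E != 0) == 0]
    abort(paste0("Zero-norm embedding row(s): ", paste(bad, collapse = ", ")))
  }
  similarity_matrix(S, metric = "cosine")
}

# Cosine similarity between the rows of X; zero-norm rows yield NA entries.
cosine_rows <- function(X, labels = rownames(X)) {
  nrm <- sqrt(rowSums(X^2))
  Xn <- X / nrm  # zero-norm rows become NaN rows
  S <- tcrossprod(Xn)
  S[!is.finite(S)] <- NA_real_
  diag(S)[is.finite(diag(S))] <- 1
  S <- (S + t(S)) / 2
  diag(S) <- ifelse(nrm > 0, 1, NA_real_)
  dimnames(S) <- list(labels, labels)
  S
}

#' Phonological similarity from Levenshtein distance between transcriptions
#'
#' Similarity between two transcriptions is 1 minus the Levenshtein edit
#' distance (insertions, deletions, substitutions, unit cost) divided by the
#' length of the longer transcription, giving values in \[0, 1\] with 1 on the
#' diagonal.
#'
#' @param phonology data frame with a word column and a transcription column
#'   of non-empty symbol strings (one character per phoneme symbol).
#' @param word_col,transcription_col column names.
#' @return a [similarity_matrix()] with metric `"levenshtein"`.
#' @export
phonological_similarity <- function(phonology, word_col = "word",
                                    transcription_col = "transcription") {
  phonology <- as.data.frame(phonology)
  check_word_table(phonology, word_col, transcription_col)
  words <- as.character(phonology[[word_col]])
  tr <- as.character(phonology[[transcription_col]])
  if (anyNA(tr) || any(!nzchar(tr))) abort("Transcriptions must be non-empty strings.")
  d <- utils::adist(tr, tr)                      # Levenshtein, unit costs
  len <- nchar(tr)
  norm <- outer(len, len, pmax)
  S <- 1 - d / norm
  diag(S) <- 1
  dimnames(S) <- list(words, words)
  similarity_matrix(S, metric = "levenshtein")
}

#' Phonological neighbourhood-density dissimilarity
#'
#' The model structure is the absolute difference in phonological
#' neighbourhood density between the two words of each pair. This is a
#' dissimilarity (larger = less alike); it is kept on its native scale with
#' the orientation flag set to `"dissimilarity"`, and downstream rank
#' correlations negate it, which is sufficient because Spearman correlation is
#' invariant to monotone rescaling.
#'
#' @param phonology data frame with a word column and a nonnegative integer
#'   density column.
#' @param word_col,density_col column names.
#' @return a [similarity_matrix()] with orientation `"dissimilarity"`.
#' @export
density_dissimilarity <- function(phonology, word_col = "word",
                                  density_col = "density") {
  phonology <- as.data.frame(phonology)
  check_word_table(phonology, word_col, density_col)
  words <- as.character(phonology[[word_col]])
  dens <- phonology[[density_col]]
  if (anyNA(dens) || any(dens < 0)) abort("Densities must be present and nonnegative.")
  S <- abs(outer(dens, dens, "-"))
  dimnames(S) <- list(words, words)
  similarity_matrix(S, metric = "neighbourhood_density", orientation = "dissimilarity")
}

#' Wu-Palmer taxonomy similarity
#'
#' For two words mapped to nodes a and b of a rooted taxonomy,
#' `WPsim = 2 depth(LCS) / (depth(a) + depth(b))`, where LCS is the least
#' common subsumer (deepest shared ancestor) and depth counts nodes from the
#' root with `depth(root) = 1`. Values lie in (0, 1\] with 1 for a node paired
#' with itself.
#'
#' @param taxonomy list with elements `nodes` (data frame: `node`, `parent`,
#'   root has `NA` parent) and `mapping` (data frame: `word`, `node`).
#' @param words optional character vector restricting/ordering the output;
#'   defaults to all mapped words in mapping order.
#' @return a [similarity_matrix()] with metric `"wu_palmer"`.
#' @export
wu_palmer_similarity <- function(taxonomy, words = NULL) {
  nodes <- as.data.frame(taxonomy$nodes)
  mapping <- as.data.frame(taxonomy$mapping)
  if (!all(c("node", "parent") %in% names(nodes)) ||
      !all(c("word", "node") %in% names(mapping))) {
    abort("`taxonomy` needs $nodes (node, parent) and $mapping (word, node).")
  }
  anc <- taxonomy_ancestry(nodes)
  if (is.null(words)) words <- as.character(mapping$word)
  idx <- match(words, mapping$word)
  missing_words <- words[is.na(idx)]
  node_of <- mapping$node[idx]
  unmapped <- !is.na(idx) & !(node_of %in% names(anc$depth))
  missing_words <- c(missing_words, words[unmapped])
  if (length(missing_words)) {
    abort(paste0("Word(s) not mapped to the taxonomy: ",
                 paste(unique(missing_words), collapse = ", ")))
  }
  paths <- anc$path[node_of]   # each: nodes from the node up to the root
  depth <- anc$depth[node_of]
  n <- length(words)
  S <- matrix(1, n, n, dimnames = list(words, words))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      pi_set <- paths[[i]]
      for (j in seq.int(i + 1L, n)) {
        common <- intersect(pi_set, paths[[j]])
        lcs_depth <- max(anc$depth[common])
        S[i, j] <- S[j, i] <- 2 * lcs_depth / (depth[i] + depth[j])
      }
    }
  }
  similarity_matrix(S, metric = "wu_palmer")
}

# Validate a rooted tree given as (node, parent) rows and return, per node,
# its depth (root = 1) and its root path. Errors on cycles, multiple roots,
# or unreachable nodes.
taxonomy_ancestry <- function(nodes) {
  node <- as.character(nodes$node)
  parent <- as.character(nodes$parent)
  if (anyDuplicated(node)) abort("Taxonomy nodes must be unique.")
  is_root <- is.na(parent)
  if (sum(is_root) != 1L) abort("Taxonomy must have exactly one root (parent = NA).")
  if (!all(parent[!is_root] %in% node)) abort("Every non-root parent must itself be a node.")
  parent_of <- setNames(parent, node)
  n <- length(node)
  depth <- setNames(rep(NA_real_, n), node)
  path <- setNames(vector("list", n), node)
  for (nd in node) {
    chain <- character(0)
    cur <- nd
    while (!is.na(cur)) {
      if (cur %in% chain) abort(sprintf("Cycle detected in taxonomy at node `%s`.", cur))
      chain <- c(chain, cur)
      if (length(chain) > n) abort("Taxonomy walk did not reach the root (cycle?).")
      cur <- parent_of[[cur]]
    }
    depth[[nd]] <- length(chain)
    path[[nd]] <- chain
  }
  list(depth = depth, path = path)
}

check_word_table <- function(df, word_col, value_cols) {
  miss <- setdiff(c(word_col, value_cols), names(df))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df[[word_col]])) abort("Words must be unique.")
  invisible(df)
}
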