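#' Word-by-word similarity matrices
#'
#' `similarity_matrix()` wraps a square symmetric matrix of pairwise word
#' similarities (or dissimilarities) together with the metric that produced it
#' and an orientation flag. The orientation matters downstream: rank
#' correlations between model structures negate dissimilarity-oriented
#' matrices so that all models correlate on a common "larger = more similar"
#' convention.
#'
#' @param S square numeric matrix with row/column names giving the word labels.
#' @param metric character scalar naming the metric (e.g. `"cosine"`,
#'   `"affective"`, `"levenshtein"`).
#' @param orientation `"similarity"` or `"dissimilarity"`.
#' @param tol maximum tolerated asymmetry `max(|S - t(S)|)`.
#'
#' @return An object of class `similarity_matrix`: the matrix with `metric`
#'   and `orientation` attributes.
#' @export
#' @examples
#' S <- diag(3); dimnames(S) <- list(letters[1:3], letters[1:3])
#' similarity_matrix(S, metric = "identity")
similarity_matrix <- function(S, metric = "unknown",
                              orientation = c("similarity", "dissimilarity"),
                              tol = 1e-12) {
  orientation <- match.arg(orientation)
  if (!is.matrix(S) || !is.numeric(S)) abort("`S` must be a numeric matrix.")
  if (nrow(S) != ncol(S)) abort("`S` must be square.")
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    abort("`S` must carry word labels as row and column names.")
  }
  if (!identical(rownames(S), colnames(S))) {
    abort("Row and column labels of `S` must be identical.")
  }
  asym <- max(abs(S - t(S)), na.rm = TRUE)
  if (is.finite(asym) && asym > tol) {
    abort(sprintf("`S` is asymmetric beyond tolerance (max |S - t(S)| = %.3g).", asym))
  }
  S[] <- (S + t(S)) / 2  # enforce exact symmetry of representation
  structure(S, metric = metric, orientation = orientation,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d words, metric = %s, orientation = %s\n",
              nrow(x), attr(x, "metric"), attr(x, "orientation")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... (%d rows omitted)\n", nrow(x) - 6L))
  invisible(x)
}

sm_labels <- function(x) rownames(x)

sm_orientation <- function(x) attr(x, "orientation") %||% "similarity"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten a similarity matrix to its off-diagonal vector (RDM vector)
#'
#' Extracts the upper triangle (i < j) in row-major pair order
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This pair ordering is fixed
#' package-wide so that model and neural RDM vectors are always comparable
#' element by element. [rdm_matrix()] inverts the operation exactly.
#'
#' @param m a [similarity_matrix()] or plain symmetric matrix.
#' @param tol asymmetry tolerance.
#' @return numeric vector of length `n (n - 1) / 2`, with attributes `labels`
#'   and `orientation` carried over.
#' @export
rdm_vector <- function(m, tol = 1e-8) {
  if (!is.matrix(m)) abort("`m` must be a matrix.")
  if (nrow(m) != ncol(m)) abort("`m` must be square.")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) {
    abort("`m` is asymmetric beyond tolerance; refusing to vectorize.")
  }
  tm <- t(m)
  v <- tm[lower.tri(tm)]  # column-major lower triangle of t(m) == row-major upper of m
  structure(as.numeric(v),
            labels = rownames(m),
            orientation = sm_orientation(m))
}

#' Rebuild a similarity matrix from an RDM vector
#'
#' @param v vector from [rdm_vector()] (or any vector of length n(n-1)/2).
#' @param labels word labels; defaults to the `labels` attribute of `v`.
#' @param diagonal value placed on the diagonal (default 1).
#' @param metric,orientation metadata for the rebuilt matrix.
#' @return a [similarity_matrix()].
#' @export
rdm_matrix <- function(v, labels = attr(v, "labels"), diagonal = 1,
                       metric = "unknown",
                       orientation = attr(v, "orientation") %||% "similarity") {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) abort("Length of `v` is not n(n-1)/2 for integer n.")
  n <- as.integer(round(n))
  if (is.null(labels)) labels <- paste0("w", seq_len(n))
  if (length(labels) != n) abort("`labels` length does not match vector size.")
  S <- matrix(diagonal, n, n, dimnames = list(labels, labels))
  tS <- t(S)
  tS[lower.tri(tS)] <- v
  S <- t(tS)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  similarity_matrix(S, metric = metric, orientation = orientation, tol = 1e-6)
}

# Orientation-signed RDM vector: dissimilarities are negated so every model
# correlates on a "larger = more similar" scale.
rdm_signed <- function(m) {
  v <- rdm_vector(m)
  if (identical(attr(v, "orientation"), "dissimilarity")) -v else as.numeric(v)
}

# Linear indices of the row-major upper triangle of an n x n matrix, matching
# rdm_vector()'s pair order. Used by hot loops to avoid re-deriving it.
upper_pair_index <- function(n) {
  ij <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  (ij[, 2L] - 1L) * n + ij[, 1L]
}
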