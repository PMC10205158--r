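#' Define fixed-size searchlight neighbourhoods over a mask
#'
#' Every in-mask voxel becomes a searchlight center whose members are its k
#' nearest in-mask voxels by Euclidean distance in millimetres (the center is
#' its own nearest neighbour). Ties are broken by ascending linear voxel
#' index, making the neighbourhoods fully deterministic. If the mask holds
#' fewer than k voxels, all of them are used.
#'
#' @param mask logical 3D array (e.g. from [grey_matter_mask()]).
#' @param k target number of voxels per searchlight (default 200).
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @return a `searchlight_map`: list with `members` (k x n-centers integer
#'   matrix of in-mask voxel positions, first row = the center), `centers`
#'   (linear voxel indices), `dim`, `voxel_size`, `k`.
#' @export
define_searchlights <- function(mask, k = 200, voxel_size = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) abort("`mask` must be a 3D array.")
  if (k < 2L) abort("`k` must be at least 2.")
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) abort("Empty mask.")
  coords <- (arrayInd(idx, dim(mask)) - 1) *
    matrix(voxel_size, n, 3L, byrow = TRUE)
  k_eff <- min(as.integer(k), n)
  members <- matrix(0L, k_eff, n)
  d2 <- rowSums(coords^2)
  chunk <- 256L
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    # squared distances from every in-mask voxel to the chunk's centers
    cross <- coords %*% t(coords[cols, , drop = FALSE])
    D2 <- d2 - 2 * cross + matrix(d2[cols], n, length(cols), byrow = TRUE)
    for (j in seq_along(cols)) {
      ord <- order(D2[, j], idx)[seq_len(k_eff)]
      # keep the center first, remaining members by distance
      cj <- cols[j]
      if (ord[1L] != cj) ord <- c(cj, setdiff(ord, cj))[seq_len(k_eff)]
      members[, cols[j]] <- ord
    }
  }
  structure(list(members = members, centers = idx, dim = dim(mask),
                 voxel_size = voxel_size, k = k_eff),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("<searchlight_map> %d centers, k = %d, grid %s\n",
              length(x$centers), x$k, paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Neural similarity structure of condition patterns
#'
#' Optionally centres the patterns by subtracting the across-condition mean
#' pattern from every condition, then computes pairwise cosine similarity
#' between condition patterns. Conditions whose (centred) pattern has zero
#' norm yield `NA` entries.
#'
#' @param patterns numeric matrix, conditions x voxels, with condition labels
#'   as row names.
#' @param centring subtract the mean pattern first? (default `TRUE`, the
#'   recommended centring for cosine-based RDMs).
#' @return a [similarity_matrix()] with metric `"cosine"`.
#' @export
neural_similarity <- function(patterns, centring = TRUE) {
  if (!is.matrix(patterns)) patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3L) abort("At least 3 conditions are required.")
  if (ncol(patterns) < 2L) abort("At least 2 voxels are required.")
  if (is.null(rownames(patterns))) {
    rownames(patterns) <- paste0("cond", seq_len(nrow(patterns)))
  }
  if (centring) {
    patterns <- patterns - matrix(colMeans(patterns), nrow(patterns),
                                  ncol(patterns), byrow = TRUE)
  }
  S <- cosine_rows(patterns)
  similarity_matrix(S, metric = "cosine", tol = 1e-8)
}

#' Plain or partial rank correlation between neural and model structure
#'
#' With no covariates, the Spearman correlation between the two RDM vectors.
#' With covariates, the partial Spearman correlation: all vectors are rank
#' transformed (average ranks for ties), the neural and model ranks are
#' residualised on the covariate ranks (plus intercept) by least squares, and
#' the residuals are correlated. Dissimilarity-oriented matrices are negated
#' before correlating.
#'
#' @param neural,model [similarity_matrix()] objects with matching labels.
#' @param covariates list of [similarity_matrix()] objects to partial out.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return correlation coefficient in \[-1, 1\], or `NA` if degenerate.
#' @export
rsa_correlation <- function(neural, model, covariates = list(),
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(sm_labels(neural), sm_labels(model))) {
    abort("`neural` and `model` must share the same labels in the same order.")
  }
  for (cv in covariates) {
    if (!identical(sm_labels(cv), sm_labels(neural))) {
      abort("Covariate labels must match the neural/model labels.")
    }
  }
  x <- rdm_signed(neural)
  y <- rdm_signed(model)
  Z <- if (length(covariates)) {
    vapply(covariates, rdm_signed, numeric(length(x)))
  } else NULL
  partial_cor_vec(x, y, Z, rank_transform = method == "spearman")
}

partial_cor_vec <- function(x, y, Z = NULL, rank_transform = TRUE) {
  if (anyNA(x) || anyNA(y) || (!is.null(Z) && anyNA(Z))) return(NA_real_)
  if (rank_transform) {
    x <- rank(x); y <- rank(y)
    if (!is.null(Z)) Z <- apply(Z, 2L, rank)
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  if (!is.null(Z)) {
    Q <- qr.Q(qr(cbind(1, Z)))
    x <- x - Q %*% crossprod(Q, x)
    y <- y - Q %*% crossprod(Q, y)
    if (sqrt(sum(x^2)) < 1e-12 || sqrt(sum(y^2)) < 1e-12) return(0)
  }
  as.numeric(cor(x, y))
}

#' Whole-brain searchlight RSA map(s)
#'
#' At every searchlight center, the member-voxel condition patterns are turned
#' into a cosine neural similarity structure (after optional centring) whose
#' rank correlation — plain or partial — with each requested model is written
#' to that voxel. All analyses share one pass over the searchlights.
#'
#' @param patterns conditions x voxels matrix: either over the full grid
#'   (`ncol == prod(dim(mask))`) or over in-mask voxels (`ncol == sum(mask)`),
#'   with conditions as row names matching the model labels.
#' @param mask logical 3D array.
#' @param analyses a single [similarity_matrix()], or a named list whose
#'   elements are either a `similarity_matrix` or a
#'   `list(model = , covariates = list(...))` for partial RSA.
#' @param k searchlight size (ignored when `searchlights` is supplied).
#' @param voxel_size voxel dimensions in mm.
#' @param centring centre patterns within each searchlight (default `TRUE`).
#' @param searchlights optional precomputed [define_searchlights()] result.
#' @return a single `rsa_map` (3D array of correlations, `NA` outside the
#'   mask) when `analyses` is one model, otherwise a named list of them.
#' @export
searchlight_rsa <- function(patterns, mask, analyses, k = 200,
                            voxel_size = c(1, 1, 1), centring = TRUE,
                            searchlights = NULL) {
  single <- inherits(analyses, "similarity_matrix")
  if (single) analyses <- list(rsa = analyses)
  if (is.null(names(analyses)) || any(!nzchar(names(analyses)))) {
    abort("`analyses` must be named.")
  }
  analyses <- lapply(analyses, function(a) {
    if (inherits(a, "similarity_matrix")) a <- list(model = a, covariates = list())
    if (is.null(a$covariates)) a$covariates <- list()
    a
  })

  if (length(dim(mask)) != 3L) abort("`mask` must be a 3D array.")
  n_in <- sum(mask)
  if (ncol(patterns) == prod(dim(mask))) {
    P <- patterns[, which(mask), drop = FALSE]
  } else if (ncol(patterns) == n_in) {
    P <- patterns
  } else {
    abort("`patterns` columns match neither the full grid nor the mask size.")
  }
  words <- rownames(P)
  n_cond <- nrow(P)
  if (n_cond < 3L) abort("At least 3 conditions are required.")

  # Per-analysis precomputation: rank-transformed (signed) model vector and,
  # for partial RSA, an orthonormal covariate basis shared by all centers.
  prep <- lapply(analyses, function(a) {
    if (!identical(sm_labels(a$model), words)) {
      abort("Model labels must match the pattern row names (same order).")
    }
    for (cv in a$covariates) {
      if (!identical(sm_labels(cv), words)) abort("Covariate labels must match the patterns.")
    }
    y <- rank(rdm_signed(a$model))
    Q <- NULL
    if (length(a$covariates)) {
      Z <- vapply(a$covariates, function(cv) rank(rdm_signed(cv)),
                  numeric(length(y)))
      Q <- qr.Q(qr(cbind(1, Z)))
      y <- y - Q %*% crossprod(Q, y)
    } else {
      y <- y - mean(y)
    }
    ny <- sqrt(sum(y^2))
    if (ny < 1e-12) abort("A model is constant (or fully explained by its covariates) after rank transform.")
    list(y = as.numeric(y) / ny, Q = Q)
  })

  if (is.null(searchlights)) {
    searchlights <- define_searchlights(mask, k = k, voxel_size = voxel_size)
  }
  mem <- searchlights$members
  n_centers <- ncol(mem)
  ut <- upper_pair_index(n_cond)
  res <- matrix(NA_real_, n_centers, length(prep))

  for (c_i in seq_len(n_centers)) {
    X <- P[, mem[, c_i], drop = FALSE]
    if (centring) X <- X - matrix(colMeans(X), n_cond, ncol(X), byrow = TRUE)
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) next  # degenerate searchlight: flagged missing
    v <- tcrossprod(X / nrm)[ut]
    rv <- rank(v)
    if (rv[1L] == rv[2L] && all(rv == rv[1L])) next  # zero rank variance
    for (a_i in seq_along(prep)) {
      pr <- prep[[a_i]]
      xr <- if (is.null(pr$Q)) rv - mean(rv) else rv - pr$Q %*% crossprod(pr$Q, rv)
      nx <- sqrt(sum(xr^2))
      res[c_i, a_i] <- if (nx < 1e-12) 0 else sum(xr * pr$y) / nx
    }
  }

  out <- lapply(seq_along(prep), function(a_i) {
    vol <- array(NA_real_, searchlights$dim)
    vol[searchlights$centers] <- res[, a_i]
    structure(vol,
              model = names(analyses)[a_i],
              covariates = names(analyses[[a_i]]$covariates) %||%
                character(0),
              voxel_size = searchlights$voxel_size,
              statistic = "spearman_rho",
              class = c("rsa_map", "array"))
  })
  names(out) <- names(analyses)
  if (single) out[[1L]] else out
}

#' Fisher r-to-z transform of a correlation map
#'
#' Voxelwise `atanh`; correlations at exactly +/-1 are flagged `NA`.
#'
#' @param x numeric array (e.g. an `rsa_map`) of correlations.
#' @return array of the same shape with transformed values.
#' @export
fisher_z <- function(x) {
  out <- x
  bad <- is.finite(x) & abs(x) >= 1
  out[] <- atanh(ifelse(bad, NA_real_, x))
  if (inherits(out, "rsa_map")) attr(out, "statistic") <- "fisher_z"
  out
}

#' Gaussian smoothing of a volume with mask renormalisation
#'
#' Separable Gaussian smoothing with the given full width at half maximum in
#' mm. Voxels outside the mask (or non-finite) are excluded by renormalising
#' the kernel weights over the valid neighbourhood, so valid values never
#' bleed across the mask border and a constant volume is returned unchanged.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm positive full width at half maximum in mm.
#' @param voxel_size voxel dimensions in mm.
#' @param mask optional logical array of valid voxels; defaults to
#'   `is.finite(vol)`.
#' @return smoothed array, `NA` outside the mask.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size = c(1, 1, 1), mask = NULL) {
  if (length(dim(vol)) != 3L) abort("`vol` must be a 3D array.")
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) abort("`fwhm_mm` must be positive.")
  if (is.null(mask)) mask <- is.finite(vol)
  w <- array(as.numeric(mask), dim(vol))
  v0 <- ifelse(mask, vol, 0)
  sd_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sd_vox <- sd_mm / voxel_size[ax]
    r <- ceiling(3.5 * sd_vox)
    if (r < 1) next
    kern <- exp(-0.5 * ((-r:r) / sd_vox)^2)
    kern <- kern / sum(kern)
    v0 <- conv_along(v0, kern, ax)
    w <- conv_along(w, kern, ax)
  }
  out <- v0 / w
  out[!mask | w == 0] <- NA_real_
  array(out, dim(vol))
}

# Zero-padded 1D convolution of a 3D array along one axis (odd-length kernel).
conv_along <- function(a, kern, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, d[axis], prod(d[-axis]))
  r <- (length(kern) - 1L) / 2L
  mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  f <- stats::filter(mp, kern, sides = 2L)
  m[] <- f[(r + 1L):(r + d[axis]), ]
  ap <- array(m, d[perm])
  aperm(ap, order(perm))
}
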