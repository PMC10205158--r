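#' Voxelwise one-sample t-test across subjects
#'
#' At every voxel present (finite) in all subjects, tests whether the mean
#' across subjects differs from zero: `t = mean / (SD / sqrt(N))`,
#' `df = N - 1`. Voxels missing in any subject, or with zero across-subject
#' SD, are flagged `NA`.
#'
#' @param maps list of 3D arrays (one per subject) on a common grid, e.g.
#'   Fisher-z searchlight maps.
#' @return a `t_map`: 3D array of t values with attribute `df`.
#' @export
one_sample_ttest <- function(maps) {
  X <- stack_maps(maps)
  n <- nrow(X)
  if (n < 3L) abort("At least 3 subjects are required.")
  mu <- colMeans(X)
  s <- sqrt(colSums((X - matrix(mu, n, ncol(X), byrow = TRUE))^2) / (n - 1))
  tval <- mu / (s / sqrt(n))
  tval[!is.finite(tval)] <- NA_real_
  out <- array(tval, dim(maps[[1L]]))
  structure(out, df = n - 1L, class = c("t_map", "array"))
}

#' Voxelwise paired t-test between two matched sets of subject maps
#'
#' Equivalent to a one-sample t-test on the voxelwise differences A - B for
#' the same subjects in the same order.
#'
#' @param mapsA,mapsB lists of 3D arrays, matched by subject.
#' @return a `t_map` (see [one_sample_ttest()]).
#' @export
paired_ttest <- function(mapsA, mapsB) {
  if (length(mapsA) != length(mapsB)) abort("`mapsA` and `mapsB` must have the same subjects.")
  diffs <- purrr::map2(mapsA, mapsB, function(a, b) {
    if (!identical(dim(a), dim(b))) abort("Subject maps must share the same grid.")
    a - b
  })
  one_sample_ttest(diffs)
}

stack_maps <- function(maps) {
  if (!is.list(maps) || length(maps) < 2L) abort("`maps` must be a list of subject volumes.")
  d <- dim(maps[[1L]])
  for (m in maps) {
    if (!identical(dim(m), d)) abort("All subject maps must share the same grid.")
  }
  do.call(rbind, lapply(maps, as.numeric))
}

#' Cluster-extent inference with permutation familywise-error control
#'
#' Thresholds the group t-map at an uncorrected voxelwise p, forms clusters of
#' suprathreshold voxels (18-connectivity by default), and assigns each
#' cluster a familywise-error corrected p-value from a sign-flipping null: the
#' subject maps are multiplied by random signs, the maximum suprathreshold
#' cluster size is recorded for each flip, and the corrected p is the
#' proportion of null maxima at least as large as the observed cluster. All
#' `2^N` sign patterns are enumerated when `N <= 12`; otherwise
#' `n_permutations` random patterns (always including the identity) are drawn.
#'
#' @param maps list of per-subject 3D arrays (e.g. Fisher-z maps).
#' @param voxel_p uncorrected voxelwise threshold (default 0.001), applied
#'   one-sided (`t > t_crit`) by default.
#' @param cluster_fwe_p familywise-error threshold on cluster p (default 0.05).
#' @param n_permutations number of random sign flips when enumeration is
#'   infeasible.
#' @param seed integer seed for the random flips.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param voxel_size voxel dimensions in mm, used for peak coordinates.
#' @param alternative `"greater"` (default; positive effects, as for RSA
#'   correlations) or `"two.sided"`.
#' @return a `group_result`: list with the observed `t_map`, `df`, `clusters`
#'   tibble (`cluster`, `size`, `p_fwe`, peak voxel indices/mm/t,
#'   `significant`), cluster `labels` array, thresholds and the permutation
#'   null of maximum cluster sizes. See [tidy()]/[glance()].
#' @export
cluster_inference <- function(maps, voxel_p = 0.001, cluster_fwe_p = 0.05,
                              n_permutations = 1000, seed = 1,
                              connectivity = 18, voxel_size = c(1, 1, 1),
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  X <- stack_maps(maps)
  n <- nrow(X)
  if (n < 3L) abort("At least 3 subjects are required.")
  df <- n - 1L
  dims <- dim(maps[[1L]])
  ok <- apply(is.finite(X), 2L, all)
  idx <- which(ok)
  Xv <- X[, idx, drop = FALSE]

  tcrit <- if (alternative == "greater") qt(1 - voxel_p, df) else qt(1 - voxel_p / 2, df)
  tfun <- function(S) {
    # t statistics for every sign-flip row of S at once; sign flips leave
    # the sum of squares unchanged.
    M <- (S %*% Xv) / n
    ssq <- matrix(colSums(Xv^2), nrow(S), ncol(Xv), byrow = TRUE)
    V <- (ssq - n * M^2) / (n - 1)
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- -Inf
    if (alternative == "two.sided") abs(Tm) else Tm
  }

  t_obs <- tfun(matrix(1, 1L, n))[1L, ]
  supra <- which(t_obs > tcrit)
  labels_arr <- array(NA_integer_, dims)
  clusters <- tibble(cluster = integer(0), size = integer(0), p_fwe = numeric(0),
                     peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
                     peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                     peak_z_mm = numeric(0), peak_t = numeric(0),
                     significant = logical(0))

  # Sign-flip null of the maximum cluster size
  if (n <= 12L) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    S <- withr::with_seed(seed,
      matrix(sample(c(1, -1), n_permutations * n, replace = TRUE),
             n_permutations, n))
    S[1L, ] <- 1  # include the identity flip
  }
  null_max <- integer(0)
  block <- 512L
  for (start in seq(1L, nrow(S), by = block)) {
    rows <- start:min(start + block - 1L, nrow(S))
    Tm <- tfun(S[rows, , drop = FALSE])
    null_max <- c(null_max, cc_max_cluster_sizes(Tm, tcrit, idx, as.integer(dims),
                                                 as.integer(connectivity)))
  }

  if (length(supra)) {
    vox <- idx[supra]
    lab <- cc_label_voxels(as.integer(vox), as.integer(dims), as.integer(connectivity))
    labels_arr[vox] <- lab
    sizes <- tabulate(lab)
    ord <- order(sizes, decreasing = TRUE)
    rows <- lapply(seq_along(ord), function(r) {
      cl <- ord[r]
      members <- which(lab == cl)
      tv <- t_obs[supra[members]]
      peak <- members[which.max(tv)]
      pc <- arrayInd(vox[peak], dims)
      tibble(cluster = r, size = sizes[cl],
             p_fwe = mean(null_max >= sizes[cl]),
             peak_x = pc[1L], peak_y = pc[2L], peak_z = pc[3L],
             peak_x_mm = (pc[1L] - 1) * voxel_size[1L],
             peak_y_mm = (pc[2L] - 1) * voxel_size[2L],
             peak_z_mm = (pc[3L] - 1) * voxel_size[3L],
             peak_t = max(tv))
    })
    clusters <- dplyr::bind_rows(rows)
    clusters$significant <- clusters$p_fwe < cluster_fwe_p
    # renumber the label volume to match the size-ordered cluster table
    relab <- match(lab, ord)
    labels_arr[vox] <- relab
  }

  t_arr <- array(NA_real_, dims)
  t_arr[idx] <- t_obs
  structure(list(t = structure(t_arr, df = df, class = c("t_map", "array")),
                 df = df, clusters = clusters, labels = labels_arr,
                 voxel_p = voxel_p, cluster_fwe_p = cluster_fwe_p,
                 t_threshold = tcrit, alternative = alternative,
                 n_permutations = length(null_max), null_max = null_max),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("Cluster-extent inference: df = %d, voxel p < %g (t > %.2f), %d sign flips\n",
              x$df, x$voxel_p, x$t_threshold, x$n_permutations))
  if (nrow(x$clusters) == 0L) {
    cat("No suprathreshold clusters.\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_result <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.group_result <- function(x, ...) {
  tibble(df = x$df, n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$significant),
         voxel_p = x$voxel_p, cluster_fwe_p = x$cluster_fwe_p,
         n_permutations = x$n_permutations)
}

#' Across-subject mean correlation and confidence interval at a voxel
#'
#' Utility mirroring peak-table reporting: the mean across subjects of the
#' voxel's correlation values with a t-based confidence interval.
#'
#' @param maps list of per-subject 3D correlation maps.
#' @param voxel integer length-3 voxel index.
#' @param conf_level confidence level (default 0.95).
#' @return tibble with `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
voxel_correlation_ci <- function(maps, voxel, conf_level = 0.95) {
  vals <- vapply(maps, function(m) m[voxel[1L], voxel[2L], voxel[3L]], numeric(1))
  vals <- vals[is.finite(vals)]
  n <- length(vals)
  if (n < 3L) abort("At least 3 finite subject values are required.")
  se <- sd(vals) / sqrt(n)
  tq <- qt(1 - (1 - conf_level) / 2, n - 1L)
  tibble(estimate = mean(vals), conf_low = mean(vals) - tq * se,
         conf_high = mean(vals) + tq * se, n = n)
}
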