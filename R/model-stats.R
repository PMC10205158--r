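#' Correlogram between word similarity models
#'
#' Correlates the off-diagonal RDM vectors of every pair of models after
#' intersecting their word labels (words absent from some source are dropped,
#' as when a taxonomy or norm set lacks a word). Dissimilarity-oriented models
#' are negated before correlating so all entries share the "larger = more
#' similar" convention.
#'
#' @param models named list of [similarity_matrix()] objects.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `lexrsa_correlogram`: the symmetric correlation matrix with
#'   attributes `method` and `n_pairs`; see [tidy()] and [autoplot()] methods.
#' @export
model_correlogram <- function(models, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.list(models) || length(models) < 2L) {
    abort("`models` must be a named list of at least two similarity matrices.")
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("`models` must be named.")
  }
  labs <- Reduce(intersect, lapply(models, sm_labels))
  if (length(labs) < 3L) {
    abort("Fewer than 3 words shared by all models after intersecting labels.")
  }
  vecs <- vapply(models, function(m) {
    rdm_signed(structure(unclass(m)[labs, labs, drop = FALSE],
                         orientation = sm_orientation(m)))
  }, numeric(length(labs) * (length(labs) - 1L) / 2L))
  R <- cor(vecs, method = method)
  structure(R, method = method, n_words = length(labs),
            n_pairs = nrow(vecs),
            class = c("lexrsa_correlogram", "matrix", "array"))
}

#' @export
print.lexrsa_correlogram <- function(x, digits = 3, ...) {
  cat(sprintf("<model correlogram> method = %s, %d shared words (%d pairs)\n",
              attr(x, "method"), attr(x, "n_words"), attr(x, "n_pairs")))
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(round(m, digits))
  invisible(x)
}

#' @describeIn model_correlogram long-format tibble of the pairwise entries.
#' @param x a `lexrsa_correlogram`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.lexrsa_correlogram <- function(x, ...) {
  nm <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(model1 = nm[idx[, 1L]], model2 = nm[idx[, 2L]],
         estimate = unclass(x)[idx],
         method = attr(x, "method"), n_pairs = attr(x, "n_pairs"))
}

#' @describeIn model_correlogram heat-map of the correlogram.
#' @param object a `lexrsa_correlogram`.
#' @exportS3Method ggplot2::autoplot
autoplot.lexrsa_correlogram <- function(object, ...) {
  nm <- rownames(object)
  df <- tidyr::expand_grid(model1 = factor(nm, nm), model2 = factor(nm, nm))
  df$estimate <- as.numeric(unclass(object)[cbind(as.integer(df$model1),
                                                  as.integer(df$model2))])
  ggplot2::ggplot(df, ggplot2::aes(.data$model1, .data$model2, fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$estimate)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = attr(object, "method")) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Pearson-Filon test for two dependent overlapping correlations
#'
#' Compares two correlations r12 and r13 that share variable 1 and were
#' measured on the same n observations, given the overlap correlation r23.
#' The statistic is
#' `z = (r12 - r13) sqrt(n) / sqrt((1 - r12^2)^2 + (1 - r13^2)^2 - 2 k)` with
#' `k = r23 (1 - r12^2 - r13^2) - r12 r13 (1 - r12^2 - r13^2 - r23^2) / 2`,
#' referred to the standard normal (two-sided p).
#'
#' @param r12,r13 the two correlations being compared, each in (-1, 1).
#' @param r23 correlation between variables 2 and 3, in (-1, 1).
#' @param n number of observations (word pairs), at least 4.
#' @return object of class `pf_test` with fields `z`, `p_value`, `r12`, `r13`,
#'   `r23`, `n`; see [tidy()]/[glance()].
#' @export
#' @examples
#' pearson_filon_z(0.065, 0.310, 0.458, n = 2145)
pearson_filon_z <- function(r12, r13, r23, n) {
  rs <- c(r12 = r12, r13 = r13, r23 = r23)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    abort("Correlations must be finite and strictly inside (-1, 1).")
  }
  if (!is.finite(n) || n < 4) abort("`n` must be at least 4.")
  k <- r23 * (1 - r12^2 - r13^2) - 0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  denom <- (1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k
  z <- (r12 - r13) * sqrt(n) / sqrt(denom)
  structure(list(z = z, p_value = 2 * pnorm(-abs(z)),
                 r12 = r12, r13 = r13, r23 = r23, n = as.integer(n)),
            class = "pf_test")
}

#' @export
print.pf_test <- function(x, ...) {
  cat(sprintf("Pearson-Filon z = %.3f, two-sided p = %.3g (r12 = %.3f, r13 = %.3f, r23 = %.3f, n = %d)\n",
              x$z, x$p_value, x$r12, x$r13, x$r23, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pf_test <- function(x, ...) {
  tibble(statistic = x$z, p.value = x$p_value,
         r12 = x$r12, r13 = x$r13, r23 = x$r23, n = x$n)
}

#' @exportS3Method generics::glance
glance.pf_test <- function(x, ...) tidy(x)

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the F test from group means, standard deviations and sizes
#' alone, as used to check arousal matching across valence classes when only
#' summary statistics are available.
#'
#' @param means,sds numeric vectors of group means and SDs.
#' @param ns integer vector of group sizes (each at least 2), recycled if
#'   scalar.
#' @return object of class `anova_summary` with `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
#' @examples
#' anova_from_summary(c(3.98, 4.23, 4.54), c(0.49, 0.79, 1.05), 22)
anova_from_summary <- function(means, sds, ns) {
  g <- length(means)
  if (g < 2L) abort("At least 2 groups are required.")
  if (length(sds) != g) abort("`means` and `sds` must have equal length.")
  ns <- as.integer(rep_len(ns, g))
  if (any(ns < 2L)) abort("Each group needs n >= 2.")
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds < 0)) {
    abort("Summary statistics must be finite (SDs nonnegative).")
  }
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1L) * sds^2)
  df1 <- g - 1L
  df2 <- N - g
  if (ss_within == 0) abort("Zero within-group variance in all groups; F is undefined.")
  f <- (ss_between / df1) / (ss_within / df2)
  structure(list(statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE)),
            class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA (from summaries): F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anova_summary <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2, p.value = x$p_value)
}

#' @exportS3Method generics::glance
glance.anova_summary <- function(x, ...) tidy(x)
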