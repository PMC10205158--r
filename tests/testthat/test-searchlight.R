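test_that("searchlight neighbourhoods match geometry and a brute-force sort", {
  # interior center of a full unit-spacing grid with k = 7: itself + 6 face
  # neighbours (the nearest voxels at distance 1)
  mask <- array(TRUE, c(10, 10, 10))
  sl <- define_searchlights(mask, k = 7)
  ctr <- c(5, 5, 5)
  ctr_lin <- ctr[1] + (ctr[2] - 1) * 10 + (ctr[3] - 1) * 100
  ci <- match(ctr_lin, sl$centers)
  mem_lin <- sl$centers[sl$members[, ci]]
  coords <- arrayInd(mem_lin, dim(mask))
  dists <- sqrt(rowSums((coords - matrix(ctr, 7, 3, byrow = TRUE))^2))
  expect_equal(mem_lin[1], ctr_lin)          # center first
  expect_equal(sort(dists), c(0, rep(1, 6))) # face neighbours only

  # k >= mask size: every neighbourhood is the whole mask
  small <- array(FALSE, c(4, 4, 4)); small[2:3, 2:3, 2:3] <- TRUE
  sl2 <- define_searchlights(small, k = 100)
  expect_equal(sl2$k, 8)
  expect_equal(ncol(sl2$members), 8)
  expect_true(all(apply(sl2$members, 2, sort) == seq_len(8)))

  # oracle: all-pairs distance sort with lexicographic tie-break
  set.seed(14)
  mask3 <- array(runif(6 * 6 * 5) < 0.6, c(6, 6, 5))
  vs <- c(2, 2, 3)
  sl3 <- define_searchlights(mask3, k = 9, voxel_size = vs)
  idx <- which(mask3)
  coords <- (arrayInd(idx, dim(mask3)) - 1) * matrix(vs, length(idx), 3, byrow = TRUE)
  for (ci in c(1, 7, length(idx))) {
    d <- sqrt(colSums((t(coords) - coords[ci, ])^2))
    expected <- order(d, idx)[1:9]
    expect_equal(sort(sl3$members[, ci]), sort(expected))
    expect_equal(sl3$members[1, ci], ci)
  }

  # determinism across repeated calls
  expect_identical(define_searchlights(mask3, k = 9, voxel_size = vs), sl3)
})

test_that("neural similarity computes cosine structure with optional centring", {
  p <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0))
  S <- neural_similarity(p, centring = FALSE)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 0)

  # centring oracle: add a common pattern to double-centred rows; centring
  # must strip it so the cosine equals plain correlation of the clean rows
  set.seed(15)
  M <- matrix(rnorm(5 * 40), 5, 40)
  M <- M - rowMeans(M)
  M <- sweep(M, 2, colMeans(M))
  common <- rnorm(40)
  X <- sweep(M, 2, common, `+`)
  rownames(X) <- paste0("c", 1:5)
  S2 <- neural_similarity(X, centring = TRUE)
  expect_equal(unclass(S2), cor(t(M)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # zero-norm centred pattern -> flagged missing entries
  flat <- rbind(a = c(1, 1), b = c(1, 1), c = c(0, 2))
  S3 <- neural_similarity(flat, centring = FALSE)
  expect_true(all(is.finite(S3)))
})

test_that("plain and partial rank correlations match closed forms", {
  set.seed(16)
  n <- 10
  neural <- random_similarity(n)
  expect_equal(rsa_correlation(neural, neural), 1)

  model <- random_similarity(n)
  # partialling a model out of itself -> residual correlation 0
  expect_equal(rsa_correlation(neural, model, covariates = list(model)), 0)

  # single-covariate partial Spearman equals the closed form on ranks
  cov1 <- random_similarity(n)
  got <- rsa_correlation(neural, model, covariates = list(cov1))
  x <- rank(rdm_vector(neural)); y <- rank(rdm_vector(model))
  z <- rank(rdm_vector(cov1))
  expect_equal(got, partial_cor_closed(x, y, z), tolerance = 1e-10)

  # plain Spearman equals stats::cor with method = "spearman"
  expect_equal(rsa_correlation(neural, model),
               cor(as.numeric(rdm_vector(neural)), as.numeric(rdm_vector(model)),
                   method = "spearman"), tolerance = 1e-12)

  # a dissimilarity built as 1 - model is negated back, so the rank
  # correlation matches the similarity-oriented model exactly
  dis <- similarity_matrix(1 - unclass(model) + diag(n),
                           orientation = "dissimilarity", tol = 1e-6)
  expect_equal(rsa_correlation(neural, dis), rsa_correlation(neural, model),
               tolerance = 1e-10)
})

test_that("searchlight maps recover planted structure and respect rank invariance", {
  set.seed(18)
  n_cond <- 12
  mask <- array(TRUE, c(6, 6, 4))
  V <- prod(dim(mask))
  model <- similarity_matrix(cor(matrix(rnorm(30 * n_cond), 30, n_cond,
                                        dimnames = list(NULL, paste0("w", 1:n_cond)))))
  # patterns whose Gram over the whole mask equals the model exactly; with
  # k >= mask size every searchlight sees all voxels, so the map must be 1
  U <- lexrsa:::psd_scores(unclass(model))
  Q <- qr.Q(qr(matrix(rnorm(V * ncol(U)), V, ncol(U))))
  patterns <- U %*% t(Q)
  rownames(patterns) <- rownames(model)
  m1 <- searchlight_rsa(patterns, mask, model, k = V, centring = FALSE)
  expect_true(all(abs(m1[mask] - 1) < 1e-8))

  # monotone transform of the model leaves the map bit-identical
  model2 <- similarity_matrix(tanh(2 * unclass(model)) + diag(n_cond) * (1 - tanh(2)),
                              tol = 1e-6)
  diag(model2) <- 1
  m2 <- searchlight_rsa(patterns, mask, model2, k = V, centring = FALSE)
  expect_identical(as.numeric(m1), as.numeric(m2))

  # independent noise patterns (66 conditions, as in the study design)
  # -> in-mask mean rho near 0 over > 500 centers
  mask_big <- array(TRUE, c(9, 9, 8))
  V_big <- prod(dim(mask_big))
  model66 <- random_similarity(66)
  noise <- matrix(rnorm(66 * V_big), 66, V_big,
                  dimnames = list(rownames(model66), NULL))
  m0 <- searchlight_rsa(noise, mask_big, model66, k = 20)
  expect_gt(sum(is.finite(m0[mask_big])), 500)
  expect_lt(abs(mean(m0[mask_big], na.rm = TRUE)), 0.02)

  # common positive rescaling of all patterns leaves the map unchanged
  m3 <- searchlight_rsa(noise * 3.7, mask_big, model66, k = 20)
  expect_equal(as.numeric(m0), as.numeric(m3), tolerance = 1e-12)
})

test_that("group-level searchlight recovery separates planted from unrelated models", {
  # pattern-level subjects: planted affective geometry in a region, noise
  # elsewhere; the planted model should win inside the region
  cfg <- synth_config(dim = c(14, 14, 12), n_subjects = 10,
                      regions = list(signal = list(center = c(7, 7, 6),
                                                   radius_vox = 2.8,
                                                   weights = c(affective = 1))))
  ws <- generate_word_set(cfg, seed = 99)
  A <- affective_similarity(ws$ratings)
  B <- embedding_similarity(ws$embeddings)
  inside_A <- outside_A <- inside_B <- numeric(10)
  for (s in 1:10) {
    plan <- lexrsa:::synth_subject_plan(ws, list(affective = A), cfg, 99, s)
    n_in <- sum(plan$mask)
    set.seed(1000 + s)
    pat <- matrix(rnorm(66 * n_in, sd = 1), 66, n_in,
                  dimnames = list(ws$words$word, NULL))
    reg_pos <- match(which(plan$region_masks[[1]]), which(plan$mask))
    pat[, reg_pos] <- pat[, reg_pos] + plan$patterns[[1]]
    maps <- searchlight_rsa(pat, plan$mask, list(A = A, B = B), k = 60,
                            voxel_size = cfg$voxel_size)
    reg <- plan$region_masks[[1]]
    inside_A[s] <- mean(maps$A[reg], na.rm = TRUE)
    outside_A[s] <- mean(maps$A[plan$mask & !reg], na.rm = TRUE)
    inside_B[s] <- mean(maps$B[reg], na.rm = TRUE)
  }
  expect_lt(t.test(inside_A - outside_A, alternative = "greater")$p.value, 0.01)
  expect_lt(t.test(inside_A - inside_B, alternative = "greater")$p.value, 0.01)
})

test_that("Fisher z-transform maps correlations through atanh with odd symmetry", {
  x <- array(c(0, 0.5, -0.5, 1, NA, 0.9), c(3, 2, 1))
  z <- fisher_z(x)
  expect_equal(z[1, 1, 1], 0)
  expect_equal(z[2, 1, 1], 0.5493061, tolerance = 1e-6)
  expect_equal(z[3, 1, 1], -z[2, 1, 1])
  expect_true(is.na(z[1, 2, 1]))  # |rho| = 1 flagged
  expect_true(is.na(z[2, 2, 1]))
})

test_that("Gaussian smoothing is mask-renormalised and conservative", {
  set.seed(19)
  vol <- array(5, c(9, 9, 9))
  sm <- smooth_volume(vol, fwhm_mm = 4, voxel_size = c(2, 2, 2))
  expect_equal(sm, vol, tolerance = 1e-10)  # constant volume unchanged

  # interior point source: total mass conserved to 1e-6
  src <- array(0, c(15, 15, 15)); src[8, 8, 8] <- 3
  sm2 <- smooth_volume(src, fwhm_mm = 3, voxel_size = c(2, 2, 2))
  expect_equal(sum(sm2), 3, tolerance = 1e-6)

  # tiny FWHM returns the input
  rnd <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_equal(smooth_volume(rnd, fwhm_mm = 1e-6), rnd, tolerance = 1e-12)

  # values outside the mask stay missing and do not bleed in
  mask <- array(TRUE, c(9, 9, 9)); mask[1:3, , ] <- FALSE
  v2 <- array(1, c(9, 9, 9)); v2[1:3, , ] <- 1000
  sm3 <- smooth_volume(v2, fwhm_mm = 4, voxel_size = c(2, 2, 2), mask = mask)
  expect_true(all(is.na(sm3[1:3, , ])))
  expect_equal(sm3[4:9, , ], array(1, c(6, 9, 9)), tolerance = 1e-10)

  expect_error(smooth_volume(rnd, fwhm_mm = 0), "positive")
})
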