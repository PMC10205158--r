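test_that("affective similarity normalises distances onto [0, 1] as specified", {
  # identical ratings -> similarity 1; hand-computed 3-word case
  r <- tiny_ratings()
  S <- affective_similarity(r)
  # distances: sqrt(108), sqrt(27), sqrt(27); normaliser sqrt(108)
  expect_equal(S["w1", "w2"], 0)
  expect_equal(S["w1", "w3"], 0.5)
  expect_equal(S["w2", "w3"], 0.5)
  expect_equal(diag(unclass(S)), c(w1 = 1, w2 = 1, w3 = 1))

  same <- tibble::tibble(word = c("a", "b"), valence = c(3, 3),
                         dominance = c(4, 4), arousal = c(5, 5.0001))
  expect_equal(affective_similarity(same)["a", "b"], 0)  # the only pair is the max

  # random sets: most distant pair at exactly 0, all values in [0, 1]
  set.seed(42)
  for (i in 1:5) {
    rr <- tibble::tibble(word = paste0("w", 1:10),
                         valence = runif(10, 1, 7),
                         dominance = runif(10, 1, 7),
                         arousal = runif(10, 1, 7))
    Si <- affective_similarity(rr)
    expect_equal(min(Si), 0)
    expect_true(all(Si >= 0 & Si <= 1))
    expect_lt(max(abs(Si - t(Si))), 1e-12)
  }
})

test_that("affective similarity is shift-invariant and scale-equivariant", {
  set.seed(7)
  r <- tibble::tibble(word = paste0("w", 1:8),
                      valence = runif(8, 2, 6), dominance = runif(8, 2, 6),
                      arousal = runif(8, 2, 6))
  S0 <- affective_similarity(r)
  shifted <- dplyr::mutate(r, valence = valence + 0.5, dominance = dominance + 0.5,
                           arousal = arousal + 0.5)
  expect_equal(unclass(affective_similarity(shifted)), unclass(S0), tolerance = 1e-12)
  scaled <- dplyr::mutate(r, valence = 1 + (valence - 1) * 0.8,
                          dominance = 1 + (dominance - 1) * 0.8,
                          arousal = 1 + (arousal - 1) * 0.8)
  expect_equal(unclass(affective_similarity(scaled)), unclass(S0), tolerance = 1e-12)
})

test_that("affective similarity rejects degenerate input", {
  expect_error(affective_similarity(tiny_ratings()[1, ]), "At least 2")
  same <- tibble::tibble(word = c("a", "b"), valence = c(3, 3),
                         dominance = c(3, 3), arousal = c(3, 3))
  expect_error(affective_similarity(same), "normaliser")
  out_of_range <- dplyr::mutate(tiny_ratings(), valence = valence + 10)
  expect_error(affective_similarity(out_of_range), "1-7")
})

test_that("embedding cosine similarity matches hand values and flags zero rows", {
  e <- tibble::tibble(word = c("a", "b", "c"),
                      x = c(1, 1, 0), y = c(0, 1, 1))
  S <- embedding_similarity(e)
  expect_equal(S["a", "c"], 0)
  expect_equal(S["a", "b"], 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(diag(unclass(S)), c(a = 1, b = 1, c = 1))
  ident <- tibble::tibble(word = c("a", "b"), x = c(2, 4), y = c(1, 2))
  expect_equal(embedding_similarity(ident)["a", "b"], 1)

  bad <- tibble::tibble(word = c("a", "zz"), x = c(1, 0), y = c(1, 0))
  expect_error(embedding_similarity(bad), "zz")
})

test_that("phonological similarity equals 1 - normalised Levenshtein distance", {
  p <- tibble::tibble(word = c("a", "b", "c"),
                      transcription = c("kat", "rat", "kat"))
  S <- phonological_similarity(p)
  expect_equal(S["a", "b"], 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(S["a", "c"], 1)
  expect_true(all(S >= 0 & S <= 1))
  expect_error(phonological_similarity(
    tibble::tibble(word = "a", transcription = "")), "non-empty")
})

test_that("Levenshtein path agrees with brute-force recursion on short strings", {
  set.seed(3)
  alphabet <- c("a", "b", "c")
  strs <- replicate(12, paste0(sample(alphabet, sample(1:5, 1), replace = TRUE),
                               collapse = ""))
  strs <- unique(strs)
  p <- tibble::tibble(word = paste0("w", seq_along(strs)), transcription = strs)
  S <- phonological_similarity(p)
  for (i in seq_along(strs)) {
    for (j in seq_along(strs)) {
      d_brute <- lev_brute(strs[i], strs[j])
      expected <- 1 - d_brute / max(nchar(strs[i]), nchar(strs[j]))
      expect_equal(S[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("neighbourhood-density model is a dissimilarity obeying the triangle inequality", {
  p <- tibble::tibble(word = c("a", "b", "c"), transcription = c("x", "y", "z"),
                      density = c(5L, 12L, 5L))
  D <- density_dissimilarity(p)
  expect_equal(D["a", "b"], 7)
  expect_equal(D["a", "c"], 0)
  expect_identical(attr(D, "orientation"), "dissimilarity")

  set.seed(9)
  dens <- sample(0:30, 12, replace = TRUE)
  p2 <- tibble::tibble(word = paste0("w", 1:12), density = dens)
  D2 <- density_dissimilarity(p2)
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(D2[i, k], D2[i, j] + D2[j, k])
  }
})

test_that("Wu-Palmer similarity follows node depths from the root", {
  tax <- list(
    nodes = data.frame(node = c("root", "A", "B", "C", "D"),
                       parent = c(NA, "root", "A", "A", "root")),
    mapping = data.frame(word = c("b", "c", "d", "a"),
                         node = c("B", "C", "D", "A")))
  S <- wu_palmer_similarity(tax)
  expect_equal(S["b", "b"], 1)                   # a node with itself
  expect_equal(S["b", "c"], 2 * 2 / (3 + 3))     # siblings under A (depth 2)
  expect_equal(S["b", "d"], 2 * 1 / (3 + 2))     # LCS is the root
  expect_equal(S["c", "d"], 2 * 1 / (3 + 2))
  expect_true(all(S > 0 & S <= 1))

  # two depth-2 leaves whose LCS is the root -> 2 * 1 / 4
  tax2 <- list(nodes = data.frame(node = c("r", "x", "y"),
                                  parent = c(NA, "r", "r")),
               mapping = data.frame(word = c("u", "v"), node = c("x", "y")))
  expect_equal(wu_palmer_similarity(tax2)["u", "v"], 0.5)

  expect_error(wu_palmer_similarity(tax, words = c("b", "nope")), "nope")
  cyc <- list(nodes = data.frame(node = c("r", "p", "q"),
                                 parent = c(NA, "q", "p")),
              mapping = data.frame(word = "w", node = "p"))
  expect_error(wu_palmer_similarity(cyc), "Cycle|root")
})

test_that("RDM vectorisation uses row-major pair order and round-trips", {
  m <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  v <- rdm_vector(similarity_matrix(m))
  expect_equal(as.numeric(v), c(0.2, 0.3, 0.4))  # (1,2), (1,3), (2,3)
  expect_equal(length(rdm_vector(random_similarity(66))), 66 * 65 / 2)

  set.seed(5)
  for (n in c(4, 9, 17)) {
    S <- random_similarity(n)
    back <- rdm_matrix(rdm_vector(S))
    expect_equal(unclass(back), unclass(S), tolerance = 1e-12)
  }
  asym <- matrix(c(1, 0.5, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(rdm_vector(asym), "asymmetric")
})
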