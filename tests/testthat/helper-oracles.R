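# Independent oracles used across the suite.

# Naive exponential-recursion Levenshtein distance.
lev_brute <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  ra <- substr(a, 2L, nchar(a))
  rb <- substr(b, 2L, nchar(b))
  min(lev_brute(ra, b) + 1L, lev_brute(a, rb) + 1L, lev_brute(ra, rb) + cost)
}

# Closed-form first-order partial correlation.
partial_cor_closed <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# Random labelled symmetric similarity matrix with unit diagonal.
random_similarity <- function(n, labels = paste0("w", seq_len(n))) {
  S <- matrix(runif(n * n, -0.5, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  similarity_matrix(S)
}

# Small word table shared by lexical-model tests.
tiny_ratings <- function() {
  tibble::tibble(word = c("w1", "w2", "w3"),
                 valence = c(1, 7, 4), dominance = c(1, 7, 4),
                 arousal = c(1, 7, 4))
}
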