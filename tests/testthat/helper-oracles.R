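# Independent brute-force oracle for Kendall's W: midranks by explicit
# counting, rank sums and tie groups by explicit loops. Shares no code
# with the package implementation.
oracle_kendalls_w <- function(x) {
  K <- nrow(x); Tn <- ncol(x)
  R <- matrix(0, K, Tn)
  for (k in seq_len(K)) {
    for (t in seq_len(Tn)) {
      less <- 0; eq <- 0
      for (u in seq_len(Tn)) {
        if (x[k, u] < x[k, t]) less <- less + 1
        if (x[k, u] == x[k, t]) eq <- eq + 1
      }
      R[k, t] <- less + (eq + 1) / 2
    }
  }
  S <- 0
  for (t in seq_len(Tn)) {
    rt <- 0
    for (k in seq_len(K)) rt <- rt + R[k, t]
    S <- S + (rt - K * (Tn + 1) / 2)^2
  }
  C <- 0
  for (k in seq_len(K)) {
    for (v in unique(x[k, ])) {
      g <- 0
      for (u in seq_len(Tn)) if (x[k, u] == v) g <- g + 1
      C <- C + g^3 - g
    }
  }
  den <- K^2 * (Tn^3 - Tn) - K * C
  if (den <= 0) return(NaN)
  12 * S / den
}

# random KCC test instance, optionally with injected ties (quantized)
random_kcc_instance <- function(K, Tn, ties = FALSE) {
  x <- matrix(rnorm(K * Tn), K, Tn)
  if (ties) x <- round(x, sample(0:1, 1))
  x
}

# unit-norm random centroids for spin tests
random_centroids <- function(n, seed = NULL) {
  draw <- function() {
    m <- matrix(rnorm(n * 3), n, 3)
    m / sqrt(rowSums(m^2))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
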