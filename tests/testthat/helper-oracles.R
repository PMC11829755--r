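# Independent oracles used across tests; kept free of the code paths they check.

# enumeration oracle for the right-tail Fisher p of a 2x2 table:
# sum hypergeometric probabilities of all tables at least as extreme
fisher_enum_oracle <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  K <- a + c_       # property-positive genes
  m <- a + b        # cluster size
  js <- max(0, m - (n - K)):min(m, K)
  probs <- choose(K, js) * choose(n - K, m - js) / choose(n, m)
  sum(probs[js >= a])
}

# position-by-position IUPAC scanner, independent of Biostrings
iupac_scan_oracle <- function(sq, pattern) {
  amb <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  s <- strsplit(sq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p); n <- length(s)
  if (n < k) return(0L)
  hits <- 0L
  for (i in 1:(n - k + 1)) {
    ok <- TRUE
    for (j in 1:k) {
      if (!(s[i + j - 1] %in% amb[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# brute-force multivariate normal log density via solve()/determinant()
mvn_logdens_oracle <- function(y, K) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(K, y)) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    0.5 * n * log(2 * pi)
}

# brute-force expressed-gene filter: enumerate every window of length run_len
filter_oracle <- function(series, min_tpm, run_len) {
  n <- length(series)
  if (run_len > n) return(FALSE)
  any(vapply(1:(n - run_len + 1), function(i) {
    all(series[i:(i + run_len - 1)] > min_tpm)
  }, logical(1)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
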