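# Independent oracles, kept deliberately separate from the package
# implementation paths they check.

# brute-force element-sum mass oracle with independently transcribed
# IUPAC monoisotopic masses (higher precision than the package table)
oracleElementMasses <- c(
  H = 1.00782503, D = 2.01410178, C = 12.0, N = 14.00307401,
  O = 15.99491462, S = 31.97207117, P = 30.97376163,
  Na = 22.98976928, Cl = 34.96885268, F = 18.99840322,
  K = 38.96370668, Br = 78.9183371, I = 126.904473)

oracleMass <- function(text) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  total <- 0
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    n <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + oracleElementMasses[[el]] * n
  }
  total
}

# explicit leave-one-out loop (refits with lm for every held-out sample)
oracleLoocv <- function(X, y) {
  X <- as.matrix(X)
  errs <- vapply(seq_len(nrow(X)), function(i) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    pred <- sum(coef(fit) * c(1, X[i, ]))
    y[i] - pred
  }, numeric(1))
  sqrt(mean(errs^2))
}

# brute-force cosine over tolerance-matched fragments (sqrt weighting)
oracleCosine <- function(mzA, intA, mzB, intB, tolPpm = 20) {
  used <- logical(length(mzB))
  dot <- 0
  for (i in order(intA, decreasing = TRUE)) {
    err <- abs(mzA[i] - mzB) / ((mzA[i] + mzB) / 2) * 1e6
    err[used] <- Inf
    j <- which.min(err)
    if (length(j) && err[j] <= tolPpm) {
      dot <- dot + sqrt(intA[i]) * sqrt(intB[j])
      used[j] <- TRUE
    }
  }
  dot / (sqrt(sum(intA)) * sqrt(sum(intB)))
}

# random valid formula for property tests
randomFormula <- function() {
  els <- c("C", "H", "N", "O", "S")
  n <- sample(2:5, 1)
  pick <- sample(els, n)
  setNames(as.integer(sample(1:30, n, replace = TRUE)), pick)
}

# tiny Gaussian-peak run built directly (no simulator) for I/O tests
gaussianTrace <- function(rt, center, sigma, height)
  height * exp(-(rt - center)^2 / (2 * sigma^2))
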