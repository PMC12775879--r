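# Independent brute-force oracles used across the test files. These are
# deliberately written as plain nested loops over the character matrices so
# they share no code with the package implementations.

toy_t1 <- function() {
  seq_alignment(c("ACGTACGT", "ACGTACGA", "ACGAACGT", "ACGTACGT"))
}

# random alignment over A,C,G,T with optional N/- contamination
random_alignment <- function(n, L, n_pops = 1, p_ambig = 0) {
  chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
  if (p_ambig > 0) {
    k <- rbinom(1, n * L, p_ambig)
    if (k > 0) chars[sample.int(n * L, k)] <- sample(c("N", "-"), k,
                                                     replace = TRUE)
  }
  pops <- sort(rep_len(paste0("P", seq_len(n_pops)), n))
  seq_alignment(matrix(chars, nrow = n), populations = pops)
}

usable_o <- function(ch) ch %in% c("A", "C", "G", "T")

oracle_mpd <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in seq_len(ncol(mat))) {
      if (usable_o(mat[i, s]) && usable_o(mat[j, s]) &&
          mat[i, s] != mat[j, s]) d <- d + 1
    }
    tot <- tot + d
    np <- np + 1
  }
  tot / np
}

oracle_S <- function(mat) {
  s <- 0
  for (col in seq_len(ncol(mat))) {
    b <- unique(mat[usable_o(mat[, col]), col])
    if (length(b) >= 2) s <- s + 1
  }
  s
}

oracle_rarest <- function(mat) {
  vals <- c()
  for (col in seq_len(ncol(mat))) {
    x <- mat[usable_o(mat[, col]), col]
    tab <- table(x)
    if (length(tab) >= 2) vals <- c(vals, min(tab))
  }
  if (length(vals) == 0) return(c(mean = 0, variance = 0))
  c(mean = mean(vals),
    variance = sum((vals - mean(vals))^2) / length(vals))
}

oracle_hap <- function(mat) {
  keys <- c()
  for (i in seq_len(nrow(mat))) keys <- c(keys, paste(mat[i, ], collapse = ""))
  p <- as.numeric(table(keys)) / nrow(mat)
  K <- length(p)
  h <- if (nrow(mat) == 1) 0 else
    nrow(mat) / (nrow(mat) - 1) * (1 - sum(p^2))
  c(K = K, h = h)
}

oracle_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  comp <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (s in seq_len(ncol(mat))) {
      if (usable_o(mat[i, s]) && usable_o(mat[j, s])) {
        comp <- comp + 1
        if (mat[i, s] != mat[j, s]) tot <- tot + 1
      }
    }
    np <- np + 1
  }
  (tot / np) / (comp / np)
}

oracle_fst <- function(matA, matB) {
  wa <- oracle_mpd(matA)
  wb <- oracle_mpd(matB)
  tot <- 0
  for (i in seq_len(nrow(matA))) for (j in seq_len(nrow(matB))) {
    d <- 0
    for (s in seq_len(ncol(matA))) {
      if (usable_o(matA[i, s]) && usable_o(matB[j, s]) &&
          matA[i, s] != matB[j, s]) d <- d + 1
    }
    tot <- tot + d
  }
  pb <- tot / (nrow(matA) * nrow(matB))
  if (pb == 0) return(0)
  max(0, (pb - (wa + wb) / 2) / pb)
}

# exact Stirling numbers of the first kind (unsigned) by integer recurrence
oracle_stirling_row <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (m in seq_len(n - 1)) {
    row <- c(0, row) + m * c(row, 0)
  }
  row
}

# exact Ewens tail probability P(K >= k | theta) for small n
oracle_ewens_tail <- function(n, theta, k) {
  st <- oracle_stirling_row(n)
  probs <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sum(probs[k:n])
}

# multinomial logistic MLE by direct optimisation of the log-likelihood
oracle_multinom_probs <- function(X, y, x0) {
  classes <- sort(unique(y))
  K <- length(classes)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  nll <- function(beta) {
    B <- matrix(beta, nrow = K - 1, byrow = TRUE)
    eta <- cbind(0, Xd %*% t(B))
    -sum(eta[cbind(seq_along(y), match(y, classes))] -
           log(rowSums(exp(eta))))
  }
  fit <- optim(rep(0, (K - 1) * p), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  B <- matrix(fit$par, nrow = K - 1, byrow = TRUE)
  eta <- c(0, B %*% c(1, x0))
  exp(eta) / sum(exp(eta))
}
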