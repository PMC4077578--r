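# independent oracles and small fixture builders used across the suite

# brute-force minimum misclassification rate over all label permutations
# (independent of the package's assignment-based implementation)
brute_force_mcr <- function(pred, truth) {
  tl <- sort(unique(truth))
  pl <- sort(unique(pred[pred != 0L]))
  s <- max(length(tl), length(pl))
  perms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, 1L))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], Recall(v[-i])))
    out
  }
  P <- perms(seq_len(s))
  best <- Inf
  for (r in seq_len(nrow(P))) {
    # permutation row r maps pred slot q -> truth slot P[r, q]
    map <- P[r, ]
    relab <- rep(-1L, length(pred))        # -1 never matches
    for (q in seq_along(pl)) {
      t_slot <- map[q]
      if (t_slot <= length(tl)) relab[pred == pl[q]] <- tl[t_slot]
    }
    best <- min(best, mean(relab != truth))
  }
  best
}

# literal multivariate t log density (direct transcription, log-gamma form)
literal_log_mvt <- function(y, mu, sigma, nu) {
  p <- length(y)
  d <- as.numeric(t(y - mu) %*% solve(sigma) %*% (y - mu))
  lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(pi * nu) -
    0.5 * determinant(sigma, logarithm = TRUE)$modulus[1] -
    ((nu + p) / 2) * log(1 + d / nu)
}

# small well-separated two-component 1-D t mixture
tmix_1d <- function(pi1 = 0.3, mu = c(-3, 3), s = c(1, 1), nu = c(5, 5)) {
  mixture_model(pi = c(pi1, 1 - pi1), mu = matrix(mu, 2),
                sigma = list(matrix(s[1]^2), matrix(s[2]^2)),
                nu = nu, family = "t")
}

# Monte-Carlo moments of the orthant-truncated multivariate t
mc_truncated_t <- function(c0, A, kappa, n = 4e5, seed = 99) {
  set.seed(seed)
  p <- length(c0)
  L <- t(chol(A))
  w <- rgamma(n, kappa / 2, rate = kappa / 2)
  X <- c0 + (L %*% matrix(rnorm(n * p), p, n)) / rep(sqrt(w), each = p)
  keep <- colSums(X > 0) == p
  Xk <- X[, keep, drop = FALSE]
  list(P = mean(keep), mean = rowMeans(Xk),
       m2 = tcrossprod(Xk) / ncol(Xk), nkeep = ncol(Xk))
}

expect_monotone_trace <- function(trace, tol_rel = 1e-8) {
  ref <- abs(trace[length(trace)])
  expect_true(all(diff(trace) > -tol_rel * max(ref, 1)),
              label = sprintf("trace non-decreasing (min step %.3g)",
                              min(diff(trace))))
}
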