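# internal numerical helpers

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = 2 * rev(e$vectors[1L, ]^2))
}

# composite rule on (0, 1]: dyadic panels (2^-(j+1), 2^-j] with a small
# Gauss-Legendre rule each, so integrands with an endpoint boundary layer of
# any width >= 2^-J are resolved.  Used by the bivariate t cdf.
graded_rule <- function(J = 40L, m = 7L) {
  gl <- gauss_legendre(m)
  lo <- 2^-(seq_len(J))
  hi <- 2^-(seq_len(J) - 1L)
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  list(u = as.vector(outer(gl$nodes, half) + rep(mid, each = m)),
       w = as.vector(outer(gl$weights, half)))
}

.jcmix_env <- new.env(parent = emptyenv())

.graded <- function() {
  if (is.null(.jcmix_env$gr)) .jcmix_env$gr <- graded_rule()
  .jcmix_env$gr
}

# run fn() with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

# derive a child seed below 2^31 from a base seed and a stream index
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 104729) %% 2147483629)
}

# round half away from zero to `digits` decimals (display convention of the
# benchmark tables; R's round() is round-half-even)
round_half_up <- function(x, digits = 4L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Cholesky factor with one-shot ridge regularization for near-degenerate
# scale matrices: on failure add eps * mean(diag) to the diagonal once
chol_safe <- function(S, eps = 1e-8, label = "Sigma") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    S <- S + diag(eps * mean(diag(S)) + 1e-300, nrow(S))
    R <- tryCatch(chol(S), error = function(e)
      stop("matrix '", label, "' is not positive definite", call. = FALSE))
  }
  R
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
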