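#' Squared Mahalanobis distance via triangular factorization
#'
#' Computes \eqn{(y-\mu)^T \Sigma^{-1} (y-\mu)} through the Cholesky factor of
#' `sigma`; the inverse is never formed explicitly.
#'
#' @param y numeric p-vector, or an n x p matrix of row vectors.
#' @param mu location p-vector.
#' @param sigma p x p symmetric positive-definite scale matrix.
#' @return non-negative scalar (or n-vector for matrix input).
#' @examples
#' mahalanobis_sq(c(1, 1), c(0, 0), matrix(c(2, 1, 1, 2), 2))  # 2/3
#' @export
mahalanobis_sq <- function(y, mu, sigma) {
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  if (ncol(y) != length(mu) || length(mu) != nrow(sigma))
    stop("dimensions of 'y', 'mu' and 'sigma' disagree", call. = FALSE)
  R <- chol_safe(sigma, eps = 0, label = "sigma")
  z <- backsolve(R, t(y) - mu, transpose = TRUE)
  d <- colSums(z^2)
  if (nrow(y) == 1L) d[[1L]] else d
}

# log multivariate t density, vectorized over rows of Y
dmvt_ln <- function(Y, mu, sigma, nu) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  p <- ncol(Y)
  if (nu <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  R <- chol_safe(sigma)
  z <- backsolve(R, t(Y) - mu, transpose = TRUE)
  d <- colSums(z^2)
  logdet <- 2 * sum(log(diag(R)))
  lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(pi * nu) -
    logdet / 2 - ((nu + p) / 2) * log1p(d / nu)
}

#' Log density of a multivariate t component
#'
#' @param y numeric p-vector or n x p matrix.
#' @param mu location; @param sigma scale matrix; @param nu degrees of freedom.
#' @return log density value(s).
#' @export
log_mvt_pdf <- function(y, mu, sigma, nu) {
  out <- dmvt_ln(y, mu, sigma, nu)
  if (is.vector(y)) out[[1L]] else out
}

# ---------------------------------------------------------------------------
# bivariate t cdf, vectorized: Plackett identity integrated in theta =
# asin(r) from the base correlation sign(rho)*1, with dyadic graded panels at
# the pi/2 endpoint where near-diagonal (h ~ k) cases have a boundary layer.
pbvt <- function(h, k, rho, nu) {
  gr <- .graded()
  n <- max(length(h), length(k), length(rho), length(nu))
  h <- rep_len(h, n); k <- rep_len(k, n)
  rho <- pmin(pmax(rep_len(rho, n), -1), 1)
  nu <- rep_len(nu, n)
  pos <- rho >= 0
  base <- ifelse(pos, pt(pmin(h, k), nu), pmax(pt(h, nu) + pt(k, nu) - 1, 0))
  L <- ifelse(pos, pi / 2 - asin(rho), asin(rho) + pi / 2)
  sgn <- ifelse(pos, 1, -1)
  M <- length(gr$u)
  U <- outer(L, gr$u)
  TH <- sgn * (pi / 2) - sgn * U
  SN <- sin(TH)
  CS2 <- pmax(cos(TH)^2, 1e-300)
  H <- matrix(h, n, M); K <- matrix(k, n, M); NU <- matrix(nu, n, M)
  Q <- (H^2 + K^2 - 2 * SN * H * K) / (NU * CS2)
  FV <- exp(-(NU / 2) * log1p(Q)) / (2 * pi)
  I <- L * as.vector(FV %*% gr$w)
  val <- ifelse(pos, base - I, base + I)
  val[!is.finite(h) & h < 0] <- 0
  val[!is.finite(k) & k < 0] <- 0
  i1 <- !is.finite(h) & h > 0
  if (any(i1)) val[i1] <- pt(k[i1], nu[i1])
  i2 <- !is.finite(k) & k > 0
  if (any(i2)) val[i2] <- pt(h[i2], nu[i2])
  pmin(pmax(val, 0), 1)
}

# trivariate t cdf: adaptive reduction over the first coordinate with the
# (vectorized) bivariate cdf inside.  x standardized, R a correlation matrix.
ptvt <- function(x, R, nu) {
  ub <- pt(x[1L], nu)
  if (ub <= 0) return(0)
  r <- R[2:3, 1L]
  S <- R[2:3, 2:3] - tcrossprod(r)
  s12 <- sqrt(S[1L, 1L] * S[2L, 2L])
  rr <- S[1L, 2L] / s12
  f <- function(u) {
    x1 <- qt(u, nu)
    fac <- sqrt((nu + x1^2) / (nu + 1))
    pbvt((x[2L] - r[1L] * x1) / (fac * sqrt(S[1L, 1L])),
         (x[3L] - r[2L] * x1) / (fac * sqrt(S[2L, 2L])), rr, nu + 1)
  }
  stats::integrate(f, 0, ub, rel.tol = 1e-10, subdivisions = 200L,
                   stop.on.error = FALSE)$value
}

#' Central multivariate t distribution function
#'
#' \eqn{P(T \le x)} for a centered p-variate t with scale matrix `sigma` and
#' `nu` degrees of freedom (`nu` need not be an integer).  Dimensions up to 3
#' use deterministic quadrature reductions (absolute error well below `tol`);
#' higher dimensions mix randomized quasi-Monte-Carlo normal probabilities
#' over the gamma weight, with the internal randomization seeded from `seed`
#' so repeated calls are identical.
#'
#' @param x numeric p-vector of upper limits (p <= 20).
#' @param sigma p x p positive-definite scale matrix.
#' @param nu degrees of freedom (> 0).
#' @param tol requested absolute accuracy for p >= 4.
#' @param seed integer seed controlling the randomized integration (p >= 4).
#' @return the probability, with attribute `"error"` giving an error bound.
#' @examples
#' pmvt_cdf(c(0, 0), diag(2), nu = 5)  # 0.25
#' @export
pmvt_cdf <- function(x, sigma, nu, tol = 1e-4, seed = 1L) {
  p <- length(x)
  if (p > 20L) stop("dimension ", p, " unsupported (max 20)", call. = FALSE)
  if (nu <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  s <- sqrt(diag(sigma))
  z <- x / s
  R <- sigma / tcrossprod(s)
  if (p == 1L) {
    out <- pt(z, nu)
    attr(out, "error") <- 1e-14
    return(out)
  }
  if (p == 2L) {
    out <- pbvt(z[1L], z[2L], R[1L, 2L], nu)
    attr(out, "error") <- 1e-11
    return(out)
  }
  if (p == 3L) {
    out <- ptvt(z, R, nu)
    attr(out, "error") <- 1e-8
    return(out)
  }
  # p >= 4: E_W[ Phi_p(sqrt(W) z; R) ], W ~ Gamma(nu/2, nu/2)
  val <- with_local_seed(child_seed(seed, 17L), function() {
    f <- function(u) {
      vapply(u, function(ui) {
        w <- qgamma(ui, nu / 2, rate = nu / 2)
        as.numeric(mvtnorm::pmvnorm(
          upper = sqrt(w) * z, corr = R,
          algorithm = mvtnorm::GenzBretz(abseps = tol / 4, maxpts = 50000L)))
      }, 0)
    }
    stats::integrate(f, 0, 1, rel.tol = tol, abs.tol = tol / 2,
                     subdivisions = 100L, stop.on.error = FALSE)$value
  })
  out <- min(max(val, 0), 1)
  attr(out, "error") <- tol
  out
}

# ---------------------------------------------------------------------------
# unrestricted (Sahu-form) skew t: intermediate quantities shared by the
# density and the EM.  Y n x p; delta a p-vector (diagonal skewness).
# Returns Omega = Sigma + Delta^2, Lambda = I - Delta Omega^-1 Delta,
# d = Mahalanobis under Omega, and Q = Delta Omega^-1 (y - mu) per row.
skewt_parts <- function(Y, mu, sigma, delta, nu) {
  p <- ncol(Y)
  Dm <- diag(delta, p)
  Om <- sigma + Dm %*% Dm
  R <- chol_safe(Om)
  z <- backsolve(R, t(Y) - mu, transpose = TRUE)      # p x n
  d <- colSums(z^2)
  Oinv_dev <- backsolve(R, z)                          # Omega^-1 (y - mu)
  Q <- t(Oinv_dev * delta)                             # n x p
  Lam <- diag(p) - Dm %*% backsolve(R, backsolve(R, Dm, transpose = TRUE))
  Lam <- (Lam + t(Lam)) / 2
  logdet <- 2 * sum(log(diag(R)))
  list(Om = Om, Lam = Lam, d = d, Q = Q, logdet = logdet)
}

# T_p(Q_j * s_j; Lambda, df) for all rows j, with shared Lambda
tp_rows <- function(A, Lam, df) {
  p <- ncol(A)
  sd <- sqrt(diag(Lam))
  if (p == 1L) return(pt(A[, 1L] / sd, df))
  if (p == 2L) {
    rho <- Lam[1L, 2L] / (sd[1L] * sd[2L])
    return(pbvt(A[, 1L] / sd[1L], A[, 2L] / sd[2L], rho, df))
  }
  R <- Lam / tcrossprod(sd)
  if (p == 3L)
    return(vapply(seq_len(nrow(A)), function(j) ptvt(A[j, ] / sd, R, df), 0))
  vapply(seq_len(nrow(A)), function(j)
    as.numeric(pmvt_cdf(A[j, ], Lam, df)), 0)
}

# log density of the unrestricted skew t, vectorized over rows of Y:
# f(y) = 2^p t_p(y; mu, Omega, nu) T_p(q(y) s(y); 0, Lambda, nu + p)
dmvst_ln <- function(Y, mu, sigma, delta, nu) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  p <- ncol(Y)
  if (all(delta == 0)) return(dmvt_ln(Y, mu, sigma, nu))
  parts <- skewt_parts(Y, mu, sigma, delta, nu)
  lt <- lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(pi * nu) -
    parts$logdet / 2 - ((nu + p) / 2) * log1p(parts$d / nu)
  s <- sqrt((nu + p) / (nu + parts$d))
  Tp <- tp_rows(parts$Q * s, parts$Lam, nu + p)
  p * log(2) + lt + log(pmax(Tp, 1e-300))
}

#' Log density of an unrestricted (Sahu-form) skew t component
#'
#' Density \eqn{f(y) = 2^p\, t_p(y; \mu, \Omega, \nu)\,
#' T_p(q(y)\,s(y); 0, \Lambda, \nu + p)} with \eqn{\Omega = \Sigma + \Delta^2},
#' \eqn{q(y) = \Delta\Omega^{-1}(y-\mu)},
#' \eqn{s(y) = \sqrt{(\nu+p)/(\nu+d_\Omega(y))}} and
#' \eqn{\Lambda = I - \Delta\Omega^{-1}\Delta}, where \eqn{\Delta} is the
#' diagonal matrix of the skewness vector `delta`.  With `delta = 0` this is
#' the multivariate t density.
#'
#' @inheritParams log_mvt_pdf
#' @param delta skewness p-vector.
#' @return log density value(s).
#' @export
log_mvskewt_pdf <- function(y, mu, sigma, delta, nu) {
  out <- dmvst_ln(y, mu, sigma, delta, nu)
  if (is.vector(y)) out[[1L]] else out
}

# per-component log density under any supported family
component_ln <- function(Y, model, h) {
  nu <- if (model$family == "normal") 1e6 else model$nu[h]
  dmvst_ln(Y, model$mu[h, ], model$sigma[[h]], model$delta[h, ], nu)
}

#' Log density of a finite mixture
#'
#' Computed with the log-sum-exp trick over component log densities.
#'
#' @param y numeric p-vector or n x p matrix of observations.
#' @param model a [mixture_model()].
#' @param log return log density (default `TRUE`).
#' @return (log) mixture density value(s).
#' @export
dmixture <- function(y, model, log = TRUE) {
  if (is.vector(y)) {
    Y <- matrix(y, nrow = 1L)
    single <- TRUE
  } else {
    Y <- as.matrix(y)
    single <- FALSE
  }
  L <- vapply(seq_len(model$g), function(h)
    base::log(model$pi[h] + 1e-300) + component_ln(Y, model, h),
    numeric(nrow(Y)))
  if (!is.matrix(L)) L <- matrix(L, nrow = nrow(Y))
  out <- log_sum_exp_rows(L)
  if (!log) out <- exp(out)
  if (single) out[[1L]] else out
}

#' Draw from a mixture of t / skew t distributions
#'
#' Uses the latent construction: component h with probability \eqn{\pi_h};
#' \eqn{w \sim \mathrm{Gamma}(\nu/2, \nu/2)};
#' \eqn{y = \mu + \Delta|u_0| + u_1} with \eqn{(u_0, u_1)} zero-mean normal
#' with block-diagonal covariance \eqn{(I_p/w, \Sigma/w)}.
#'
#' @param n number of draws.
#' @param model a [mixture_model()].
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return list with `y` (n x p matrix) and `component` (n-vector of
#'   1-based component origins).
#' @export
rmixture <- function(n, model, seed = 1L) {
  stopifnot(n >= 1L)
  p <- model$p
  with_local_seed(seed, function() {
    comp <- sample.int(model$g, n, replace = TRUE, prob = model$pi)
    Y <- matrix(0, n, p, dimnames = list(NULL, model$marker_names))
    for (h in seq_len(model$g)) {
      idx <- which(comp == h)
      if (!length(idx)) next
      m <- length(idx)
      nu <- if (model$family == "normal") Inf else model$nu[h]
      w <- if (is.finite(nu)) rgamma(m, nu / 2, rate = nu / 2) else rep(1, m)
      U0 <- abs(matrix(rnorm(m * p), m, p)) / sqrt(w)
      L <- t(chol_safe(model$sigma[[h]]))
      U1 <- t(L %*% matrix(rnorm(m * p), p, m)) / sqrt(w)
      Y[idx, ] <- rep(model$mu[h, ], each = m) +
        U0 * rep(model$delta[h, ], each = m) + U1
    }
    list(y = Y, component = comp)
  })
}
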