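# Moments of the orthant-truncated multivariate t.
#
# S ~ t_p(c, A, kappa) truncated to the positive orthant S > 0.  Writing the
# t as a gamma mixture of normals and applying the classical truncated-normal
# boundary identities to each mixand, every boundary term integrates to a
# lower-dimensional t quantity with shifted degrees of freedom:
#   P          = T_p(c; A, kappa)
#   E[S]       = c + A g / P,
#     g_j      = c1_j T_{p-1}(sqrt((kappa-1)/(kappa+q_j)) m_j; A^(j), kappa-1)
#     c1_j     = G((kappa-1)/2)/G(kappa/2) sqrt(kappa/(4 pi A_jj))
#                  (1 + q_j/kappa)^{-(kappa-1)/2},  q_j = c_j^2/A_jj
#   E[(S-c)(S-c)^T] P = A (kappa/(kappa-2)) T_p(sqrt((kappa-2)/kappa) c; A, kappa-2)
#       - sum_j A_.j A_.j^T (c_j/A_jj) g_j
#       + sum_{j != q} A_.j (A_.q - A_.j A_jq/A_jj)^T H_jq
#     H_jq     = c2_jq T_{p-2}(sqrt((kappa-2)/(kappa+d_jq)) m_jq; A^(jq), kappa-2)
#     c2_jq    = (kappa/(4 pi)) |A_2|^{-1/2} G((kappa-2)/2)/G(kappa/2)
#                  (1 + d_jq/kappa)^{-(kappa-2)/2}
# with m_j, A^(j) (m_jq, A^(jq)) the conditional location/scale given S_j = 0
# (S_j = S_q = 0) and d_jq the bivariate Mahalanobis distance of the origin.
# First moments need kappa > 1, second moments kappa > 2.  Correctness is
# pinned by Monte-Carlo oracles in the test suite.

tmvt_moments <- function(c0, A, kappa, second = TRUE) {
  p <- length(c0)
  P <- as.numeric(pmvt_cdf(c0, A, kappa))
  dA <- diag(A)
  q <- c0^2 / dA
  lgk <- lgamma(kappa / 2)
  g <- numeric(p)
  for (j in seq_len(p)) {
    c1 <- exp(lgamma((kappa - 1) / 2) - lgk) * sqrt(kappa / (4 * pi * dA[j])) *
      (1 + q[j] / kappa)^(-(kappa - 1) / 2)
    if (p == 1L) {
      Tj <- 1
    } else {
      m <- c0[-j] - A[-j, j] * c0[j] / dA[j]
      Aj <- A[-j, -j, drop = FALSE] - tcrossprod(A[-j, j]) / dA[j]
      Tj <- as.numeric(pmvt_cdf(sqrt((kappa - 1) / (kappa + q[j])) * m,
                                Aj, kappa - 1))
    }
    g[j] <- c1 * Tj
  }
  xi <- as.vector(A %*% g)
  Psafe <- max(P, 1e-300)
  m1 <- c0 + xi / Psafe
  if (!second) return(list(P = P, mean = m1))
  t1 <- (kappa / (kappa - 2)) *
    as.numeric(pmvt_cdf(sqrt((kappa - 2) / kappa) * c0, A, kappa - 2))
  J <- A * t1
  for (j in seq_len(p))
    J <- J - tcrossprod(A[, j]) * (c0[j] / dA[j]) * g[j]
  if (p >= 2L) {
    for (j in seq_len(p)) for (qi in seq_len(p)) {
      if (qi == j) next
      jq <- c(j, qi)
      A2 <- A[jq, jq]
      det2 <- A2[1L, 1L] * A2[2L, 2L] - A2[1L, 2L]^2
      ci <- solve(A2, c0[jq])
      d2 <- sum(c0[jq] * ci)
      c2 <- (kappa / (4 * pi)) * exp(lgamma((kappa - 2) / 2) - lgk) /
        sqrt(det2) * (1 + d2 / kappa)^(-(kappa - 2) / 2)
      if (p == 2L) {
        Tjq <- 1
      } else {
        r <- setdiff(seq_len(p), jq)
        m <- c0[r] - A[r, jq, drop = FALSE] %*% ci
        Ajq <- A[r, r, drop = FALSE] -
          A[r, jq, drop = FALSE] %*% solve(A2, A[jq, r, drop = FALSE])
        Tjq <- as.numeric(pmvt_cdf(sqrt((kappa - 2) / (kappa + d2)) *
                                     as.vector(m), Ajq, kappa - 2))
      }
      J <- J + outer(A[, j], A[, qi] - A[, j] * A[j, qi] / dA[j]) * c2 * Tjq
    }
  }
  m2 <- (J + tcrossprod(c0, xi) + tcrossprod(xi, c0)) / Psafe + tcrossprod(c0)
  list(P = P, mean = m1, m2 = (m2 + t(m2)) / 2)
}

# Vectorized version over rows of centers C with a shared scale matrix A
# (p <= 2 closed over pbvt/pt; p >= 3 falls back to the scalar routine).
# Returns P (n), M1 (n x p), M2 (n x p^2, columns in column-major matrix
# order).
tmvt_moments_rows <- function(C, A, kappa) {
  n <- nrow(C)
  p <- ncol(C)
  if (p > 2L) {
    P <- numeric(n); M1 <- matrix(0, n, p); M2 <- matrix(0, n, p * p)
    for (j in seq_len(n)) {
      mo <- tmvt_moments(C[j, ], A, kappa)
      P[j] <- mo$P; M1[j, ] <- mo$mean; M2[j, ] <- as.vector(mo$m2)
    }
    return(list(P = P, M1 = M1, M2 = M2))
  }
  dA <- diag(A)
  lgk <- lgamma(kappa / 2)
  if (p == 1L) {
    a <- dA[1L]
    c0 <- C[, 1L]
    P <- pt(c0 / sqrt(a), kappa)
    q <- c0^2 / a
    g <- exp(lgamma((kappa - 1) / 2) - lgk) * sqrt(kappa / (4 * pi * a)) *
      (1 + q / kappa)^(-(kappa - 1) / 2)
    xi <- a * g
    Ps <- pmax(P, 1e-300)
    m1 <- c0 + xi / Ps
    t1 <- (kappa / (kappa - 2)) * pt(sqrt((kappa - 2) / kappa) * c0 / sqrt(a),
                                     kappa - 2)
    J <- a * t1 - a * c0 * g
    m2 <- (J + 2 * c0 * xi) / Ps + c0^2
    return(list(P = P, M1 = matrix(m1, n, 1L), M2 = matrix(m2, n, 1L)))
  }
  # p == 2
  sd <- sqrt(dA)
  rho <- A[1L, 2L] / (sd[1L] * sd[2L])
  P <- pbvt(C[, 1L] / sd[1L], C[, 2L] / sd[2L], rho, kappa)
  Ps <- pmax(P, 1e-300)
  q1 <- C[, 1L]^2 / dA[1L]
  q2 <- C[, 2L]^2 / dA[2L]
  # conditional scalars given S_j = 0
  s1 <- A[2L, 2L] - A[1L, 2L]^2 / dA[1L]
  s2 <- A[1L, 1L] - A[1L, 2L]^2 / dA[2L]
  m_1 <- C[, 2L] - A[1L, 2L] * C[, 1L] / dA[1L]
  m_2 <- C[, 1L] - A[1L, 2L] * C[, 2L] / dA[2L]
  cg <- exp(lgamma((kappa - 1) / 2) - lgk)
  g1 <- cg * sqrt(kappa / (4 * pi * dA[1L])) * (1 + q1 / kappa)^(-(kappa - 1) / 2) *
    pt(sqrt((kappa - 1) / (kappa + q1)) * m_1 / sqrt(s1), kappa - 1)
  g2 <- cg * sqrt(kappa / (4 * pi * dA[2L])) * (1 + q2 / kappa)^(-(kappa - 1) / 2) *
    pt(sqrt((kappa - 1) / (kappa + q2)) * m_2 / sqrt(s2), kappa - 1)
  xi1 <- A[1L, 1L] * g1 + A[1L, 2L] * g2
  xi2 <- A[1L, 2L] * g1 + A[2L, 2L] * g2
  M1 <- cbind(C[, 1L] + xi1 / Ps, C[, 2L] + xi2 / Ps)
  # second moments
  fac <- sqrt((kappa - 2) / kappa)
  t1 <- (kappa / (kappa - 2)) *
    pbvt(fac * C[, 1L] / sd[1L], fac * C[, 2L] / sd[2L], rho, kappa - 2)
  det2 <- dA[1L] * dA[2L] - A[1L, 2L]^2
  d2 <- (dA[2L] * C[, 1L]^2 - 2 * A[1L, 2L] * C[, 1L] * C[, 2L] +
           dA[1L] * C[, 2L]^2) / det2
  H <- (kappa / (4 * pi)) * exp(lgamma((kappa - 2) / 2) - lgk) / sqrt(det2) *
    (1 + d2 / kappa)^(-(kappa - 2) / 2)
  # J = A t1 - sum_j A_.j A_.j^T (c_j/A_jj) g_j + pair terms
  b1 <- (C[, 1L] / dA[1L]) * g1
  b2 <- (C[, 2L] / dA[2L]) * g2
  J11 <- dA[1L] * t1 - dA[1L]^2 * b1 - A[1L, 2L]^2 * b2
  J22 <- dA[2L] * t1 - A[1L, 2L]^2 * b1 - dA[2L]^2 * b2
  J12 <- A[1L, 2L] * t1 - dA[1L] * A[1L, 2L] * b1 - A[1L, 2L] * dA[2L] * b2
  # pair (j=1,q=2): outer(A_.1, A_.2 - A_.1 A_12/A_11); (j=2,q=1) symmetric
  v1 <- c(A[1L, 1L], A[1L, 2L])
  v2 <- c(A[1L, 2L], A[2L, 2L])
  w12 <- v2 - v1 * A[1L, 2L] / dA[1L]
  w21 <- v1 - v2 * A[1L, 2L] / dA[2L]
  P11 <- v1[1L] * w12[1L] + v2[1L] * w21[1L]
  P22 <- v1[2L] * w12[2L] + v2[2L] * w21[2L]
  P12 <- v1[1L] * w12[2L] + v2[1L] * w21[2L]
  P21 <- v1[2L] * w12[1L] + v2[2L] * w21[1L]
  J11 <- J11 + P11 * H
  J22 <- J22 + P22 * H
  J12 <- J12 + (P12 + P21) / 2 * H
  m2_11 <- (J11 + 2 * C[, 1L] * xi1) / Ps + C[, 1L]^2
  m2_22 <- (J22 + 2 * C[, 2L] * xi2) / Ps + C[, 2L]^2
  m2_12 <- (J12 + C[, 1L] * xi2 + C[, 2L] * xi1) / Ps + C[, 1L] * C[, 2L]
  list(P = P, M1 = M1, M2 = cbind(m2_11, m2_12, m2_12, m2_22))
}
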