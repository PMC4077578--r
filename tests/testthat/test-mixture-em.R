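test_that("k-means initialization finds separated structure, reproducibly", {
  set.seed(6)
  Y <- rbind(matrix(rnorm(600, -4, 1), ncol = 2),
             matrix(rnorm(600, 4, 1), ncol = 2))
  m <- initialize_mixture(Y, 2, "t", seed = 3)
  centers <- m$mu[order(m$mu[, 1]), ]
  expect_lt(max(abs(centers[1, ] - c(-4, -4))), 0.5)
  expect_lt(max(abs(centers[2, ] - c(4, 4))), 0.5)
  expect_identical(m, initialize_mixture(Y, 2, "t", seed = 3))
  # g = 1: sample mean and covariance
  m1 <- initialize_mixture(Y, 1, "t", seed = 1)
  expect_equal(as.vector(m1$mu), colMeans(Y), tolerance = 1e-10)
  expect_equal(m1$sigma[[1]], jcmix:::regularize_cov(cov(Y), 2),
               tolerance = 1e-10)
  expect_error(initialize_mixture(Y[1:5, ], 3, "t"), "smaller g")
})

test_that("responsibilities normalize, respect symmetry, match brute force", {
  m <- tmix_1d(pi1 = 0.5, mu = c(-2, 2))
  # cell exactly midway between symmetric components
  est <- posterior_responsibilities(matrix(0), m)
  expect_equal(as.vector(est$tau), c(0.5, 0.5), tolerance = 1e-12)
  # g = 1 trivially all one
  m1 <- mixture_model(pi = 1, mu = 0, sigma = list(matrix(1)), nu = 5,
                      family = "t")
  expect_equal(as.vector(posterior_responsibilities(matrix(c(1, 2)), m1)$tau),
               c(1, 1))
  # rows sum to one and agree with direct density ratios on random cells
  set.seed(7)
  mm <- default_template(p = 2, g = 3, family = "t", separation = 3, seed = 9)
  Y <- rmixture(100, mm, seed = 10)$y
  est2 <- posterior_responsibilities(Y, mm)
  expect_true(all(abs(rowSums(est2$tau) - 1) < 1e-10))
  direct <- sapply(1:3, function(h)
    mm$pi[h] * exp(log_mvt_pdf(Y, mm$mu[h, ], mm$sigma[[h]], mm$nu[h])))
  direct <- direct / rowSums(direct)
  expect_equal(est2$tau, direct, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(max.col(est2$tau, ties.method = "first"),
                   max.col(direct, ties.method = "first"))
})

test_that("M-step reduces to weighted Gaussian updates and honors fixed nu", {
  set.seed(8)
  m <- tmix_1d(pi1 = 0.4, mu = c(-2, 2))
  Y <- rmixture(400, m, seed = 11)$y
  est <- posterior_responsibilities(Y, m)
  lat <- est
  lat$w[] <- 1                                 # unit gamma weights
  up <- update_parameters(Y, lat, m, nu_mode = 4)
  for (h in 1:2) {
    tw <- lat$tau[, h]
    expect_equal(up$mu[h, 1], sum(tw * Y[, 1]) / sum(tw), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(up$sigma[[h]][1, 1],
                 sum(tw * (Y[, 1] - up$mu[h, 1])^2) / sum(tw),
                 tolerance = 1e-4)
    expect_equal(up$pi[h], mean(tw), tolerance = 1e-12)
  }
  expect_equal(up$nu, c(4, 4))
  # with real weights the update moves towards the generating parameters
  big <- rmixture(3e4, m, seed = 12)$y
  start <- m
  start$mu <- start$mu + 0.5
  est_b <- posterior_responsibilities(big, start)
  up_b <- update_parameters(big, est_b, start)
  expect_lt(sum(abs(up_b$mu - m$mu)), sum(abs(start$mu - m$mu)))
})

test_that("EM recovers a two-component t mixture and is monotone", {
  truth <- tmix_1d(pi1 = 0.3, mu = c(-3, 3))
  Y <- rmixture(5000, truth, seed = 4)$y
  fit <- stmix(Y, g = 2, family = "t", n_starts = 3, seed = 1)
  o <- order(fit$model$mu[, 1])
  expect_lt(max(abs(fit$model$pi[o] - c(.3, .7))), 0.02)
  expect_lt(max(abs(fit$model$mu[o, ] - c(-3, 3))), 0.1)
  expect_monotone_trace(fit$loglik_trace)
  expect_identical(fit$labels, max.col(fit$responsibilities,
                                       ties.method = "first"))
  # g = 1 on Gaussian-like data: location is the sample mean (the fitted
  # dof run to the effectively-Gaussian cap, so the robust weights flatten)
  Yg <- matrix(rnorm(5000, 2, 1))
  f1 <- stmix(Yg, g = 1, family = "t", n_starts = 1, seed = 1, tol = 1e-10)
  expect_equal(unname(f1$model$mu[1, 1]), mean(Yg), tolerance = 5e-4)
})

test_that("labels are permutation-registered quantities: relabeling is neutral", {
  m <- tmix_1d()
  Y <- rmixture(800, m, seed = 13)$y
  est <- posterior_responsibilities(Y, m)
  perm <- c(2L, 1L)
  mp <- mixture_model(pi = m$pi[perm], mu = m$mu[perm, , drop = FALSE],
                      sigma = m$sigma[perm], delta = m$delta[perm, , drop = FALSE],
                      nu = m$nu[perm], family = m$family)
  estp <- posterior_responsibilities(Y, mp)
  expect_equal(est$loglik, estp$loglik, tolerance = 1e-10)
  expect_equal(est$tau, estp$tau[, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("BIC arithmetic and parameter counting", {
  expect_equal(bic_score(-100, 5, 100), 200 + 5 * log(100), tolerance = 1e-10)
  expect_equal(bic_score(-100, 6, 100) - bic_score(-100, 5, 100), log(100))
  expect_identical(n_params(2, 3, "t"), 21L)     # 1 + 6 + 12 + 2
  expect_identical(n_params(2, 3, "skew-t"), 27L)
})

test_that("BIC selects the generating order and does not overfit", {
  tpl <- default_template(p = 2, g = 3, family = "t", separation = 4,
                          seed = 21)
  Y <- rmixture(3000, tpl, seed = 22)$y
  sel <- select_components(Y, g_range = 1:4, family = "t", n_starts = 1,
                           seed = 2, max_iter = 100)
  expect_identical(sel$g, 3L)
  expect_identical(sel$bic_by_g$g[which.min(sel$bic_by_g$bic)], 3L)
  # single blob: g = 1 wins
  Y1 <- matrix(rnorm(2000), ncol = 2)
  sel1 <- select_components(Y1, g_range = 1:3, family = "t", n_starts = 1,
                            seed = 3, max_iter = 100)
  expect_identical(sel1$g, 1L)
  # degenerate range returns that fit unconditionally
  sel2 <- select_components(Y1, g_range = 2, family = "t", n_starts = 1,
                            seed = 3, max_iter = 30)
  expect_identical(sel2$g, 2L)
})

test_that("skew-t EM recovers separated skewed components", {
  truth <- mixture_model(pi = c(.4, .6), mu = rbind(-6, 4),
                         sigma = list(matrix(1), matrix(1)),
                         delta = rbind(2, -1), nu = c(8, 8),
                         family = "skew-t")
  Y <- rmixture(1000, truth, seed = 5)$y
  fit <- stmix(Y, g = 2, family = "skew-t", n_starts = 2, seed = 2,
               max_iter = 300)
  o <- order(fit$model$mu[, 1])
  expect_lt(max(abs(fit$model$pi[o] - c(.4, .6))), 0.03)
  expect_lt(max(abs(fit$model$mu[o, 1] - c(-6, 4))), 0.5)
  expect_identical(sign(fit$model$delta[o, 1]), c(1, -1))
  expect_monotone_trace(fit$loglik_trace)
})
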