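test_that("sample models are affine instantiations of the template", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 4,
                          seed = 1)
  id <- jcmix:::identity_transform(2, 2, tpl$pi)
  expect_equal(sample_model_from_template(tpl, id)$mu, tpl$mu)
  # pure translation on one entry
  tr <- id; tr$b[1, 2] <- 2
  mu2 <- sample_model_from_template(tpl, tr)$mu
  expect_equal(mu2[1, 2], tpl$mu[1, 2] + 2)
  expect_equal(mu2[-3], tpl$mu[-3])            # column-major entry (1,2)
  # scaling arithmetic
  tr2 <- id; tr2$a[1, ] <- 1.5
  tpl2 <- tpl; tpl2$mu[1, ] <- c(2, -4)
  expect_equal(sample_model_from_template(tpl2, tr2)$mu[1, ], c(3, -6),
               ignore_attr = TRUE)
  expect_error(sample_model_from_template(tpl, within(id, a[1, 1] <- -1)),
               "positive")
})

test_that("a batch of identical samples fits identity transforms", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 3)
  Y <- rmixture(1200, tpl, seed = 14)$y
  single <- stmix(Y, g = 2, family = "t", n_starts = 2, seed = 5)
  fit <- jcm(list(s1 = Y, s2 = Y, s3 = Y), g = 2, family = "t", seed = 5,
             n_starts = 2)
  for (tr in fit$transforms) {
    expect_lt(max(abs(tr$a - 1)), 0.02)
    expect_lt(max(abs(tr$b)), 0.02)
  }
  expect_lt(abs(fit$loglik - 3 * single$loglik) / abs(3 * single$loglik),
            0.001)
  expect_monotone_trace(fit$objective_trace, tol_rel = 1e-6)
})

test_that("joint fit registers populations across a translated batch", {
  tpl <- default_template(p = 3, g = 3, family = "t", separation = 4,
                          seed = 2)
  sim <- simulate_batch(tpl, m = 4, n_per_sample = 800, sigma_a = 0,
                        sigma_b = 0.3, seed = 15)
  fit <- jcm(sim$batch, g = 3, family = "t", seed = 7, n_starts = 2)
  # match fitted template components to the truth by mean distance
  D <- as.matrix(dist(rbind(fit$template$mu, tpl$mu)))[1:3, 4:6]
  a <- jcmix:::solve_assignment(D)
  perm <- integer(3); perm[a] <- 1:3
  mcr <- vapply(seq_along(sim$labels), function(k)
    misclassification_rate(perm[fit$per_sample[[k]]$labels],
                           sim$labels[[k]]), 0)
  expect_lt(mean(mcr), 0.05)
  expect_lt(max(abs(fit$template$pi - tpl$pi[a])), 0.05)
  expect_monotone_trace(fit$objective_trace, tol_rel = 1e-6)
  # registration key: per-sample means equal a * mu + b exactly
  for (k in 1:4) {
    tr <- fit$transforms[[k]]
    mod_k <- sample_model_from_template(fit$template, tr)
    expect_equal(mod_k$mu, tr$a * fit$template$mu + tr$b, tolerance = 1e-12)
  }
})

test_that("transform estimation recovers null, shift and scale settings", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 2)
  sim <- rmixture(5000, tpl, seed = 9)
  # null transform
  tr0 <- estimate_transform(sim$y, tpl,
                            rem = list(sigma_a2 = 0.1, sigma_b2 = 0.1))
  expect_lt(max(abs(tr0$a - 1)), 0.05)
  expect_lt(max(abs(tr0$b)), 0.05)
  # +2 shift on marker 2 of component 1's cells (translation-only fit,
  # since a free scaling absorbs offsets on large-mean components)
  Y <- sim$y
  Y[sim$component == 1, 2] <- Y[sim$component == 1, 2] + 2
  trs <- estimate_transform(Y, tpl,
                            rem = list(sigma_a2 = 0.1, sigma_b2 = 0.1),
                            translation_only = TRUE)
  expect_equal(trs$b[1, 2], 2, tolerance = 0.1)
  expect_lt(max(abs(trs$b[cbind(c(1, 2, 2), c(1, 1, 2))])), 0.1)
  # component means scaled x1.5 about the origin, asserted where |mu| >= 1;
  # the translation prior is kept tight so the offset is attributed to the
  # scaling effect (a and b are separated only through their priors)
  Ysc <- sim$y + 0.5 * tpl$mu[sim$component, ]
  tra <- estimate_transform(Ysc, tpl,
                            rem = list(sigma_a2 = 0.2, sigma_b2 = 0.01))
  big <- abs(tpl$mu) >= 1
  expect_lt(max(abs(tra$a[big] - 1.5)), 0.1)
  expect_error(
    estimate_transform(marker_sample(sim$y, c("X1", "X2")), tpl),
    "mismatch")
})

test_that("shrinkage limits: zero variances give a pooled fit, large ones free it", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 4)
  sim <- simulate_batch(tpl, m = 3, n_per_sample = 400, sigma_a = 0,
                        sigma_b = 0.25, seed = 16)
  zero <- jcm(sim$batch, g = 2, family = "t", seed = 6, n_starts = 1,
              rem_fixed = list(sigma_a2 = 0, sigma_b2 = 0))
  for (tr in zero$transforms) {
    expect_equal(tr$a, matrix(1, 2, 2), ignore_attr = TRUE)
    expect_equal(tr$b, matrix(0, 2, 2), ignore_attr = TRUE)
  }
  # with one sample and wide-open variances the transformed model attains
  # essentially the unconstrained single-sample likelihood
  Y <- sim$batch$samples[[1]]$data
  free <- jcm(list(s = Y), g = 2, family = "t", seed = 6, n_starts = 2,
              rem_fixed = list(sigma_a2 = 25, sigma_b2 = 25))
  un <- stmix(Y, g = 2, family = "t", n_starts = 2, seed = 6)
  expect_lt((un$loglik - free$loglik) / abs(un$loglik), 0.002)
})

test_that("feature-by-sample export has the documented shape and content", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 5)
  sim <- simulate_batch(tpl, m = 3, n_per_sample = 300, sigma_a = 0,
                        sigma_b = 0, seed = 17)
  fit <- jcm(sim$batch, g = 2, family = "t", seed = 2, n_starts = 1,
             max_iter = 10, rem_fixed = list(sigma_a2 = 0, sigma_b2 = 0))
  fm <- export_feature_matrix(fit)
  expect_identical(dim(fm), c(24L, 3L))          # 2 * (1+2+2+2+1+2+2)
  expect_identical(colnames(fm), fit$sample_ids)
  expect_true(all(fm[grep("^a\\.", rownames(fm)), ] == 1))
  expect_true(all(fm[grep("^b\\.", rownames(fm)), ] == 0))
  expect_true(all(c("pi.1", "mu.2.M1", "sigma_diag.1.M2", "nu.2",
                    "a.1.M1", "b.2.M2") %in% rownames(fm)))
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(fm, f)
  back <- read.csv(f, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), as.matrix(fm), tolerance = 1e-12)
})

test_that("jcm methods: print, coef, logLik, predict, simulate, residuals", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 6)
  sim <- simulate_batch(tpl, m = 2, n_per_sample = 300, sigma_a = 0,
                        sigma_b = 0.2, seed = 18)
  fit <- jcm(sim$batch, g = 2, family = "t", seed = 3, n_starts = 1,
             max_iter = 20)
  expect_output(print(fit), "template")
  expect_output(print(summary(fit)), "proportions")
  cf <- coef(fit)
  expect_s3_class(cf$template, "mixture_model")
  expect_identical(attr(logLik(fit), "nobs"), 600L)
  newY <- rmixture(200, tpl, seed = 19)$y
  lab <- predict(fit, newY)
  expect_length(lab, 200)
  expect_true(all(lab %in% 1:2))
  sim2 <- simulate(fit, nsim = 2, seed = 4, n_per_sample = 50)
  expect_length(sim2$batch$samples, 2)
  res <- residuals(fit)
  expect_identical(dim(res[[1]]), dim(sim$batch$samples[[1]]$data))
})

test_that("overlay curves integrate to one and track translations", {
  tpl <- default_template(p = 2, g = 2, family = "skew-t", separation = 5,
                          seed = 7)
  dd <- overlay_density_data(list(tref = tpl), marker = "M1", grid_n = 2001)
  h <- diff(dd$x[1:2])
  expect_equal(sum(dd$density) * h, 1, tolerance = 0.01)
  # identical models give identical curves; a +2 shifted model's mode moves
  tr <- jcmix:::identity_transform(2, 2, tpl$pi)
  tr$b[] <- 2
  shifted <- sample_model_from_template(tpl, tr)
  dd2 <- overlay_density_data(list(a = tpl, b = tpl, s = shifted),
                              marker = "M1", grid_n = 4001)
  ca <- dd2[dd2$model == "a", ]; cb <- dd2[dd2$model == "b", ]
  cs <- dd2[dd2$model == "s", ]
  expect_identical(ca$density, cb$density)
  expect_equal(cs$x[which.max(cs$density)] - ca$x[which.max(ca$density)],
               2, tolerance = 0.1)
  expect_error(overlay_density_data(list(a = tpl), marker = "CD99"),
               "unknown marker")
})
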