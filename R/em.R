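# EM for single-sample mixtures of multivariate t / unrestricted skew t.

default_fit_options <- function(family = "t", g = 2L, max_iter = 500L,
                                tol = 1e-6, n_starts = 3L, seed = 1L,
                                nu_mode = "estimate",
                                min_cluster_fraction = 0.005,
                                subsample = 20000L) {
  list(family = family, g = g, max_iter = max_iter, tol = tol,
       n_starts = n_starts, seed = seed, nu_mode = nu_mode,
       min_cluster_fraction = min_cluster_fraction, subsample = subsample)
}

#' K-means based mixture initialization
#'
#' Runs k-means on a subsample of at most `subsample` cells (seeded, so the
#' initialization is reproducible) and turns the partition into mixture
#' parameters: cluster centers as locations, regularized within-cluster
#' covariances as scales, cluster fractions as proportions, `nu = 30` and
#' zero skewness.
#'
#' @param Y n x p data matrix.
#' @param g number of components; requires `n >= g * (p + 1)`.
#' @param family `"t"` or `"skew-t"`.
#' @param seed integer seed.
#' @param subsample k-means subsample cap.
#' @return a [mixture_model()].
#' @export
initialize_mixture <- function(Y, g, family = c("t", "skew-t"), seed = 1L,
                               subsample = 20000L) {
  family <- match.arg(family)
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  if (n < g * (p + 1))
    stop("too few cells (", n, ") for g = ", g,
         " components in ", p, " dimensions; try a smaller g", call. = FALSE)
  with_local_seed(seed, function() {
    idx <- if (n > subsample) sample.int(n, subsample) else seq_len(n)
    Ys <- Y[idx, , drop = FALSE]
    if (g == 1L) {
      mu <- matrix(colMeans(Ys), 1L)
      sg <- list(regularize_cov(stats::cov(Ys), p))
      pi <- 1
    } else {
      km <- suppressWarnings(stats::kmeans(Ys, centers = g, nstart = 5L,
                                           iter.max = 50L))
      mu <- km$centers
      pi <- as.numeric(km$size) / nrow(Ys)
      pooled <- regularize_cov(stats::cov(Ys), p)
      sg <- lapply(seq_len(g), function(h) {
        pts <- Ys[km$cluster == h, , drop = FALSE]
        if (nrow(pts) < p + 2L) return(pooled)
        regularize_cov(stats::cov(pts), p)
      })
    }
    delta <- matrix(0, g, p)
    if (family == "skew-t") {
      # delta = 0 is close to a stationary point of the EM map, so start
      # from the empirical marginal skewness of each cluster: delta along
      # the skew direction (scaled by the cluster sd), location pulled back
      # by the implied half-normal mean shift E|u0| ~ 0.79 at nu = 30.
      cl <- if (g == 1L) rep(1L, nrow(Ys)) else km$cluster
      for (h in seq_len(g)) {
        pts <- Ys[cl == h, , drop = FALSE]
        if (nrow(pts) < 8L) next
        sdv <- pmax(apply(pts, 2L, stats::sd), 1e-8)
        zc <- sweep(sweep(pts, 2L, colMeans(pts)), 2L, sdv, "/")
        skw <- colMeans(zc^3)
        delta[h, ] <- sign(skw) * pmax(pmin(abs(skw), 1.5), 0.1)^(1 / 3) *
          0.8 * sdv
        mu[h, ] <- mu[h, ] - 0.79 * delta[h, ]
      }
    }
    model <- mixture_model(pi = pi, mu = mu, sigma = sg,
                           delta = delta, nu = rep(30, g),
                           family = if (family == "skew-t") "skew-t" else "t",
                           marker_names = colnames(Y))
    if (family == "skew-t" && any(delta != 0)) {
      # the sign of the cluster-wise skewness is unreliable (the k-means
      # partition truncates inter-cluster tails), so pick each component's
      # sign greedily by the observed mixture log-likelihood on the
      # subsample, which sees the full density shape
      Yss <- if (nrow(Ys) > 2000L)
        Ys[sample.int(nrow(Ys), 2000L), , drop = FALSE] else Ys
      ll <- sum(dmixture(Yss, model, log = TRUE))
      for (h in seq_len(g)) {
        cand <- model
        cand$mu[h, ] <- cand$mu[h, ] + 2 * 0.79 * cand$delta[h, ]
        cand$delta[h, ] <- -cand$delta[h, ]
        ll_c <- sum(dmixture(Yss, cand, log = TRUE))
        if (ll_c > ll) { model <- cand; ll <- ll_c }
      }
    }
    model
  })
}

regularize_cov <- function(S, p, eps = 1e-6) {
  S <- (S + t(S)) / 2
  S + diag(eps * max(mean(diag(S)), 1e-8), p)
}

# ---------------------------------------------------------------------------
# E-step

#' Posterior responsibilities and latent weights
#'
#' For each cell and component computes the responsibility
#' \eqn{\tau_{jh} = \pi_h f_h(y_j) / \sum_l \pi_l f_l(y_j)}, the conditional
#' gamma weight \eqn{E[w \mid y]} (equal to \eqn{(\nu+p)/(\nu+d)} for the t
#' family), and for the skew t family the conditional first and second
#' moments of the latent positive vector `u` scaled by `w`.
#'
#' @param Y n x p data matrix.
#' @param model a [mixture_model()].
#' @return list with `tau` (n x g), `w` (n x g), `loglik`, and for the skew
#'   t family `u_mean` and `u_cov` (per-component lists of `E[w u | y]` and
#'   `E[w u u' | y]`).
#' @export
posterior_responsibilities <- function(Y, model) {
  est <- estep_mixture(as.matrix(Y), model)
  if (any(!is.finite(est$ll_cells)))
    stop("all component densities vanished at cell ",
         which(!is.finite(est$ll_cells))[1L], call. = FALSE)
  est[c("tau", "w", "loglik", "u_mean", "u_cov")]
}

estep_mixture <- function(Y, model) {
  n <- nrow(Y); p <- ncol(Y); g <- model$g
  logf <- matrix(0, n, g)
  w <- matrix(1, n, g)
  u_mean <- vector("list", g)
  u_cov <- vector("list", g)
  skew <- model$family == "skew-t"
  for (h in seq_len(g)) {
    nu <- model$nu[h]
    if (!skew) {
      R <- chol_safe(model$sigma[[h]])
      z <- backsolve(R, t(Y) - model$mu[h, ], transpose = TRUE)
      d <- colSums(z^2)
      logdet <- 2 * sum(log(diag(R)))
      logf[, h] <- lgamma((nu + p) / 2) - lgamma(nu / 2) -
        (p / 2) * log(pi * nu) - logdet / 2 - ((nu + p) / 2) * log1p(d / nu)
      w[, h] <- (nu + p) / (nu + d)
      attr(w, paste0("d", h)) <- d
    } else {
      parts <- skewt_parts(Y, model$mu[h, ], model$sigma[[h]],
                           model$delta[h, ], nu)
      s1 <- sqrt((nu + p) / (nu + parts$d))
      denomT <- pmax(tp_rows(parts$Q * s1, parts$Lam, nu + p), 1e-300)
      lt <- lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(pi * nu) -
        parts$logdet / 2 - ((nu + p) / 2) * log1p(parts$d / nu)
      logf[, h] <- p * log(2) + lt + log(denomT)
      kap <- nu + p + 2
      s2 <- sqrt(kap / (nu + parts$d))
      mo <- tmvt_moments_rows(parts$Q * s2, parts$Lam, kap)
      e1 <- ((nu + p) / (nu + parts$d)) * pmax(mo$P, 1e-300) / denomT
      srt <- 1 / s2                      # sqrt((nu+d)/(nu+p+2))
      w[, h] <- e1
      u_mean[[h]] <- e1 * (mo$M1 * srt)               # E[w u | y], n x p
      u_cov[[h]] <- e1 * (mo$M2 * srt^2)              # E[w u u' | y], n x p^2
      attr(w, paste0("d", h)) <- parts$d
    }
  }
  lp <- sweep(logf, 2L, log(pmax(model$pi, 1e-300)), "+")
  ll_cells <- log_sum_exp_rows(lp)
  tau <- exp(lp - ll_cells)
  list(tau = tau, w = w, logf = logf, ll_cells = ll_cells,
       loglik = sum(ll_cells), u_mean = u_mean, u_cov = u_cov)
}

# ---------------------------------------------------------------------------
# M-step

# solve the t-family degrees-of-freedom score equation on [0.5, 400];
# slw_sw already carries E[log w | y] = digamma((nu_old+p)/2) -
# log((nu_old+d)/2), so the score is the plain gamma-weight score
solve_nu_score <- function(slw_sw, p, nu_old) {
  # slw_sw = mean over cells (tau-weighted) of E[log w - w | y]
  f <- function(nu)
    -digamma(nu / 2) + log(nu / 2) + 1 + slw_sw
  lo <- 0.5; hi <- 400
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi)) return(nu_old)
  if (flo <= 0) return(lo)
  if (fhi >= 0) return(hi)              # effectively Gaussian
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' One M-step update of mixture parameters
#'
#' Given latent expectations from [posterior_responsibilities()], returns the
#' updated mixture.  For the t family these are the classical weighted
#' updates with the degrees of freedom solved from the digamma score
#' equation on `[0.5, 400]`; for the skew t family the updates use the
#' truncated-moment expectations, and the degrees of freedom are refined by
#' a bracketed search on the observed log-likelihood.
#'
#' @param Y n x p data matrix.
#' @param latents output of [posterior_responsibilities()].
#' @param model current [mixture_model()].
#' @param nu_mode `"estimate"` or a fixed numeric value for all components.
#' @param min_cluster_fraction components claiming fewer than this fraction
#'   of cells raise a collapse condition.
#' @return updated [mixture_model()].
#' @export
update_parameters <- function(Y, latents, model, nu_mode = "estimate",
                              min_cluster_fraction = 0.005) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y); g <- model$g
  tau <- latents$tau; w <- latents$w
  nh <- colSums(tau)
  if (any(nh < min_cluster_fraction * n)) {
    h <- which.min(nh)
    cond <- structure(class = c("component_collapse", "condition"),
                      list(message = paste0("component ", h, " collapsed (",
                                            format(nh[h]), " cells)"),
                           call = NULL))
    stop(cond)
  }
  skew <- model$family == "skew-t"
  pi_new <- nh / n
  mu <- model$mu; sig <- model$sigma; del <- model$delta; nu <- model$nu
  for (h in seq_len(g)) {
    tw <- tau[, h] * w[, h]
    sw <- sum(tw)
    if (!skew) {
      mu[h, ] <- colSums(Y * tw) / sw
      dev <- sweep(Y, 2L, mu[h, ])
      S <- crossprod(dev * tw, dev) / nh[h]
      sig[[h]] <- regularize_cov(S, p, eps = 1e-10)
    } else {
      e2 <- latents$u_mean[[h]]          # n x p, E[w u|y]
      e3 <- latents$u_cov[[h]]           # n x p^2
      A1 <- sw
      sy <- colSums(Y * tau[, h] * w[, h])
      E2 <- colSums(e2 * tau[, h])
      M3 <- matrix(colSums(e3 * tau[, h]), p, p)
      # CM mu (given current delta)
      mu[h, ] <- (sy - del[h, ] * E2) / A1
      # CM delta (given new mu, current Sigma)
      Cyu <- crossprod(Y * tau[, h], e2)               # p x p
      B <- Cyu - tcrossprod(mu[h, ], E2)
      G <- chol2inv(chol_safe(sig[[h]]))
      W <- G * M3
      rhs <- colSums(G * B)
      del[h, ] <- tryCatch(solve(W + diag(1e-12, p), rhs),
                           error = function(e) del[h, ])
      # CM Sigma (given new mu, delta)
      dev <- sweep(Y, 2L, mu[h, ])
      Syy <- crossprod(dev * tau[, h] * w[, h], dev)
      Rm <- crossprod(dev * tau[, h], e2)              # sum tau (y-mu) e2'
      Dm <- diag(del[h, ], p)
      S <- (Syy - Rm %*% Dm - Dm %*% t(Rm) + Dm %*% M3 %*% Dm) / nh[h]
      sig[[h]] <- regularize_cov((S + t(S)) / 2, p, eps = 1e-10)
    }
    if (is.numeric(nu_mode)) {
      nu[h] <- nu_mode
    } else if (!skew) {
      d <- attr(w, paste0("d", h))
      elw <- digamma((model$nu[h] + p) / 2) - log((model$nu[h] + d) / 2)
      nu[h] <- solve_nu_score(sum(tau[, h] * (elw - w[, h])) / nh[h],
                              p, model$nu[h])
    }
    # skew-t nu handled by the driver (observed-likelihood line search)
  }
  mixture_model(pi = pi_new, mu = mu, sigma = sig, delta = del, nu = nu,
                family = model$family, marker_names = model$marker_names)
}

# ECME refinement of nu for the skew-t family: bracketed observed-likelihood
# search per component, keeping the better of old/new (never decreases).
refine_nu_skewt <- function(Y, model, nu_mode) {
  if (is.numeric(nu_mode)) return(model)
  n <- nrow(Y)
  logf <- vapply(seq_len(model$g), function(h)
    log(pmax(model$pi[h], 1e-300)) + component_ln(Y, model, h),
    numeric(n))
  for (h in seq_len(model$g)) {
    obj <- function(lnu) {
      lf <- log(pmax(model$pi[h], 1e-300)) +
        dmvst_ln(Y, model$mu[h, ], model$sigma[[h]], model$delta[h, ],
                 exp(lnu))
      M <- logf; M[, h] <- lf
      sum(log_sum_exp_rows(M))
    }
    cur <- model$nu[h]
    iv <- log(c(max(0.5, cur / 3), min(400, cur * 3)))
    opt <- stats::optimize(obj, iv, maximum = TRUE, tol = 0.05)
    if (opt$objective > obj(log(cur))) {
      model$nu[h] <- exp(opt$maximum)
      logf[, h] <- log(pmax(model$pi[h], 1e-300)) +
        dmvst_ln(Y, model$mu[h, ], model$sigma[[h]], model$delta[h, ],
                 model$nu[h])
    }
  }
  model
}

# ---------------------------------------------------------------------------
# driver

run_em <- function(Y, model, opts) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  est <- NULL
  model_cur <- model
  for (iter in seq_len(opts$max_iter)) {
    model_cur <- model
    est <- estep_mixture(Y, model)
    trace <- c(trace, est$loglik)
    if (is.finite(ll_old) &&
        abs(est$loglik - ll_old) < opts$tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- est$loglik
    model <- update_parameters(Y, est, model, nu_mode = opts$nu_mode,
                               min_cluster_fraction = opts$min_cluster_fraction)
    # dof refinement is an extra (always-improving) step; running it every
    # third sweep keeps the cdf-heavy line search off the critical path
    if (model$family == "skew-t" && iter %% 3L == 0L)
      model <- refine_nu_skewt(Y, model, opts$nu_mode)
  }
  # returned model is the one the final E-step (and trace entry) was
  # computed under, so responsibilities, labels and loglik are consistent
  list(model = model_cur, est = est, trace = trace, converged = converged,
       n_iter = iter)
}

#' Fit a mixture of multivariate t or skew t distributions to one sample
#'
#' Runs EM from `n_starts` k-means initializations and keeps the run with
#' the best final log-likelihood.  If `g` is a vector, each order is fitted
#' and the fit minimizing BIC is returned (ties broken towards the smaller
#' order).  A start whose smallest component collapses is retried once from
#' a fresh initialization, and fails on a second collapse.
#'
#' @param Y n x p numeric matrix (cells x markers) or a [marker_sample()].
#' @param g integer number of components, or a vector of candidate orders
#'   (each within 1..30) to be compared by BIC.
#' @param family `"t"` or `"skew-t"`.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change falls below `tol` (default `1e-6`) or after
#'   `max_iter` iterations (default 500).
#' @param n_starts number of random starts (default 3).
#' @param seed integer seed controlling initializations.
#' @param nu_mode `"estimate"` (per-component degrees of freedom, searched in
#'   `[0.5, 400]`; 400 means effectively Gaussian) or a fixed numeric value.
#' @param min_cluster_fraction smallest admissible component weight.
#' @return an object of class `"stmix"`: list with elements `model`
#'   ([mixture_model()]), `loglik`, `loglik_trace`, `responsibilities`,
#'   `labels`, `bic`, `converged`, `n_iter`, `n`, plus the options used.
#' @examples
#' sim <- rmixture(500, mixture_model(pi = c(.5, .5),
#'                                    mu = rbind(-3, 3),
#'                                    sigma = list(matrix(1), matrix(1)),
#'                                    nu = c(5, 5), family = "t"), seed = 2)
#' fit <- stmix(sim$y, g = 2, family = "t", n_starts = 1, seed = 3)
#' fit
#' @export
stmix <- function(Y, g = 2L, family = c("t", "skew-t"), max_iter = 500L,
                  tol = 1e-6, n_starts = 3L, seed = 1L,
                  nu_mode = "estimate", min_cluster_fraction = 0.005) {
  family <- match.arg(family)
  if (inherits(Y, "marker_sample")) Y <- Y$data
  Y <- as.matrix(Y)
  g <- as.integer(g)
  if (any(g < 1L) || any(g > 30L))
    stop("'g' must lie within 1..30", call. = FALSE)
  opts <- default_fit_options(family, g, max_iter, tol, n_starts, seed,
                              nu_mode, min_cluster_fraction)
  if (length(g) > 1L) {
    fits <- vector("list", length(g))
    errs <- character(length(g))
    for (i in seq_along(g)) {
      fits[[i]] <- tryCatch(
        stmix(Y, g[i], family, max_iter, tol, n_starts, seed, nu_mode,
              min_cluster_fraction),
        error = function(e) { errs[i] <<- conditionMessage(e); NULL })
    }
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok))
      stop("no mixture order could be fitted: ",
           paste(unique(errs[nzchar(errs)]), collapse = "; "), call. = FALSE)
    bics <- vapply(fits[ok], `[[`, 0, "bic")
    # ties (within 1e-9) resolved towards the smaller order
    best <- which(bics <= min(bics) + 1e-9)[1L]
    out <- fits[ok][[best]]
    out$bic_by_g <- data.frame(g = g[ok], bic = bics)
    return(out)
  }
  best <- NULL
  n_fail <- 0L
  for (s in seq_len(n_starts)) {
    run <- NULL
    for (attempt in 0:1) {
      sd_s <- child_seed(seed, s + attempt * 101L)
      run <- tryCatch({
        model0 <- initialize_mixture(Y, g, family, seed = sd_s,
                                     subsample = opts$subsample)
        if (is.numeric(nu_mode)) model0$nu[] <- nu_mode
        if (family == "skew-t" && any(model0$delta != 0)) {
          # the cluster-wise skewness sign can be flipped by the partition
          # truncating inter-cluster tails; burn a short EM on both signs
          # and continue the better one (emEM-style)
          alt <- model0
          alt$mu <- alt$mu + 2 * 0.79 * alt$delta
          alt$delta <- -alt$delta
          burn_opts <- opts; burn_opts$max_iter <- 15L
          r1 <- run_em(Y, model0, burn_opts)
          r2 <- tryCatch(run_em(Y, alt, burn_opts),
                         component_collapse = function(e) NULL)
          pick <- if (!is.null(r2) && max(r2$trace) > max(r1$trace)) r2 else r1
          cont <- run_em(Y, pick$model, opts)
          cont$trace <- c(pick$trace, cont$trace)
          cont$n_iter <- cont$n_iter + pick$n_iter
          cont
        } else run_em(Y, model0, opts)
      }, component_collapse = function(e) NULL)
      if (!is.null(run)) break
    }
    if (is.null(run)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || max(run$trace) > max(best$trace)) best <- run
  }
  if (is.null(best))
    stop("all ", n_starts, " starts collapsed; try a smaller g", call. = FALSE)
  est <- best$est
  labels <- max.col(est$tau, ties.method = "first")
  d <- n_params(g, ncol(Y), family)
  structure(list(model = best$model, loglik = est$loglik,
                 loglik_trace = best$trace, responsibilities = est$tau,
                 labels = labels, bic = bic_score(est$loglik, d, nrow(Y)),
                 converged = best$converged, n_iter = best$n_iter,
                 n = nrow(Y), g = g, family = family, options = opts),
            class = "stmix")
}

#' Bayesian Information Criterion
#'
#' `-2 * loglik + d * log(n)`; see [n_params()] for the parameter count of
#' each mixture family.
#'
#' @param loglik maximized log-likelihood; @param d free parameter count;
#' @param n number of observations.
#' @return the BIC value (smaller is better).
#' @export
bic_score <- function(loglik, d, n) {
  stopifnot(n >= 1, d >= 1)
  -2 * loglik + d * log(n)
}

#' Select the mixture order by BIC
#'
#' Fits each order in `g_range` and returns the fit minimizing BIC; ties go
#' to the smaller order.  Equivalent to `stmix(Y, g = g_range, ...)`.
#'
#' @inheritParams stmix
#' @param g_range vector of candidate orders within 1..30.
#' @return an `"stmix"` fit with an extra `bic_by_g` table.
#' @export
select_components <- function(Y, g_range, family = c("t", "skew-t"), ...) {
  stmix(Y, g = g_range, family = match.arg(family), ...)
}

#' @export
print.stmix <- function(x, ...) {
  cat(sprintf("<stmix>: %d-component %s mixture, n = %d cells\n",
              x$g, x$family, x$n))
  cat(sprintf("  loglik %.3f | BIC %.3f | %d iterations (%s)\n", x$loglik,
              x$bic, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  pi:", paste(format(round(x$model$pi, 3)), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.stmix <- function(object, ...) {
  structure(object$loglik, df = n_params(object$g, object$model$p,
                                         object$family),
            nobs = object$n, class = "logLik")
}

#' @export
coef.stmix <- function(object, ...) object$model

#' @export
predict.stmix <- function(object, newdata = NULL, type = c("labels",
                          "responsibilities"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "labels") return(object$labels)
    return(object$responsibilities)
  }
  if (inherits(newdata, "marker_sample")) newdata <- newdata$data
  est <- estep_mixture(as.matrix(newdata), object$model)
  if (type == "labels") max.col(est$tau, ties.method = "first") else est$tau
}

#' @export
simulate.stmix <- function(object, nsim = 1L, seed = 1L, ...) {
  rmixture(nsim, object$model, seed = seed)
}
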