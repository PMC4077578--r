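# Two-level joint model: a batch-level template mixture plus per-sample
# random-effects transforms (component-wise scaling a and translation b of
# the template means, and sample-specific proportions).  Fitted by an
# expectation / conditional-maximization scheme whose monotone objective is
# the observed log-likelihood plus the log random-effects prior of (a, b)
# (the MAP objective); both traces are recorded.

identity_transform <- function(g, p, pi) {
  list(a = matrix(1, g, p), b = matrix(0, g, p), pi = pi)
}

#' Instantiate a sample-level model from a template and a transform
#'
#' Component h of the returned mixture has location
#' `a[h, ] * mu[h, ] + b[h, ]` (elementwise), proportions `transform$pi`,
#' and the template's scale, skewness and degrees of freedom unchanged.
#'
#' @param template a [mixture_model()].
#' @param transform list with `a` (g x p, positive), `b` (g x p), `pi`
#'   (g-vector summing to 1).
#' @return a [mixture_model()] for the sample.
#' @export
sample_model_from_template <- function(template, transform) {
  g <- template$g; p <- template$p
  stopifnot(all(dim(transform$a) == c(g, p)),
            all(dim(transform$b) == c(g, p)),
            length(transform$pi) == g)
  if (any(transform$a <= 0))
    stop("scaling effects 'a' must be positive", call. = FALSE)
  mixture_model(pi = transform$pi,
                mu = transform$a * template$mu + transform$b,
                sigma = template$sigma, delta = template$delta,
                nu = template$nu, family = template$family,
                marker_names = template$marker_names)
}

# log prior of the random effects under the REM
rem_logprior <- function(transforms, rem) {
  if (isTRUE(rem$fixed_zero)) return(0)
  g <- nrow(transforms[[1L]]$a)
  sa <- rep_len(sqrt(rem$sigma_a2), g)
  sb <- rep_len(sqrt(rem$sigma_b2), g)
  tot <- 0
  for (tr in transforms) {
    tot <- tot + sum(stats::dnorm(tr$a, 1, sa, log = TRUE)) +
      sum(stats::dnorm(tr$b, 0, sb, log = TRUE))
  }
  tot
}

# exact conditional-maximization (ridge / MAP) update of one sample's
# transform given the template, REM variances and E-step sums
update_transform <- function(est, Y, template, transform, rem,
                             translation_only = FALSE) {
  g <- template$g; p <- template$p
  skew <- template$family == "skew-t"
  a <- transform$a; b <- transform$b
  sa2 <- rep_len(rem$sigma_a2, g)
  sb2 <- rep_len(rem$sigma_b2, g)
  for (h in seq_len(g)) {
    tau_h <- est$tau[, h]
    sw <- sum(tau_h * est$w[, h])
    if (skew) {
      sy <- colSums(Y * (tau_h * est$w[, h])) -
        template$delta[h, ] * colSums(est$u_mean[[h]] * tau_h)
    } else {
      sy <- colSums(Y * (tau_h * est$w[, h]))
    }
    G <- chol2inv(chol_safe(template$sigma[[h]]))
    mu_h <- template$mu[h, ]
    if (translation_only) {
      # solve (sw G + diag(1/sb2)) b = G (sy - sw a mu), a fixed at 1
      A <- sw * G + diag(1 / sb2[h], p)
      rhs <- G %*% (sy - sw * (a[h, ] * mu_h))
      b[h, ] <- solve(A, rhs)
    } else {
      # theta = (a_1..a_p, b_1..b_p); X = [diag(mu), I]
      Dm <- diag(mu_h, p)
      XtGX <- rbind(cbind(Dm %*% G %*% Dm, Dm %*% G),
                    cbind(G %*% Dm, G))
      P <- diag(c(rep(1 / sa2[h], p), rep(1 / sb2[h], p)), 2 * p)
      rhs <- c(Dm %*% G %*% sy, G %*% sy) + c(rep(1 / sa2[h], p), rep(0, p))
      th <- solve(sw * XtGX + P, rhs)
      a_new <- th[seq_len(p)]
      if (all(a_new > 0)) {
        a[h, ] <- a_new
        b[h, ] <- th[p + seq_len(p)]
      } else {
        # fall back to translation-only for this component (keeps a > 0)
        A <- sw * G + diag(1 / sb2[h], p)
        a[h, ] <- 1
        b[h, ] <- solve(A, G %*% (sy - sw * mu_h))
      }
    }
  }
  pi_k <- pmax(colSums(est$tau), 1e-12)
  list(a = a, b = b, pi = pi_k / sum(pi_k))
}

# CM-1: template location/scale/skew/dof update from all samples' weighted
# sufficient statistics (GLS in template coordinates)
update_template <- function(template, batch_data, ests, transforms,
                            nu_mode, min_cluster_fraction) {
  g <- template$g; p <- template$p
  skew <- template$family == "skew-t"
  mu <- template$mu; sig <- template$sigma
  del <- template$delta; nu <- template$nu
  ntot <- sum(vapply(batch_data, nrow, 0L))
  for (h in seq_len(g)) {
    G <- chol2inv(chol_safe(sig[[h]]))
    M <- matrix(0, p, p); v <- numeric(p)
    nh <- 0
    for (k in seq_along(batch_data)) {
      est <- ests[[k]]; Y <- batch_data[[k]]; tr <- transforms[[k]]
      tau_h <- est$tau[, h]
      nh <- nh + sum(tau_h)
      sw <- sum(tau_h * est$w[, h])
      if (skew) {
        sy <- colSums((Y - rep(tr$b[h, ], each = nrow(Y))) *
                        (tau_h * est$w[, h])) -
          template$delta[h, ] * colSums(est$u_mean[[h]] * tau_h)
      } else {
        sy <- colSums((Y - rep(tr$b[h, ], each = nrow(Y))) *
                        (tau_h * est$w[, h]))
      }
      Ak <- tr$a[h, ]
      M <- M + sw * (Ak * t(Ak * G))       # diag(a) G diag(a) scaled
      v <- v + Ak * as.vector(G %*% sy)
    }
    if (nh < min_cluster_fraction * ntot) {
      cond <- structure(class = c("component_collapse", "condition"),
                        list(message = paste0("template component ", h,
                                              " collapsed"), call = NULL))
      stop(cond)
    }
    mu[h, ] <- solve(M + diag(1e-12, p), v)
    # scale (and skewness) from pooled residuals about the transformed means
    Syy <- matrix(0, p, p); Rm <- matrix(0, p, p); M3 <- matrix(0, p, p)
    sw_all <- 0
    for (k in seq_along(batch_data)) {
      est <- ests[[k]]; Y <- batch_data[[k]]; tr <- transforms[[k]]
      tau_h <- est$tau[, h]
      mu_k <- tr$a[h, ] * mu[h, ] + tr$b[h, ]
      dev <- sweep(Y, 2L, mu_k)
      Syy <- Syy + crossprod(dev * (tau_h * est$w[, h]), dev)
      if (skew) {
        Rm <- Rm + crossprod(dev * tau_h, est$u_mean[[h]])
        M3 <- M3 + matrix(colSums(est$u_cov[[h]] * tau_h), p, p)
      }
      sw_all <- sw_all + sum(tau_h)
    }
    if (skew) {
      B <- Rm
      W <- G * M3
      del[h, ] <- tryCatch(solve(W + diag(1e-12, p), colSums(G * B)),
                           error = function(e) del[h, ])
      Dm <- diag(del[h, ], p)
      S <- (Syy - Rm %*% Dm - Dm %*% t(Rm) + Dm %*% M3 %*% Dm) / sw_all
    } else {
      S <- Syy / sw_all
    }
    sig[[h]] <- regularize_cov((S + t(S)) / 2, p, eps = 1e-10)
    if (is.numeric(nu_mode)) {
      nu[h] <- nu_mode
    } else if (!skew) {
      num <- 0; den <- 0
      for (k in seq_along(batch_data)) {
        est <- ests[[k]]
        d <- attr(est$w, paste0("d", h))
        tau_h <- est$tau[, h]
        elw <- digamma((template$nu[h] + p) / 2) -
          log((template$nu[h] + d) / 2)
        num <- num + sum(tau_h * (elw - est$w[, h]))
        den <- den + sum(tau_h)
      }
      nu[h] <- solve_nu_score(num / den, p, template$nu[h])
    }
  }
  # template proportions: cell-count-weighted mean of the sample proportions
  nk <- vapply(batch_data, nrow, 0L)
  piT <- Reduce(`+`, Map(function(tr, n) tr$pi * n, transforms, nk)) / sum(nk)
  out <- mixture_model(pi = piT / sum(piT), mu = mu, sigma = sig, delta = del,
                       nu = nu, family = template$family,
                       marker_names = template$marker_names)
  out
}

# ECME dof refinement for the skew-t template over the pooled batch, with
# the other components' log terms cached so each candidate dof costs one
# component-density sweep
refine_nu_template <- function(template, batch_data, transforms, nu_mode) {
  if (is.numeric(nu_mode) || template$family != "skew-t") return(template)
  g <- template$g
  logf <- lapply(seq_along(batch_data), function(k) {
    mod_k <- sample_model_from_template(template, transforms[[k]])
    vapply(seq_len(g), function(h)
      log(pmax(mod_k$pi[h], 1e-300)) + component_ln(batch_data[[k]], mod_k, h),
      numeric(nrow(batch_data[[k]])))
  })
  comp_h <- function(k, h, nu) {
    tr <- transforms[[k]]
    log(pmax(tr$pi[h], 1e-300)) +
      dmvst_ln(batch_data[[k]],
               tr$a[h, ] * template$mu[h, ] + tr$b[h, ],
               template$sigma[[h]], template$delta[h, ], nu)
  }
  for (h in seq_len(g)) {
    obj <- function(lnu) {
      tot <- 0
      for (k in seq_along(batch_data)) {
        M <- logf[[k]]
        M[, h] <- comp_h(k, h, exp(lnu))
        tot <- tot + sum(log_sum_exp_rows(M))
      }
      tot
    }
    cur <- template$nu[h]
    cur_obj <- obj(log(cur))
    opt <- stats::optimize(obj, log(c(max(0.5, cur / 3), min(400, cur * 3))),
                           maximum = TRUE, tol = 0.05)
    if (opt$objective > cur_obj) {
      template$nu[h] <- exp(opt$maximum)
      for (k in seq_along(batch_data))
        logf[[k]][, h] <- comp_h(k, h, template$nu[h])
    }
  }
  template
}

#' Fit the joint template / random-effects model to a batch of samples
#'
#' Fits all samples of a batch simultaneously: each sample follows its own
#' g-component t or skew-t mixture whose component means are an affine
#' transform `a * mu + b` of a shared batch template, with
#' `a ~ N(1, sigma_a^2)` and `b ~ N(0, sigma_b^2)` per sample, component and
#' marker.  Scale matrices, skewness and degrees of freedom are template
#' level; proportions are sample specific.  Because every sample shares the
#' template's component indices, the fitted labels are registered: label h
#' denotes the same population in every sample.
#'
#' The fit alternates (ii) per-sample E-steps under the transformed
#' template, (iii) a template update from all samples' weighted sufficient
#' statistics in template coordinates, (iv) closed-form ridge (MAP) updates
#' of each sample's `(a, b)` and proportions, and (v) maximum-likelihood
#' updates of the random-effect variances (floored at `1e-8`), until the
#' penalized objective changes by less than `tol` (relative) or `max_iter`
#' is reached.
#'
#' @param x a [sample_batch()], a list of cells-x-markers matrices, or a
#'   single matrix (treated as a batch of one).
#' @param g number of template components.
#' @param family `"t"` or `"skew-t"`.
#' @param max_iter,tol stopping rule for the outer iteration.
#' @param seed integer seed (template initialization).
#' @param n_starts random starts for the template initialization fit.
#' @param init_subsample per-sample cap of the balanced pooled subsample
#'   used to initialize the template (default 5000).
#' @param nu_mode `"estimate"` or a fixed numeric value.
#' @param rem_fixed optional list `list(sigma_a2 =, sigma_b2 =)` freezing
#'   the random-effect variances (0 forces identity transforms, reducing
#'   the fit to a pooled single-mixture fit; with one sample this
#'   reproduces the plain mixture fit of that sample).
#' @param var_structure `"scalar"` (one variance shared over components and
#'   markers) or `"component"` (one per component).
#' @param translation_only fix all scaling effects at `a = 1`.
#' @param outlier_floor if `TRUE`, cells whose best posterior is below
#'   `1/(2g)` are labelled 0 (outlier).
#' @param min_cluster_fraction smallest admissible template component size.
#' @return an object of class `"jcm"`: list with `template`
#'   ([mixture_model()]), `transforms` (per sample: `a`, `b`, `pi`), `rem`
#'   (`sigma_a2`, `sigma_b2`), `per_sample` (responsibilities, labels,
#'   loglik), `loglik`, `objective_trace`, `loglik_trace`, `bic`,
#'   `converged`, `n_iter`, `sample_ids`, and the call options.
#' @examples
#' tpl <- default_template(p = 2, g = 2, separation = 5, seed = 1)
#' sim <- simulate_batch(tpl, m = 3, n_per_sample = 300, sigma_a = 0,
#'                       sigma_b = 0.2, seed = 2)
#' fit <- jcm(sim$batch, g = 2, seed = 3, n_starts = 1)
#' fit
#' @export
jcm <- function(x, g = 2L, family = c("t", "skew-t"), max_iter = 100L,
                tol = 1e-6, seed = 1L, n_starts = 2L, init_subsample = 5000L,
                nu_mode = "estimate", rem_fixed = NULL,
                var_structure = c("scalar", "component"),
                translation_only = FALSE, outlier_floor = FALSE,
                min_cluster_fraction = 0.005) {
  family <- match.arg(family)
  var_structure <- match.arg(var_structure)
  if (is.matrix(x)) x <- list(x)
  if (inherits(x, "sample_batch")) {
    sample_ids <- vapply(x$samples, `[[`, "", "sample_id")
    marker_names <- x$marker_names
    batch_data <- lapply(x$samples, `[[`, "data")
  } else if (is.list(x)) {
    batch_data <- lapply(x, as.matrix)
    sample_ids <- names(x) %||% paste0("sample", seq_along(x))
    if (any(!nzchar(sample_ids))) sample_ids <- paste0("sample", seq_along(x))
    marker_names <- colnames(batch_data[[1L]]) %||%
      paste0("M", seq_len(ncol(batch_data[[1L]])))
  } else stop("'x' must be a sample_batch, list of matrices, or matrix",
              call. = FALSE)
  m <- length(batch_data)
  p <- ncol(batch_data[[1L]])
  for (k in seq_len(m)) {
    if (ncol(batch_data[[k]]) != p)
      stop("sample ", sample_ids[k], " has a different number of markers",
           call. = FALSE)
    if (nrow(batch_data[[k]]) < g * (p + 1))
      stop("sample ", sample_ids[k], " has too few cells for g = ", g,
           call. = FALSE)
  }
  fixed_zero <- !is.null(rem_fixed) &&
    all(unlist(rem_fixed[c("sigma_a2", "sigma_b2")]) == 0)
  glen <- if (var_structure == "component") g else 1L
  rem <- list(
    sigma_a2 = rep_len(if (!is.null(rem_fixed)) rem_fixed$sigma_a2 else 0.04,
                       glen),
    sigma_b2 = rep_len(if (!is.null(rem_fixed)) rem_fixed$sigma_b2 else 0.04,
                       glen),
    fixed = !is.null(rem_fixed), fixed_zero = fixed_zero)

  # (i) template initialization on a balanced pooled subsample
  pool <- with_local_seed(child_seed(seed, 3L), function() {
    do.call(rbind, lapply(batch_data, function(Y) {
      if (nrow(Y) > init_subsample)
        Y[sample.int(nrow(Y), init_subsample), , drop = FALSE]
      else Y
    }))
  })
  colnames(pool) <- marker_names
  # the initialization only has to land in the right basin -- the outer ECM
  # sweeps keep improving the template -- so the skew-t init is capped
  init <- stmix(pool, g = g, family = family,
                max_iter = if (family == "skew-t") 30L else 200L, tol = tol,
                n_starts = n_starts, seed = seed, nu_mode = nu_mode,
                min_cluster_fraction = min_cluster_fraction)
  template <- init$model
  transforms <- replicate(m, identity_transform(g, p, template$pi),
                          simplify = FALSE)

  obj_trace <- numeric(0)
  ll_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  ests <- NULL
  template_cur <- template
  transforms_cur <- transforms
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # (ii) per-sample E-step under the transformed template
    template_cur <- template
    transforms_cur <- transforms
    ests <- vector("list", m)
    ll <- 0
    for (k in seq_len(m)) {
      mod_k <- sample_model_from_template(template, transforms[[k]])
      ests[[k]] <- estep_mixture(batch_data[[k]], mod_k)
      if (!is.finite(ests[[k]]$loglik))
        stop("non-finite likelihood for sample ", sample_ids[k],
             " at iteration ", iter, call. = FALSE)
      ll <- ll + ests[[k]]$loglik
    }
    obj <- ll + if (fixed_zero) 0 else rem_logprior(transforms, rem)
    obj_trace <- c(obj_trace, obj)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * abs(obj_old)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
    # (iii) CM-1: template parameters
    template <- update_template(template, batch_data, ests, transforms,
                                nu_mode, min_cluster_fraction)
    if (family == "skew-t" && iter %% 3L == 0L)
      template <- refine_nu_template(template, batch_data, transforms,
                                     nu_mode)
    # (iv) CM-2: per-sample transforms (identity when variances fixed at 0)
    if (!fixed_zero) {
      for (k in seq_len(m)) {
        transforms[[k]] <- update_transform(ests[[k]], batch_data[[k]],
                                            template, transforms[[k]], rem,
                                            translation_only)
      }
    } else {
      for (k in seq_len(m)) {
        pi_k <- pmax(colSums(ests[[k]]$tau), 1e-12)
        transforms[[k]]$pi <- pi_k / sum(pi_k)
      }
    }
    # (v) CM-3: REM variances (ML of the fitted effects, floored)
    if (!rem$fixed) {
      A <- vapply(transforms, `[[`, matrix(0, g, p), "a")
      B <- vapply(transforms, `[[`, matrix(0, g, p), "b")
      dim(A) <- c(g, p * m); dim(B) <- c(g, p * m)
      if (var_structure == "component") {
        rem$sigma_a2 <- pmax(rowMeans((A - 1)^2), 1e-8)
        rem$sigma_b2 <- pmax(rowMeans(B^2), 1e-8)
      } else {
        rem$sigma_a2 <- max(mean((A - 1)^2), 1e-8)
        rem$sigma_b2 <- max(mean(B^2), 1e-8)
      }
    }
  }
  per_sample <- vector("list", m)
  for (k in seq_len(m)) {
    tau <- ests[[k]]$tau
    labels <- max.col(tau, ties.method = "first")
    if (outlier_floor)
      labels[tau[cbind(seq_len(nrow(tau)), labels)] < 1 / (2 * g)] <- 0L
    per_sample[[k]] <- list(sample_id = sample_ids[k],
                            responsibilities = tau, labels = labels,
                            loglik = ests[[k]]$loglik)
  }
  names(per_sample) <- sample_ids
  names(transforms_cur) <- sample_ids
  ll <- sum(vapply(per_sample, `[[`, 0, "loglik"))
  ntot <- sum(vapply(batch_data, nrow, 0L))
  d <- n_params(g, p, family) + m * (g - 1) + 2L
  structure(list(template = template_cur, transforms = transforms_cur,
                 rem = rem[c("sigma_a2", "sigma_b2")],
                 per_sample = per_sample, data = batch_data, loglik = ll,
                 objective_trace = obj_trace, loglik_trace = ll_trace,
                 bic = bic_score(ll, d, ntot), converged = converged,
                 n_iter = iter, sample_ids = sample_ids, g = g, p = p,
                 family = family, marker_names = marker_names,
                 n_cells = vapply(batch_data, nrow, 0L),
                 options = list(seed = seed, tol = tol, max_iter = max_iter,
                                nu_mode = nu_mode,
                                var_structure = var_structure,
                                translation_only = translation_only,
                                outlier_floor = outlier_floor,
                                rem_fixed = rem_fixed)),
            class = "jcm")
}

#' Register a new sample against a frozen template
#'
#' Runs the per-sample steps of [jcm()] with the template held fixed:
#' iterates responsibilities and the MAP update of the sample's scaling /
#' translation effects and proportions, and returns the fitted transform,
#' registered per-cell labels, and the sample's log-likelihood under the
#' transformed template.
#'
#' @param sample a [marker_sample()] or numeric matrix with matching
#'   markers.
#' @param template a [mixture_model()].
#' @param rem list with `sigma_a2`, `sigma_b2` (random-effect variances).
#' @param max_iter,tol stopping rule.
#' @param translation_only fix `a = 1`.
#' @param outlier_floor label low-posterior cells 0.
#' @return an object of class `"sample_transform"`: `a`, `b`, `pi`,
#'   `labels`, `responsibilities`, `loglik`, `objective`, `n_iter`.
#' @export
estimate_transform <- function(sample, template,
                               rem = list(sigma_a2 = 0.04, sigma_b2 = 0.04),
                               max_iter = 50L, tol = 1e-6,
                               translation_only = FALSE,
                               outlier_floor = FALSE) {
  if (inherits(sample, "marker_sample")) {
    if (!identical(sample$marker_names, template$marker_names)) {
      extra <- setdiff(sample$marker_names, template$marker_names)
      miss <- setdiff(template$marker_names, sample$marker_names)
      stop("marker mismatch between sample and template; only in sample: [",
           paste(extra, collapse = ", "), "]; only in template: [",
           paste(miss, collapse = ", "), "]", call. = FALSE)
    }
    Y <- sample$data
  } else Y <- as.matrix(sample)
  if (ncol(Y) != template$p)
    stop("sample has ", ncol(Y), " markers but template has ", template$p,
         call. = FALSE)
  g <- template$g
  rem$fixed_zero <- all(c(rem$sigma_a2, rem$sigma_b2) == 0)
  tr <- identity_transform(g, template$p, template$pi)
  obj_old <- -Inf
  est <- NULL
  n_iter <- 0L
  for (n_iter in seq_len(max_iter)) {
    mod <- sample_model_from_template(template, tr)
    est <- estep_mixture(Y, mod)
    obj <- est$loglik +
      if (rem$fixed_zero) 0 else rem_logprior(list(tr), rem)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * abs(obj_old)) break
    obj_old <- obj
    if (!rem$fixed_zero) {
      tr <- update_transform(est, Y, template, tr, rem, translation_only)
    } else {
      pi_k <- pmax(colSums(est$tau), 1e-12)
      tr$pi <- pi_k / sum(pi_k)
    }
  }
  labels <- max.col(est$tau, ties.method = "first")
  if (outlier_floor)
    labels[est$tau[cbind(seq_len(nrow(est$tau)), labels)] < 1 / (2 * g)] <- 0L
  structure(list(a = tr$a, b = tr$b, pi = tr$pi, labels = labels,
                 responsibilities = est$tau, loglik = est$loglik,
                 objective = obj_old, n_iter = n_iter),
            class = "sample_transform")
}

#' Feature-by-sample matrix from fitted batches
#'
#' Exports a generic feature-by-sample table: one row per parameter of each
#' sample's transformed model (`pi`, `nu` per component; `mu`, `sigma_diag`,
#' `delta`, `a`, `b` per component and marker), one column per sample.
#' Row names follow `"{param}.{component}"` or
#' `"{param}.{component}.{marker}"`.
#'
#' @param fits a `"jcm"` fit or a list of `"jcm"` fits sharing `g`, markers
#'   and family.
#' @return a data.frame of features by samples.
#' @export
export_feature_matrix <- function(fits) {
  if (inherits(fits, "jcm")) fits <- list(fits)
  g <- fits[[1L]]$g; p <- fits[[1L]]$p; mk <- fits[[1L]]$marker_names
  for (f in fits) {
    if (!inherits(f, "jcm")) stop("'fits' must contain jcm fits", call. = FALSE)
    if (f$g != g || f$p != p || !identical(f$marker_names, mk))
      stop("all fits must share g, p and marker names", call. = FALSE)
  }
  feat_names <- unlist(lapply(seq_len(g), function(h) {
    c(paste0("pi.", h),
      paste0("mu.", h, ".", mk),
      paste0("sigma_diag.", h, ".", mk),
      paste0("delta.", h, ".", mk),
      paste0("nu.", h),
      paste0("a.", h, ".", mk),
      paste0("b.", h, ".", mk))
  }))
  cols <- list()
  for (f in fits) {
    tpl <- f$template
    for (k in seq_along(f$sample_ids)) {
      tr <- f$transforms[[k]]
      mod <- sample_model_from_template(tpl, tr)
      v <- unlist(lapply(seq_len(g), function(h) {
        c(mod$pi[h], mod$mu[h, ], diag(mod$sigma[[h]]), mod$delta[h, ],
          mod$nu[h], tr$a[h, ], tr$b[h, ])
      }))
      cols[[f$sample_ids[k]]] <- v
    }
  }
  out <- as.data.frame(cols, check.names = FALSE)
  rownames(out) <- feat_names
  out
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.jcm <- function(x, ...) {
  cat(sprintf("<jcm>: %d-component %s template over %d samples (%d markers)\n",
              x$g, x$family, length(x$sample_ids), x$p))
  cat(sprintf("  loglik %.3f | BIC %.3f | %d iterations (%s)\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  REM variances: sigma_a2 = %s, sigma_b2 = %s\n",
              paste(format(signif(x$rem$sigma_a2, 3)), collapse = " "),
              paste(format(signif(x$rem$sigma_b2, 3)), collapse = " ")))
  invisible(x)
}

#' @export
summary.jcm <- function(object, ...) {
  m <- length(object$sample_ids)
  tab <- data.frame(
    sample = object$sample_ids,
    n = object$n_cells,
    loglik = vapply(object$per_sample, `[[`, 0, "loglik"),
    mean_abs_a1 = vapply(object$transforms, function(tr) mean(abs(tr$a - 1)), 0),
    mean_abs_b = vapply(object$transforms, function(tr) mean(abs(tr$b)), 0),
    row.names = NULL)
  out <- list(fit = object, samples = tab,
              proportions = t(vapply(object$transforms, `[[`,
                                     numeric(object$g), "pi")))
  class(out) <- "summary.jcm"
  out
}

#' @export
print.summary.jcm <- function(x, ...) {
  print(x$fit)
  cat("\nPer-sample fit and transform magnitude:\n")
  print(x$samples, digits = 4)
  cat("\nSample-specific proportions:\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' @export
coef.jcm <- function(object, ...) {
  list(template = object$template, transforms = object$transforms,
       rem = object$rem)
}

#' @export
logLik.jcm <- function(object, ...) {
  d <- n_params(object$g, object$p, object$family) +
    length(object$sample_ids) * (object$g - 1) + 2L
  structure(object$loglik, df = d, nobs = sum(object$n_cells),
            class = "logLik")
}

#' @export
predict.jcm <- function(object, newdata, type = c("labels", "transform",
                                                  "responsibilities"), ...) {
  type <- match.arg(type)
  tr <- estimate_transform(newdata, object$template,
                           rem = object$rem, ...)
  switch(type, labels = tr$labels, transform = tr,
         responsibilities = tr$responsibilities)
}

#' @export
simulate.jcm <- function(object, nsim = 1L, seed = 1L,
                         n_per_sample = 1000L, ...) {
  simulate_batch(object$template, m = nsim, n_per_sample = n_per_sample,
                 sigma_a = sqrt(mean(object$rem$sigma_a2)),
                 sigma_b = sqrt(mean(object$rem$sigma_b2)), seed = seed)
}

#' @export
residuals.jcm <- function(object, ...) {
  # per-cell deviation from the transformed mean of the assigned component
  out <- vector("list", length(object$sample_ids))
  names(out) <- object$sample_ids
  for (k in seq_along(out)) {
    tr <- object$transforms[[k]]
    mu_k <- tr$a * object$template$mu + tr$b
    lab <- object$per_sample[[k]]$labels
    lab[lab == 0L] <- NA_integer_
    out[[k]] <- object$data[[k]] - mu_k[lab, , drop = FALSE]
  }
  out
}
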