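# Scoring clusterings against reference labels, comparing mixtures, and
# classifying new samples against class templates.

# Hungarian algorithm (successive shortest augmenting paths with potentials)
# for the square/rectangular min-cost assignment of rows to columns.
# cost: n x m with n <= m.  Returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)                     # p[j+1]: row matched to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else if (j > 0L) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Misclassification rate under the best label permutation
#'
#' The error rate of a clustering against reference labels, minimized over
#' all one-to-one relabelings of the predicted clusters, computed exactly by
#' optimal assignment on the confusion matrix (equivalent to the full
#' permutation search).  Predicted label 0 denotes outlier/unassigned cells
#' and always counts as an error; predicted clusters in excess of the
#' reference classes remain unmatched and count entirely as errors.
#'
#' @param pred integer vector of predicted cluster labels (0 = outlier).
#' @param truth integer (or factor) vector of reference class labels.
#' @return the misclassification proportion in `[0, 1]`.
#' @examples
#' misclassification_rate(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 0
#' misclassification_rate(c(1, 1, 1, 2), c(1, 1, 2, 2))  # 0.25
#' @export
misclassification_rate <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have equal length", call. = FALSE)
  n <- length(truth)
  keep <- pred != 0L
  tl <- sort(unique(truth))
  pl <- sort(unique(pred[keep]))
  if (!length(pl)) return(1)
  N <- matrix(0, length(pl), length(tl))
  tp <- table(factor(pred[keep], levels = pl), factor(truth[keep], levels = tl))
  N[] <- tp
  s <- max(nrow(N), ncol(N))
  C <- matrix(0, s, s)
  C[seq_len(nrow(N)), seq_len(ncol(N))] <- N
  best <- -C                      # maximize matches = minimize negative
  assign <- solve_assignment(best)
  matched <- sum(C[cbind(seq_len(s), assign)])
  1 - matched / n
}

#' Size-weighted best-match F-measure of a clustering
#'
#' For each reference class c, `F(c)` is the best harmonic mean of precision
#' and recall over all predicted clusters q,
#' `2 |c & q| / (|c| + |q|)`; the returned value is the class-size-weighted
#' average of the `F(c)`.
#'
#' @inheritParams misclassification_rate
#' @return a proportion in `[0, 1]`; 1 iff the clustering equals the truth
#'   up to relabeling.
#' @export
f_measure <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have equal length", call. = FALSE)
  n <- length(truth)
  N <- table(truth, pred)
  csz <- rowSums(N)
  qsz <- colSums(N)
  Fc <- vapply(seq_len(nrow(N)), function(i)
    max(2 * N[i, ] / (csz[i] + qsz)), 0)
  sum(csz / n * Fc)
}

#' Monte Carlo Kullback-Leibler divergence between two mixtures
#'
#' Estimates `E_p[log p - log q]` from `n_mc` draws of `model_p`, clipped at
#' zero from below.  The standard error of the (unclipped) estimate is
#' attached as attribute `"se"`.
#'
#' @param model_p,model_q [mixture_model()] objects of equal dimension.
#' @param n_mc number of Monte Carlo draws.
#' @param seed integer seed.
#' @return non-negative estimate with attribute `"se"`.
#' @export
kl_divergence_mc <- function(model_p, model_q, n_mc = 1e5L, seed = 1L) {
  if (model_p$p != model_q$p)
    stop("models must share the dimension", call. = FALSE)
  draw <- rmixture(n_mc, model_p, seed = seed)
  lp <- dmixture(draw$y, model_p, log = TRUE)
  lq <- dmixture(draw$y, model_q, log = TRUE)
  if (any(!is.finite(lq)))
    stop("model_q has vanishing density at sampled points; regularize its ",
         "scale matrices or enlarge its degrees of freedom", call. = FALSE)
  d <- lp - lq
  est <- mean(d)
  structure(max(est, 0), se = stats::sd(d) / sqrt(n_mc))
}

#' Classify a sample against fitted class templates
#'
#' Registers the sample against each class template (via
#' [estimate_transform()]) and scores it by the transform-adjusted mean
#' log-likelihood per cell (default), or by the symmetric Monte Carlo
#' Kullback-Leibler divergence between the sample's own mixture fit and the
#' template.  The best class is returned; ties go to the lexicographically
#' smallest class id.
#'
#' @param sample a [marker_sample()] or matrix.
#' @param class_templates named list; each element either a
#'   [mixture_model()] or a list with elements `template` and `rem`.
#' @param method `"loglik"` (default, deterministic) or `"kl"`.
#' @param n_mc,seed Monte Carlo settings for `method = "kl"`.
#' @param ... passed to [estimate_transform()].
#' @return list with `class_id`, `scores` (named; higher is better for
#'   `"loglik"`, lower for `"kl"`), and `method`.
#' @export
classify_sample <- function(sample, class_templates,
                            method = c("loglik", "kl"),
                            n_mc = 2e4L, seed = 1L, ...) {
  method <- match.arg(method)
  if (!length(class_templates)) stop("no class templates", call. = FALSE)
  ids <- names(class_templates)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'class_templates' must be a named list", call. = FALSE)
  Y <- if (inherits(sample, "marker_sample")) sample$data else as.matrix(sample)
  scores <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    ct <- class_templates[[i]]
    tpl <- if (inherits(ct, "mixture_model")) ct else ct$template
    rem <- if (inherits(ct, "mixture_model") || is.null(ct$rem))
      list(sigma_a2 = 0.04, sigma_b2 = 0.04) else ct$rem
    if (method == "loglik") {
      tr <- estimate_transform(sample, tpl, rem = rem, ...)
      scores[i] <- tr$loglik / nrow(Y)
    } else {
      own <- stmix(Y, g = tpl$g,
                   family = if (tpl$family == "skew-t") "skew-t" else "t",
                   n_starts = 1L, seed = seed)
      k1 <- kl_divergence_mc(own$model, tpl, n_mc = n_mc,
                             seed = child_seed(seed, 7L))
      k2 <- kl_divergence_mc(tpl, own$model, n_mc = n_mc,
                             seed = child_seed(seed, 8L))
      scores[i] <- as.numeric(k1) + as.numeric(k2)
    }
  }
  ord <- order(if (method == "loglik") -scores else scores, ids)
  list(class_id = ids[ord[1L]], scores = scores, method = method)
}

#' Aggregate per-sample misclassification rates by method
#'
#' @param table data.frame or named list: one numeric vector of per-sample
#'   MCRs per method (equal lengths).
#' @return data.frame with one row per method: `amcr` (arithmetic mean) and
#'   `median`, both rounded half-up to 4 decimals for display.
#' @export
summarize_mcr_table <- function(table) {
  if (is.data.frame(table)) table <- as.list(table)
  if (!length(table)) stop("empty table", call. = FALSE)
  lens <- vapply(table, length, 0L)
  if (any(lens == 0L)) stop("empty MCR sequence", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("per-method sequences must have equal length", call. = FALSE)
  data.frame(method = names(table),
             amcr = round_half_up(vapply(table, mean, 0), 4L),
             median = round_half_up(vapply(table, stats::median, 0), 4L),
             row.names = NULL)
}

#' Published benchmark misclassification rates (flowCAP-I DLBCL subset)
#'
#' Per-sample misclassification rates, against manual expert gates, of
#' several automated gating methods on the 16 manually analyzed samples of
#' the flowCAP-I diffuse large B-cell lymphoma benchmark, as published with
#' the JCM method.  Methods: `jcm` (joint template fit), `hdpgmm`
#' (hierarchical Dirichlet process Gaussian mixture), `flame`
#' (FLAME with post-hoc meta-clustering alignment), and per-sample (`_i`) /
#' pooled (`_p`) variants of FLAME, flowClust and SWIFT.
#'
#' @return data.frame with column `sample` plus one numeric column per
#'   method.
#' @export
dlbcl_benchmark <- function() {
  path <- system.file("extdata", "dlbcl_benchmark_mcr.csv", package = "jcmix",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
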