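#' Construct a single-sample expression matrix
#'
#' A marker sample holds one flow cytometry sample as a numeric matrix of
#' cells (rows) by markers (columns), on an already compensated and
#' scale-transformed intensity scale, together with identifying metadata.
#'
#' @param data numeric matrix, cells x markers; all values finite.
#' @param marker_names character vector of unique marker names, one per
#'   column.  Defaults to the column names of `data`.
#' @param sample_id sample identifier.
#' @param class_label optional class (batch) label the sample belongs to.
#' @param condition optional condition annotation (e.g. a time point).
#' @return an object of class `"marker_sample"`: a list with elements
#'   `data`, `marker_names`, `sample_id`, `class_label`, `condition`.
#' @examples
#' s <- marker_sample(matrix(rnorm(200), 50, 4),
#'                    marker_names = c("CD4", "CD45RA", "SLP76", "ZAP70"))
#' dim(s$data)
#' @export
marker_sample <- function(data, marker_names = colnames(data),
                          sample_id = "sample1", class_label = NULL,
                          condition = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(marker_names))
    marker_names <- paste0("M", seq_len(ncol(data)))
  marker_names <- as.character(marker_names)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("'data' must have at least one cell and one marker", call. = FALSE)
  if (!all(is.finite(data)))
    stop("'data' contains non-finite values", call. = FALSE)
  if (length(marker_names) != ncol(data))
    stop("length of 'marker_names' must equal ncol(data)", call. = FALSE)
  if (anyDuplicated(marker_names))
    stop("'marker_names' must be unique", call. = FALSE)
  colnames(data) <- marker_names
  structure(list(data = data, marker_names = marker_names,
                 sample_id = as.character(sample_id),
                 class_label = class_label, condition = condition),
            class = "marker_sample")
}

#' @export
print.marker_sample <- function(x, ...) {
  cat(sprintf("<marker_sample '%s'>: %d cells x %d markers (%s)\n",
              x$sample_id, nrow(x$data), ncol(x$data),
              paste(x$marker_names, collapse = ", ")))
  invisible(x)
}

#' Construct a batch of samples sharing a marker panel
#'
#' @param samples list of [marker_sample()] objects with identical marker
#'   names in identical order.
#' @param class_id identifier of the batch (class).
#' @return an object of class `"sample_batch"`.
#' @export
sample_batch <- function(samples, class_id = "batch1") {
  if (inherits(samples, "marker_sample")) samples <- list(samples)
  if (length(samples) < 1L)
    stop("a batch needs at least one sample", call. = FALSE)
  ok <- vapply(samples, inherits, TRUE, what = "marker_sample")
  if (!all(ok)) stop("all elements must be marker_sample objects", call. = FALSE)
  mk <- samples[[1L]]$marker_names
  same <- vapply(samples, function(s) identical(s$marker_names, mk), TRUE)
  if (!all(same))
    stop("all samples must share identical marker names in identical order",
         call. = FALSE)
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    ids <- make.unique(ids)
  for (i in seq_along(samples)) samples[[i]]$sample_id <- ids[i]
  structure(list(class_id = as.character(class_id), samples = samples,
                 marker_names = mk),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  n <- vapply(x$samples, function(s) nrow(s$data), 0L)
  cat(sprintf("<sample_batch '%s'>: %d samples, %d markers, %d-%d cells/sample\n",
              x$class_id, length(x$samples), length(x$marker_names),
              min(n), max(n)))
  invisible(x)
}

#' Construct a finite mixture of multivariate t / skew t components
#'
#' The component density is the multivariate normal (large degrees of
#' freedom), t, or the unrestricted (Sahu-form) skew t with diagonal skewness
#' matrix.  Proportions must sum to one; each scale matrix must be symmetric
#' positive definite.
#'
#' @param pi numeric vector of mixing proportions (length g, sums to 1).
#' @param mu g x p matrix of component locations (or p-vector when g = 1).
#' @param sigma list of g p x p scale matrices.
#' @param delta g x p matrix of skewness parameters (all zero for the normal
#'   and t families).
#' @param nu numeric vector of g degrees of freedom (> 0; ignored for the
#'   normal family).
#' @param family one of `"normal"`, `"t"`, `"skew-t"`.
#' @param marker_names optional character vector of p marker names.
#' @return an object of class `"mixture_model"`.
#' @examples
#' m <- mixture_model(pi = c(.4, .6), mu = rbind(c(-2, 0), c(2, 1)),
#'                    sigma = list(diag(2), diag(2)), nu = c(5, 10),
#'                    family = "t")
#' m
#' @export
mixture_model <- function(pi, mu, sigma, delta = NULL, nu = NULL,
                          family = c("t", "skew-t", "normal"),
                          marker_names = NULL) {
  family <- match.arg(family)
  pi <- as.numeric(pi)
  g <- length(pi)
  if (is.vector(mu)) mu <- matrix(mu, nrow = g)
  mu <- as.matrix(mu)
  p <- ncol(mu)
  if (!is.list(sigma)) sigma <- list(sigma)
  if (is.null(delta)) delta <- matrix(0, g, p)
  if (is.vector(delta)) delta <- matrix(delta, nrow = g)
  delta <- as.matrix(delta)
  if (is.null(nu)) nu <- rep(30, g)
  nu <- rep_len(as.numeric(nu), g)
  if (is.null(marker_names)) {
    marker_names <- colnames(mu) %||% paste0("M", seq_len(p))
  }
  dimnames(mu) <- list(NULL, as.character(marker_names))
  dimnames(delta) <- list(NULL, as.character(marker_names))
  sigma <- lapply(sigma, function(S) { dimnames(S) <- NULL; S })
  nu <- unname(nu); pi <- unname(pi)
  model <- structure(list(family = family, g = g, p = p, pi = pi, mu = mu,
                          sigma = sigma, delta = delta, nu = nu,
                          marker_names = as.character(marker_names)),
                     class = "mixture_model")
  validate_mixture_model(model)
  model
}

validate_mixture_model <- function(model) {
  with(model, {
    if (g < 1L) stop("mixture needs at least one component", call. = FALSE)
    if (abs(sum(pi) - 1) > 1e-10)
      stop("mixing proportions must sum to 1 (got ", format(sum(pi)), ")",
           call. = FALSE)
    if (any(pi < -1e-12) || any(pi > 1 + 1e-12))
      stop("mixing proportions must lie in [0, 1]", call. = FALSE)
    if (nrow(mu) != g || nrow(delta) != g || length(sigma) != g)
      stop("component parameter dimensions disagree with g", call. = FALSE)
    if (ncol(delta) != p)
      stop("'delta' must have p columns", call. = FALSE)
    if (length(marker_names) != p)
      stop("'marker_names' must have length p", call. = FALSE)
    for (h in seq_len(g)) {
      S <- sigma[[h]]
      if (!is.matrix(S) || nrow(S) != p || ncol(S) != p)
        stop("sigma[[", h, "]] must be a ", p, "x", p, " matrix", call. = FALSE)
      if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
        stop("sigma[[", h, "]] is not symmetric", call. = FALSE)
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 0)
        stop("sigma[[", h, "]] is not positive definite (min eigenvalue ",
             format(ev), ")", call. = FALSE)
    }
    if (family != "normal" && any(nu <= 0))
      stop("degrees of freedom must be positive", call. = FALSE)
    if (family %in% c("normal", "t") && any(delta != 0))
      stop("family '", family, "' requires zero skewness", call. = FALSE)
    if (any(!is.finite(mu)) || any(!is.finite(delta)))
      stop("non-finite component parameters", call. = FALSE)
  })
  invisible(model)
}

#' @export
print.mixture_model <- function(x, digits = 3, ...) {
  cat(sprintf("<mixture_model>: %d-component %s mixture in %d dimensions\n",
              x$g, x$family, x$p))
  cat("  pi:", paste(format(round(x$pi, digits)), collapse = " "), "\n")
  cat("  nu:", paste(format(round(x$nu, 1)), collapse = " "), "\n")
  cat("  markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

# number of free parameters for BIC: (g-1) proportions + g*p locations +
# g*p(p+1)/2 scale elements + g dofs (+ g*p skews for the skew-t family)
#' Count free parameters of a mixture family
#'
#' @param g number of components; @param p dimension;
#' @param family `"t"` or `"skew-t"`.
#' @return integer parameter count used in the BIC penalty.
#' @export
n_params <- function(g, p, family = c("t", "skew-t")) {
  family <- match.arg(family)
  d <- (g - 1) + g * p + g * p * (p + 1) / 2 + g
  if (family == "skew-t") d <- d + g * p
  as.integer(d)
}
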