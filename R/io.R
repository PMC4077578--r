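# CSV expression matrices, JSON model documents, and per-cell label files.

MODEL_SCHEMA <- "1.0"

#' Read a CSV/TSV expression matrix
#'
#' Expects a rectangular numeric table, cells as rows and markers as
#' columns.  Ragged rows and non-numeric cells raise format errors naming
#' the offending (row, column) position in the data block.
#'
#' @param path file path.
#' @param has_header first row holds marker names (default `TRUE`).
#' @param sep field separator (`","`; use `"\t"` for TSV).
#' @param sample_id sample identifier (defaults to the file name).
#' @return a [marker_sample()].
#' @export
read_marker_csv <- function(path, has_header = TRUE, sep = ",",
                            sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  if (has_header) {
    header <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (!length(cells)) stop("no data rows in ", path, call. = FALSE)
  } else {
    header <- paste0("M", seq_along(cells[[1L]]))
  }
  p <- length(header)
  lens <- lengths(cells)
  if (any(lens != p))
    stop("ragged table in ", path, ": row ", which(lens != p)[1L],
         " has ", lens[lens != p][1L], " fields, expected ", p, call. = FALSE)
  M <- matrix(NA_real_, length(cells), p)
  for (j in seq_len(p)) {
    col <- vapply(cells, `[[`, "", j)
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' at row ", bad[1L],
           ", column ", j, " of ", path, call. = FALSE)
    M[, j] <- v
  }
  marker_sample(M, marker_names = header,
                sample_id = sample_id %||%
                  tools::file_path_sans_ext(basename(path)))
}

#' Write a marker sample as CSV with full double precision
#'
#' @param sample a [marker_sample()] or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(sample, path) {
  if (!inherits(sample, "marker_sample")) sample <- marker_sample(sample)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sample$marker_names, collapse = ","), con)
  rows <- apply(sample$data, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17L), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# JSON model documents

model_to_list <- function(model) {
  validate_mixture_model(model)
  if (any(is.nan(unlist(model[c("pi", "mu", "delta", "nu")]))) ||
      any(vapply(model$sigma, function(S) any(is.nan(S)), TRUE)))
    stop("NaN in model parameters; refusing to serialize", call. = FALSE)
  list(family = model$family, g = model$g, p = model$p,
       marker_names = model$marker_names,
       components = lapply(seq_len(model$g), function(h) {
         list(pi = model$pi[h], mu = as.vector(model$mu[h, ]),
              sigma = apply(model$sigma[[h]], 1L, as.vector, simplify = FALSE),
              delta = as.vector(model$delta[h, ]), nu = model$nu[h])
       }))
}

list_to_model <- function(x) {
  g <- x$g
  comps <- x$components
  mixture_model(
    pi = vapply(comps, function(cp) cp$pi, 0),
    mu = do.call(rbind, lapply(comps, function(cp) unlist(cp$mu))),
    sigma = lapply(comps, function(cp)
      do.call(rbind, lapply(cp$sigma, unlist))),
    delta = do.call(rbind, lapply(comps, function(cp) unlist(cp$delta))),
    nu = vapply(comps, function(cp) cp$nu, 0),
    family = x$family, marker_names = unlist(x$marker_names))
}

#' Serialize a mixture model or joint batch fit to JSON
#'
#' Writes a self-describing JSON document (schema version, family, g, p,
#' all component parameters; for a `"jcm"` fit additionally the per-sample
#' transforms, random-effect variances and fit diagnostics).  Numbers are
#' written at full double precision so that a round trip reproduces the
#' model to better than 1e-12 relative error.  Per-cell quantities
#' (responsibilities, labels) are not part of the document; see
#' [write_labels()].
#'
#' @param object a [mixture_model()] or `"jcm"` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(object, path) {
  if (inherits(object, "mixture_model")) {
    doc <- c(list(schema = MODEL_SCHEMA, type = "mixture_model"),
             model_to_list(object))
  } else if (inherits(object, "jcm")) {
    trs <- lapply(seq_along(object$sample_ids), function(k) {
      tr <- object$transforms[[k]]
      if (any(is.nan(c(tr$a, tr$b, tr$pi))))
        stop("NaN in transform parameters; refusing to serialize",
             call. = FALSE)
      list(sample_id = object$sample_ids[k],
           a = apply(tr$a, 1L, as.vector, simplify = FALSE),
           b = apply(tr$b, 1L, as.vector, simplify = FALSE),
           pi = as.vector(tr$pi))
    })
    doc <- list(schema = MODEL_SCHEMA, type = "jcm_fit",
                template = model_to_list(object$template),
                transforms = trs,
                rem = object$rem,
                diagnostics = list(loglik = object$loglik, bic = object$bic,
                                   objective_trace = object$objective_trace,
                                   loglik_trace = object$loglik_trace,
                                   n_iter = object$n_iter,
                                   converged = object$converged),
                sample_ids = object$sample_ids,
                family = object$family, g = object$g, p = object$p,
                marker_names = object$marker_names,
                n_cells = object$n_cells)
  } else stop("cannot serialize objects of class ",
              paste(class(object), collapse = "/"), call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize a model document written by [write_model_json()]
#'
#' @param path JSON path.
#' @return a [mixture_model()] or a (data-free) `"jcm"` fit object.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, MODEL_SCHEMA))
    stop("unsupported model schema '", doc$schema %||% "<missing>",
         "' (expected '", MODEL_SCHEMA, "')", call. = FALSE)
  if (identical(doc$type, "mixture_model")) return(list_to_model(doc))
  if (!identical(doc$type, "jcm_fit"))
    stop("unknown document type '", doc$type %||% "<missing>", "'",
         call. = FALSE)
  template <- list_to_model(doc$template)
  g <- doc$g; p <- doc$p
  transforms <- lapply(doc$transforms, function(tr) {
    list(a = do.call(rbind, lapply(tr$a, unlist)),
         b = do.call(rbind, lapply(tr$b, unlist)),
         pi = unlist(tr$pi))
  })
  names(transforms) <- vapply(doc$transforms, `[[`, "", "sample_id")
  structure(list(template = template, transforms = transforms,
                 rem = list(sigma_a2 = unlist(doc$rem$sigma_a2),
                            sigma_b2 = unlist(doc$rem$sigma_b2)),
                 per_sample = NULL, data = NULL,
                 loglik = doc$diagnostics$loglik,
                 objective_trace = unlist(doc$diagnostics$objective_trace),
                 loglik_trace = unlist(doc$diagnostics$loglik_trace),
                 bic = doc$diagnostics$bic,
                 converged = isTRUE(doc$diagnostics$converged),
                 n_iter = doc$diagnostics$n_iter,
                 sample_ids = unlist(doc$sample_ids),
                 g = g, p = p, family = doc$family,
                 marker_names = unlist(doc$marker_names),
                 n_cells = unlist(doc$n_cells),
                 options = NULL),
            class = "jcm")
}

# ---------------------------------------------------------------------------
# label files: one integer per cell (0 = outlier, 1..g = registered
# template component), with a sidecar naming the template components

#' Write per-cell registered labels
#'
#' @param labels integer vector (0 = outlier/unassigned, 1..g = template
#'   component index).
#' @param path output path; a sidecar `<path>.components` names the
#'   template components.
#' @param component_names optional character vector naming components 1..g.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, component_names = NULL) {
  writeLines(as.character(as.integer(labels)), path)
  if (is.null(component_names))
    component_names <- paste0("population", seq_len(max(max(labels), 1L)))
  writeLines(paste(seq_along(component_names), component_names),
             paste0(path, ".components"))
  invisible(path)
}

#' Read per-cell labels written by [write_labels()]
#'
#' @param path label file path.
#' @return integer vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.integer(readLines(path, warn = FALSE))
}
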