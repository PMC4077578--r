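# Minimal FCS 3.0/3.1 list-mode reader/writer for float data.
# Scope: $MODE L, $DATATYPE F (float32) or D (float64), byte orders 1,2,3,4
# and 4,3,2,1.  Integer data and FCS 2.x are rejected with explicit errors.

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1L])
  txt <- rawToChar(raw_text[-1L])
  parts <- strsplit(txt, delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), 2L)])
  setNames(as.list(vals), keys)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Reads float list-mode data ($DATATYPE F or D, $MODE L), honoring
#' $BYTEORD, into a [marker_sample()].  No compensation or intensity
#' transformation is applied; the data are returned exactly as stored.
#'
#' @param path path to an FCS file.
#' @param markers optional character vector restricting (and ordering) the
#'   returned columns by their $PnN names.
#' @return a [marker_sample()] with `$TOT` rows and one column per
#'   (selected) parameter.
#' @export
read_fcs <- function(path, markers = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 58L)
  if (length(header) < 58L)
    stop("file too short to be an FCS file: ", path, call. = FALSE)
  version <- rawToChar(header[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version,
         "' (only FCS3.0/FCS3.1 are supported)", call. = FALSE)
  off <- function(i) {
    # 58-byte header: 6-char version, 4 spaces, then six 8-char offsets
    s <- trimws(rawToChar(header[(11L + 8L * (i - 1L)):(10L + 8L * i)]))
    if (!nzchar(s)) 0 else as.numeric(s)
  }
  text_start <- off(1L); text_end <- off(2L)
  data_start <- off(3L); data_end <- off(4L)
  seek(con, text_start)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_start + 1L))
  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop("missing required keyword ", key, " in ", path,
                         call. = FALSE)
    v
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE '", dtype, "' (only float list mode F/D)",
         call. = FALSE)
  mode <- toupper(need("$MODE"))
  if (mode != "L")
    stop("unsupported $MODE '", mode, "' (only list mode L)", call. = FALSE)
  byteord <- need("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD '", byteord, "'", call. = FALSE))
  tot <- as.integer(need("$TOT"))
  par <- as.integer(need("$PAR"))
  pnn <- vapply(seq_len(par), function(i) {
    v <- kw[[paste0("$P", i, "N")]]
    if (is.null(v)) paste0("P", i) else v
  }, "")
  bits <- vapply(seq_len(par), function(i) {
    v <- kw[[paste0("$P", i, "B")]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, 0L)
  want_bits <- if (dtype == "F") 32L else 64L
  if (any(!is.na(bits) & bits != want_bits))
    stop("$PnB = ", bits[which(bits != want_bits)[1L]],
         " inconsistent with $DATATYPE ", dtype, call. = FALSE)
  if (data_start == 0 || data_end == 0) {
    data_start <- as.numeric(kw[["$BEGINDATA"]] %||% 0)
    data_end <- as.numeric(kw[["$ENDDATA"]] %||% 0)
  }
  if (data_start <= 0)
    stop("cannot locate the DATA segment in ", path, call. = FALSE)
  seek(con, data_start)
  nval <- tot * par
  vals <- readBin(con, "double", n = nval, size = if (dtype == "F") 4L else 8L,
                  endian = endian)
  if (length(vals) < nval)
    stop("DATA segment truncated in ", path, call. = FALSE)
  M <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  colnames(M) <- pnn
  if (!is.null(markers)) {
    missing <- setdiff(markers, pnn)
    if (length(missing))
      stop("marker(s) not present: [", paste(missing, collapse = ", "),
           "]; available $PnN names: [", paste(pnn, collapse = ", "), "]",
           call. = FALSE)
    M <- M[, markers, drop = FALSE]
    pnn <- markers
  }
  marker_sample(M, marker_names = pnn,
                sample_id = kw[["$FIL"]] %||%
                  tools::file_path_sans_ext(basename(path)))
}

#' Write a marker sample as a minimal FCS 3.1 file
#'
#' Intended for producing synthetic fixtures and exchanging simulated data,
#' not for instrument emulation.  `$DATATYPE D` (doubles) round-trips the
#' matrix bit-exactly; `"F"` stores float32.
#'
#' @param sample a [marker_sample()] (or numeric matrix).
#' @param path output path.
#' @param datatype `"D"` (default) or `"F"`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path, datatype = c("D", "F")) {
  datatype <- match.arg(datatype)
  if (!inherits(sample, "marker_sample")) sample <- marker_sample(sample)
  M <- sample$data
  tot <- nrow(M); par <- ncol(M)
  size <- if (datatype == "D") 8L else 4L
  delim <- "/"
  kv <- c("$DATATYPE", datatype, "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$TOT", as.character(tot), "$PAR", as.character(par),
          "$NEXTDATA", "0", "$FIL", sample$sample_id)
  for (i in seq_len(par)) {
    kv <- c(kv, paste0("$P", i, "N"), sample$marker_names[i],
            paste0("$P", i, "B"), as.character(size * 8L),
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144")
  }
  # assemble with placeholder offsets, then fix once lengths are known
  make_text <- function(bd, ed) {
    paste0(delim, paste(c(kv, "$BEGINDATA", as.character(bd),
                          "$ENDDATA", as.character(ed)),
                        collapse = delim), delim)
  }
  header_len <- 58L
  guess <- make_text(999999999, 999999999)
  text_start <- header_len
  text_end <- text_start + nchar(guess) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + tot * par * size - 1L
  # offsets appear inside the text; keep the text length fixed by padding
  txt <- make_text(data_start, data_end)
  txt <- paste0(txt, strrep(" ", nchar(guess) - nchar(txt)))
  pad8 <- function(x) formatC(x, width = 8L, flag = " ")
  header <- paste0("FCS3.1    ", pad8(text_start), pad8(text_end),
                   pad8(data_start), pad8(data_end), pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(M)), con, size = size, endian = "little")
  invisible(path)
}
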