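make_fixture_sample <- function(n = 100, seed = 1) {
  set.seed(seed)
  marker_sample(matrix(rnorm(n * 4, 5, 2), n, 4),
                marker_names = c("CD4", "CD45RA", "SLP76", "ZAP70"),
                sample_id = "fixture1")
}

test_that("FCS round trip is bit-exact for doubles, float32 for F", {
  s <- make_fixture_sample()
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, f)
  r <- read_fcs(f)
  expect_identical(unname(r$data), unname(s$data))
  expect_equal(dim(r$data), c(100L, 4L))
  expect_identical(r$marker_names, s$marker_names)
  write_fcs(s, f, datatype = "F")
  rf <- read_fcs(f)
  expect_lt(max(abs(rf$data - s$data)), 1e-3)   # float32 rounding
  expect_false(identical(rf$data, s$data))
})

test_that("FCS marker selection returns requested columns in order", {
  s <- make_fixture_sample()
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, f)
  r <- read_fcs(f, markers = c("CD4", "CD45RA"))
  expect_equal(dim(r$data), c(100L, 2L))
  expect_identical(colnames(r$data), c("CD4", "CD45RA"))
  expect_identical(r$data[, "CD4"], s$data[, "CD4"])
  r2 <- read_fcs(f, markers = c("ZAP70", "CD4"))
  expect_identical(colnames(r2$data), c("ZAP70", "CD4"))
  expect_error(read_fcs(f, markers = "CD8"), "CD8.*available.*CD4",
               ignore.case = TRUE)
})

test_that("FCS reader rejects what it does not support, by name", {
  expect_error(read_fcs(file.path(tempdir(), "no-such-file.fcs")),
               "not found")
  # FCS 2.0 header
  f <- withr::local_tempfile(fileext = ".fcs")
  writeBin(charToRaw(sprintf("FCS2.0    %58s", "")), f)
  expect_error(read_fcs(f), "FCS2.0")
  # integer datatype
  s <- make_fixture_sample(10)
  f2 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, f2)
  raw <- readBin(f2, "raw", file.size(f2))
  pos <- grepRaw("\\$DATATYPE/D", raw)
  raw[pos + 10L] <- charToRaw("I")
  writeBin(raw, f2)
  expect_error(read_fcs(f2), "DATATYPE")
})

test_that("CSV matrices parse, round trip, and report bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4", "5,6"), f)
  s <- read_marker_csv(f)
  expect_identical(s$marker_names, c("a", "b"))
  expect_equal(unname(s$data), rbind(c(1, 2), c(3, 4), c(5, 6)))
  # full-precision round trip
  orig <- make_fixture_sample(50)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(orig, f2)
  back <- read_marker_csv(f2)
  expect_identical(unname(back$data), unname(orig$data))
  # error positions
  writeLines(c("a,b", "1,2", "x,4"), f)
  expect_error(read_marker_csv(f), "row 2, column 1")
  writeLines(c("a,b", "1,2", "3"), f)
  expect_error(read_marker_csv(f), "ragged")
  writeLines(character(0), f)
  expect_error(read_marker_csv(f), "empty")
})

test_that("model JSON round trip is lossless across random valid models", {
  set.seed(5)
  for (i in 1:6) {
    fam <- sample(c("t", "skew-t"), 1)
    m <- default_template(p = sample(1:4, 1), g = sample(1:4, 1),
                          family = fam, separation = 3, seed = i)
    f <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, f)
    b <- read_model_json(f)
    expect_equal(b$pi, m$pi, tolerance = 1e-12)
    expect_equal(b$mu, m$mu, tolerance = 1e-12)
    expect_equal(b$sigma, m$sigma, tolerance = 1e-12)
    expect_equal(b$delta, m$delta, tolerance = 1e-12)
    expect_equal(b$nu, m$nu, tolerance = 1e-12)
    expect_identical(b$family, m$family)
    expect_identical(b$marker_names, m$marker_names)
  }
})

test_that("model JSON schema is explicit: g blocks of p-vectors", {
  m <- default_template(p = 4, g = 5, family = "t", separation = 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  doc <- jsonlite::read_json(f)
  expect_identical(doc$type, "mixture_model")
  expect_length(doc$components, 5L)
  expect_true(all(vapply(doc$components,
                         function(cp) length(cp$mu) == 4L, TRUE)))
  expect_true(all(vapply(doc$components,
                         function(cp) length(cp$sigma) == 4L, TRUE)))
})

test_that("model JSON rejects schema mismatches and NaN parameters", {
  m <- default_template(p = 2, g = 2, family = "t", separation = 3, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  doc <- jsonlite::read_json(f)
  doc$schema <- "0.0"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(read_model_json(f), "schema")
  m$mu[1, 1] <- NaN
  expect_error(write_model_json(m, f), "NaN|finite")
})

test_that("jcm fit JSON round trips template, transforms and variances", {
  tpl <- default_template(p = 2, g = 2, family = "t", separation = 5,
                          seed = 2)
  sim <- simulate_batch(tpl, m = 2, n_per_sample = 300, sigma_a = 0,
                        sigma_b = 0.2, seed = 3)
  fit <- jcm(sim$batch, g = 2, family = "t", seed = 1, n_starts = 1,
             max_iter = 15)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, f)
  b <- read_model_json(f)
  expect_s3_class(b, "jcm")
  expect_equal(b$template$mu, fit$template$mu, tolerance = 1e-12)
  expect_equal(b$transforms[[1]]$a, fit$transforms[[1]]$a,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b$rem$sigma_b2, fit$rem$sigma_b2, tolerance = 1e-12)
  expect_equal(b$loglik, fit$loglik, tolerance = 1e-12)
})

test_that("label files round trip with a component sidecar", {
  f <- withr::local_tempfile(fileext = ".txt")
  lab <- c(0L, 1L, 2L, 2L, 3L)
  write_labels(lab, f, component_names = c("naive", "memory", "blast"))
  expect_identical(read_labels(f), lab)
  side <- readLines(paste0(f, ".components"))
  expect_identical(side, c("1 naive", "2 memory", "3 blast"))
})
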