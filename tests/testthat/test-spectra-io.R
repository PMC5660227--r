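test_that("raw_spectrum enforces its invariants", {
  expect_s3_class(raw_spectrum("a", c(1000, 1001), c(5, 0)), "raw_spectrum")
  expect_error(raw_spectrum("a", c(1000, 1000), c(1, 1)), "increasing")
  expect_error(raw_spectrum("a", c(1000, 999), c(1, 1)), "increasing")
  expect_error(raw_spectrum("a", c(1000, 1001), c(1, -1)), "non-negative")
  expect_error(raw_spectrum("a", 1000, 1), "at least 2")
  expect_error(raw_spectrum("a", c(1000, NA), c(1, 1)), "finite")
  expect_error(raw_spectrum("a", c(1000, 1001), c(1, 1), group = "X"),
               "group")
})

test_that("mzXML write/read round-trips spectra", {
  tmp <- withr::local_tempfile(fileext = ".mzXML")
  s <- gauss_spectrum("rt", peaks_mz = c(2084, 4478),
                      heights = c(100, 40), lo = 2000, hi = 5000)
  for (args in list(list(precision = 32L, compress = FALSE),
                    list(precision = 64L, compress = FALSE),
                    list(precision = 64L, compress = TRUE))) {
    do.call(write_mzxml, c(list(s, tmp), args))
    back <- read_mzxml(tmp)
    expect_length(back, 1L)
    tol <- if (args$precision == 32L) 1e-6 else 1e-12
    expect_equal(back[[1]]$mz, s$mz, tolerance = tol)
    expect_equal(back[[1]]$intensity, s$intensity, tolerance = tol)
  }
})

test_that("multi-scan mzXML preserves file order", {
  tmp <- withr::local_tempfile(fileext = ".mzXML")
  sp <- lapply(1:3, function(i)
    gauss_spectrum(paste0("s", i), peaks_mz = 1500 + 100 * i,
                   heights = 10 * i, lo = 1200, hi = 2200))
  write_mzxml(sp, tmp)
  back <- read_mzxml(tmp)
  expect_length(back, 3L)
  apexes <- vapply(back, function(s) s$mz[which.max(s$intensity)], 0)
  expect_equal(apexes, c(1600, 1700, 1800), tolerance = 1e-5)
})

test_that("unsorted mzXML peak lists are sorted with intensities kept paired", {
  # hand-craft a file with shuffled (mz, intensity) pairs
  mz <- c(1100, 1000, 1300, 1050, 1200, 1250, 1150, 1010, 1020, 1030)
  it <- seq(10, 100, by = 10)
  pairs <- as.numeric(rbind(mz, it))
  b64 <- gsub("\n", "", jsonlite::base64_enc(
    writeBin(pairs, raw(), size = 8, endian = "big")), fixed = TRUE)
  tmp <- withr::local_tempfile(fileext = ".mzXML")
  writeLines(sprintf(paste0(
    '<?xml version="1.0"?>\n<mzXML xmlns="http://sashimi.sourceforge.net/',
    'schema_revision/mzXML_3.2">\n <msRun scanCount="1">\n  <scan num="1" ',
    'msLevel="1" peaksCount="10" retentionTime="PT1S">\n   <peaks ',
    'precision="64" byteOrder="network" contentType="m/z-int" ',
    'compressionType="none" compressedLen="0">%s</peaks>\n  </scan>\n ',
    '</msRun>\n</mzXML>'), b64), tmp)
  back <- read_mzxml(tmp)[[1]]
  ord <- order(mz)
  expect_equal(back$mz, mz[ord])
  expect_equal(back$intensity, it[ord])
})

test_that("malformed and empty mzXML inputs raise parse errors", {
  tmp <- withr::local_tempfile(fileext = ".mzXML")
  writeLines("<mzXML><msRun>", tmp)
  expect_error(read_mzxml(tmp), "malformed")
  expect_error(read_mzxml(file.path(tempdir(), "nope.mzXML")), "not found")
})

test_that("CSV spectrum reader handles values, headers and errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2084,100", "2085,50"), tmp)
  s <- read_csv_spectrum(tmp, "x")
  expect_equal(s$mz, c(2084, 2085))
  expect_equal(s$intensity, c(100, 50))
  writeLines(c("mz,intensity", "2084,100", "2085,50"), tmp)
  expect_equal(read_csv_spectrum(tmp, "x")$intensity, c(100, 50))
  writeLines(character(0), tmp)
  expect_error(read_csv_spectrum(tmp, "x"), "empty")
  writeLines(c("2084,abc", "2085,50"), tmp)
  expect_error(read_csv_spectrum(tmp, "x"), "row 1")
  writeLines(c("2084,1", "2084,2", "2085,3"), tmp)
  expect_error(read_csv_spectrum(tmp, "x"), "duplicate")
})

test_that("CSV spectrum round-trip keeps 6 significant figures", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  s <- gauss_spectrum("rt", noise_sd = 5, lo = 1000, hi = 1500, seed = 42)
  write_csv_spectrum(s, tmp)
  back <- read_csv_spectrum(tmp, "rt")
  expect_equal(back$mz, s$mz, tolerance = 1e-6)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-6)
})

test_that("peak matrix CSV round-trips exactly and labels clusters in Da", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  m <- peak_matrix(matrix(runif(6, 0, 1000), 2, 3),
                   cluster_mz = c(1781.2, 2084.9, 4478.1),
                   samples = c("a", "b"), groups = c("HC", "CRC"))
  write_peak_matrix(m, tmp)
  header <- readLines(tmp, n = 2L)[2]
  expect_match(header, "sample_id,group,mz_1781,mz_2085,mz_4478")
  back <- read_peak_matrix(tmp)
  expect_equal(back$values, m$values)
  expect_equal(back$cluster_mz, m$cluster_mz)
  expect_identical(back$samples, m$samples)
  expect_identical(back$groups, m$groups)
})

test_that("colliding rounded cluster labels fall back to one decimal", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- peak_matrix(matrix(1:4, 2, 2), cluster_mz = c(2084.2, 2084.4),
                   samples = c("a", "b"), groups = c("HC", "CRC"))
  expect_warning(write_peak_matrix(m, tmp), "collide")
  expect_match(readLines(tmp, n = 2L)[2], "mz_2084.2,mz_2084.4")
  back <- suppressWarnings(read_peak_matrix(tmp))
  expect_equal(back$cluster_mz, m$cluster_mz)
})

test_that("manifest reader validates and preserves row order", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,stage", "z9,CRC,II", "a1,HC,", "m5,CRC,IV"),
             tmp)
  m <- read_manifest(tmp)
  expect_identical(m$sample_id, c("z9", "a1", "m5"))
  writeLines(c("sample_id,group", "a,HC", "a,CRC"), tmp)
  expect_error(read_manifest(tmp), "unique")
  writeLines(c("sample_id,group,stage", "a,HC,II"), tmp)
  expect_error(read_manifest(tmp), "stage")
  writeLines(c("sample_id,group", "a,healthy"), tmp)
  expect_error(read_manifest(tmp), "group")
})
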