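# DICOM series discovery, loading, sorting, and gap handling.

make_slices <- function(n, series = 1L, locs = (seq_len(n) - 1) * 5,
                        size = 16) {
  lapply(seq_len(n), function(i) list(
    pixels = matrix((seq_len(size * size) * 997L + i * 131L) %% 65536L,
                    size, size),
    meta = slice_metadata(width = size, height = size, slice_thickness = 5,
                          pixel_spacing = c(1.5, 1.5),
                          window_center = 20000, window_width = 10000,
                          slice_location = locs[i], series_number = series,
                          series_description = paste0("T1 series ", series))))
}

write_slices <- function(slices, folder, prefix = "img") {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(slices))
    liverseg:::dcm_write_slice(
      file.path(folder, sprintf("%s_%03d.dcm", prefix, i)),
      slices[[i]]$pixels, slices[[i]]$meta)
  folder
}

test_that("DICOM write/read round-trips pixels and metadata exactly", {
  sl <- make_slices(1)[[1]]
  path <- file.path(withr::local_tempdir(), "one.dcm")
  liverseg:::dcm_write_slice(path, sl$pixels, sl$meta)
  r <- liverseg:::dcm_read_slice(path)
  expect_identical(r$pixels, sl$pixels)
  expect_equal(r$meta$slice_location, sl$meta$slice_location)
  expect_equal(r$meta$window_center, sl$meta$window_center)
  expect_equal(r$meta$window_width, sl$meta$window_width)
  expect_equal(r$meta$pixel_spacing, sl$meta$pixel_spacing)
  expect_identical(r$meta$series_number, sl$meta$series_number)
  expect_identical(r$meta$series_description, sl$meta$series_description)
  expect_identical(r$meta$bits_allocated, 16L)
  expect_identical(r$meta$modality, "MR")
})

test_that("written files are readable by an independent DICOM library", {
  sl <- make_slices(1, locs = 17.5)[[1]]
  path <- file.path(withr::local_tempdir(), "x.dcm")
  liverseg:::dcm_write_slice(path, sl$pixels, sl$meta)
  script <- file.path(dirname(path), "check.py")
  writeLines(c(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "print(int(d.SeriesNumber), float(d.SliceLocation),",
    "      int(d.Rows), int(d.Columns), int(d.BitsAllocated),",
    "      float(d.WindowCenter), float(d.WindowWidth),",
    "      int(d.pixel_array.sum()), d.Modality)"), script)
  out <- system2("python", c(script, path), stdout = TRUE)
  got <- strsplit(trimws(out[length(out)]), " ")[[1]]
  expect_equal(as.numeric(got[1:7]),
               c(1, 17.5, 16, 16, 16, 20000, 10000))
  expect_equal(as.numeric(got[8]), sum(sl$pixels))
  expect_identical(got[9], "MR")
})

test_that("discover_series groups files by SeriesNumber, ordered", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(2, series = 7L), folder, "b")
  write_slices(make_slices(3, series = 3L), folder, "a")
  ds <- discover_series(folder)
  expect_length(ds, 2)
  expect_equal(vapply(ds, `[[`, integer(1), "series_number"), c(3L, 7L))
  expect_equal(vapply(ds, `[[`, integer(1), "n_files"), c(3L, 2L))
  expect_match(ds[[1]]$series_description, "series 3")
})

test_that("discover_series: single file, unreadable files, empty folder", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(1, series = 2L), folder)
  writeLines("not dicom at all", file.path(folder, "junk.txt"))
  expect_warning(ds <- discover_series(folder), "skipping unreadable")
  expect_length(ds, 1)
  expect_equal(ds[[1]]$n_files, 1L)

  empty <- withr::local_tempdir()
  writeLines("nope", file.path(empty, "junk.txt"))
  expect_error(suppressWarnings(discover_series(empty)), "empty folder")
})

test_that("load_series sorts by SliceLocation and is permutation-invariant", {
  folder <- withr::local_tempdir()
  sl <- make_slices(3, locs = c(30, 10, 20))
  write_slices(sl, folder)
  v <- load_series(folder)
  locs <- vapply(v$metadata, `[[`, numeric(1), "slice_location")
  expect_equal(locs, c(10, 20, 30))
  # slice written with location 10 is now first, bit-identical to disk
  expect_identical(get_layer(v, "source")[[1]], sl[[2]]$pixels)

  # write the same series in shuffled file order: identical volume
  folder2 <- withr::local_tempdir()
  write_slices(sl[c(2, 3, 1)], folder2, "shuf")
  v2 <- load_series(folder2)
  expect_identical(get_layer(v, "source"), get_layer(v2, "source"))
})

test_that("load_series: single slice, duplicates, series selection", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(1), folder)
  expect_equal(load_series(folder)$z_max, 1L)

  dup <- withr::local_tempdir()
  write_slices(make_slices(2, locs = c(5, 5)), dup)
  expect_error(load_series(dup), "duplicate SliceLocation.*5")

  two <- withr::local_tempdir()
  write_slices(make_slices(2, series = 1L), two, "s1")
  write_slices(make_slices(2, series = 2L), two, "s2")
  expect_error(load_series(two), "pick one")
  expect_equal(load_series(two, 2)$z_max, 2L)
})

test_that("missing WC/WW headers fall back to the slice intensity range", {
  # hand-assemble a file without the VOI tags using the codec primitives
  folder <- withr::local_tempdir()
  path <- file.path(folder, "novoi.dcm")
  px <- matrix(c(100L, 300L, 500L, 700L), 2, 2)
  el <- liverseg:::dcm_element
  u16 <- liverseg:::uint16_to_raw
  body <- c(el(0x0008, 0x0060, "CS", "MR"),
            el(0x0018, 0x0050, "DS", "5"),
            el(0x0020, 0x0011, "IS", "1"),
            el(0x0020, 0x1041, "DS", "0"),
            el(0x0028, 0x0030, "DS", "1\\1"),
            el(0x0028, 0x0010, "US", u16(2L)),
            el(0x0028, 0x0011, "US", u16(2L)),
            el(0x0028, 0x0100, "US", u16(16L)),
            el(0x7FE0, 0x0010, "OW", u16(as.integer(t(px)))))
  con <- file(path, "wb")
  writeBin(raw(128), con); writeBin(charToRaw("DICM"), con)
  writeBin(body, con); close(con)
  expect_warning(v <- load_series(folder), "missing WindowCenter")
  expect_equal(v$metadata[[1]]$window_center, (100 + 700) / 2)
  expect_equal(v$metadata[[1]]$window_width, 600)
  expect_identical(get_layer(v, "source")[[1]], px)
})

test_that("check_gaps inserts empty slices at inferred positions", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(4, locs = c(0, 5, 10, 20)), folder)
  expect_message(v <- check_gaps(load_series(folder)), "1 missing")
  expect_equal(v$z_max, 5L)
  expect_equal(v$missing_slices, 4L)
  expect_true(all(get_layer(v, "source")[[4]] == 0))
  locs <- vapply(v$metadata, `[[`, numeric(1), "slice_location")
  expect_equal(locs, c(0, 5, 10, 15, 20))

  # two consecutive missing slices from one wide gap
  folder2 <- withr::local_tempdir()
  write_slices(make_slices(3, locs = c(0, 5, 20)), folder2)
  expect_message(v2 <- check_gaps(load_series(folder2)), "2 missing")
  expect_equal(v2$missing_slices, c(3L, 4L))
  locs2 <- vapply(v2$metadata, `[[`, numeric(1), "slice_location")
  expect_equal(locs2, c(0, 5, 10, 15, 20))
})

test_that("check_gaps: evenly spaced series untouched, corrupt spacing fatal", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(4), folder)
  v <- check_gaps(load_series(folder))
  expect_equal(v$z_max, 4L)
  expect_length(v$missing_slices, 0)

  bad <- withr::local_tempdir()
  write_slices(make_slices(4, locs = c(0, 5, 10, 13.4)), bad)
  expect_error(check_gaps(load_series(bad)), "corrupted series")
})

test_that("after check_gaps slice locations are evenly spaced", {
  folder <- withr::local_tempdir()
  write_slices(make_slices(5, locs = c(0, 5, 15, 30, 35)), folder)
  v <- suppressMessages(check_gaps(load_series(folder)))
  locs <- vapply(v$metadata, `[[`, numeric(1), "slice_location")
  d <- diff(locs)
  expect_true(all(abs(d - d[1]) <= 1e-3 * d[1]))
})

test_that("layers are append-only and source is bit-identical to disk", {
  folder <- withr::local_tempdir()
  sl <- make_slices(2)
  write_slices(sl, folder)
  v <- load_series(folder)
  expect_identical(get_layer(v, "source")[[2]], sl[[2]]$pixels)
  v2 <- add_layer(v, "extra", get_layer(v, "source"))
  expect_error(add_layer(v2, "extra", get_layer(v, "source")),
               "append-only")
  expect_error(get_layer(v, "nope"), "no layer")
})
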