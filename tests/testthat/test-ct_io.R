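test_that("DICOM round trip preserves pixels exactly and pitch to 6 decimals", {
  set.seed(11)
  px <- matrix(sample(-200:300, 40 * 30, replace = TRUE), 40, 30)
  sl <- ct_slice(px, 0.80, source_id = "fixture")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(sl, path)
  got <- read_ct_slice(path)
  expect_identical(got$pixels, px + 0)
  expect_equal(got$pixel_pitch, 0.80, tolerance = 1e-6)
})

test_that("stored values are rescaled to HU by slope and intercept", {
  # stored 1079 with slope 1, intercept -1024 is 55 HU
  sl <- ct_slice(matrix(55, 8, 8), 0.80)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(sl, path)
  bytes <- readBin(path, "raw", file.size(path))
  expect_identical(readBin(bytes[(length(bytes) - 1):length(bytes)],
                           "integer", size = 2, endian = "little",
                           signed = FALSE), 1079L)
  expect_equal(read_ct_slice(path)$pixels[1, 1], 55)
})

test_that("HU conversion is affine: shifting stored values shifts HU by k*slope", {
  px <- matrix(sample(0:100, 100, replace = TRUE), 10, 10)
  p1 <- withr::local_tempfile(fileext = ".dcm")
  p2 <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(ct_slice(px, 0.8), p1)
  write_ct_slice(ct_slice(px + 17, 0.8), p2)
  expect_equal(read_ct_slice(p2)$pixels, read_ct_slice(p1)$pixels + 17)
})

# builds a DICOM file from an explicit element list (for malformed cases)
write_raw_dicom <- function(path, drop = character(), extra = NULL,
                            spacing = "0.800000\\0.800000") {
  px <- as.integer(t(matrix(1079L, 4, 4)))
  els <- list(
    Rows = hccwave:::.dicom_us(0x0028L, 0x0010L, 4L),
    Columns = hccwave:::.dicom_us(0x0028L, 0x0011L, 4L),
    PixelSpacing = hccwave:::.dicom_str(0x0028L, 0x0030L, "DS", spacing),
    PixelRepresentation = hccwave:::.dicom_us(0x0028L, 0x0103L, 0L),
    RescaleIntercept = hccwave:::.dicom_str(0x0028L, 0x1052L, "DS", "-1024"),
    RescaleSlope = hccwave:::.dicom_str(0x0028L, 0x1053L, "DS", "1"),
    PixelData = hccwave:::.dicom_element(0x7FE0L, 0x0010L, "OW",
                                         hccwave:::.raw_u16(px))
  )
  els <- els[setdiff(names(els), drop)]
  hccwave:::.dicom_write_file(path, c(extra, unlist(unname(els))))
}

test_that("missing rescale or spacing metadata raises a naming error", {
  p <- withr::local_tempfile(fileext = ".dcm")
  write_raw_dicom(p, drop = "RescaleIntercept")
  expect_error(read_ct_slice(p), "RescaleIntercept")
  write_raw_dicom(p, drop = "PixelSpacing")
  expect_error(read_ct_slice(p), "PixelSpacing")
})

test_that("multi-frame input is rejected", {
  p <- withr::local_tempfile(fileext = ".dcm")
  write_raw_dicom(p, extra = hccwave:::.dicom_str(0x0028L, 0x0008L, "IS", "3"))
  expect_error(read_ct_slice(p), "multi-frame")
})

test_that("anisotropic spacing warns and uses the mean pitch", {
  p <- withr::local_tempfile(fileext = ".dcm")
  write_raw_dicom(p, spacing = "0.730000\\0.890000")
  expect_warning(sl <- read_ct_slice(p), "anisotropic")
  expect_equal(sl$pixel_pitch, 0.81, tolerance = 1e-9)
})

test_that("ROI masks read from PNG preserve region structure", {
  sl <- ct_slice(matrix(55, 40, 30), 0.8)
  p <- withr::local_tempfile(fileext = ".png")

  png::writePNG(matrix(1, 40, 30), p)
  expect_true(all(read_roi_mask(p, sl)$mask))

  blobs <- matrix(0, 40, 30)
  blobs[3:8, 3:8] <- 1
  blobs[20:24, 10:14] <- 1
  blobs[35:38, 25:28] <- 1
  png::writePNG(blobs, p)
  m <- read_roi_mask(p, sl)
  expect_identical(sum(m$mask), sum(blobs > 0))
  lab <- hccwave:::.cc_label_8(m$mask)
  expect_identical(attr(lab, "n_components"), 3L)

  png::writePNG(matrix(1, 10, 10), p)
  expect_error(read_roi_mask(p, sl), "shape")
})

test_that("an all-zero mask reads fine but fails at measurement time", {
  sl <- ct_slice(matrix(90, 20, 20), 0.8)
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 20, 20), p)
  m <- read_roi_mask(p, sl)
  expect_false(any(m$mask))
  b <- binarize(sl$pixels, 65, 0.8)
  expect_error(extract_lesions(b, m), "empty ROI")
})

test_that("measurement CSV has a deterministic order with tie-breaks", {
  mk <- function(label, area, row, col) {
    structure(list(label = label, pixel_count = 10L, area_cm2 = area,
                   max_diameter_cm = 1.2, centroid = c(row, col),
                   boundary_pixels = cbind(row, col)),
              class = "lesion_measurement")
  }
  p <- withr::local_tempfile(fileext = ".csv")

  write_measurements(list(), p)
  empty <- read.csv(p)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("source_id", "lesion_index", "area_cm2",
                     "max_diameter_cm", "centroid_row", "centroid_col"))

  write_measurements(list(mk(1, 1.0, 5, 5)), p, source_id = "s1")
  one <- read.csv(p)
  expect_equal(one$area_cm2, 1.0)
  expect_equal(one$max_diameter_cm, 1.2)

  # equal areas: ordered by centroid row, then column
  ms <- list(mk(1, 2.0, 30, 2), mk(2, 2.0, 10, 9), mk(3, 2.0, 10, 4))
  write_measurements(ms, p)
  got <- read.csv(p)
  expect_equal(got$lesion_index, c(3, 2, 1))
})
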