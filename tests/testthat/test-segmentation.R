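test_that("binarization uses a strict greater-than comparison", {
  expect_false(any(binarize(matrix(60, 5, 5), 65, 0.8)$mask))
  expect_true(all(binarize(matrix(90, 5, 5), 65, 0.8)$mask))
  img <- matrix(c(64, 90, 65, 65, 55, 66, 66, 70, 64), 3, 3)
  expected <- matrix(c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                       TRUE, TRUE, FALSE), 3, 3)
  expect_identical(binarize(img, 65, 0.8)$mask, expected)
})

test_that("3x3 erosion and dilation behave per the structuring element", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  single <- binary_image(m, 0.8)
  expect_false(any(erode3x3(single)$mask))
  dil_expected <- matrix(FALSE, 9, 9)
  dil_expected[4:6, 4:6] <- TRUE
  expect_identical(dilate3x3(single)$mask, dil_expected)

  blk <- matrix(FALSE, 9, 9)
  blk[3:7, 3:7] <- TRUE
  er <- erode3x3(binary_image(blk, 0.8))$mask
  expected <- matrix(FALSE, 9, 9)
  expected[4:6, 4:6] <- TRUE
  expect_identical(er, expected)

  # all-ones image: interior survives, 1-pixel border is stripped
  ones <- binary_image(matrix(TRUE, 8, 8), 0.8)
  er1 <- erode3x3(ones)$mask
  expect_true(all(er1[2:7, 2:7]))
  expect_false(any(er1[c(1, 8), ]))
  expect_false(any(er1[, c(1, 8)]))

  expect_false(any(dilate3x3(binary_image(matrix(FALSE, 6, 6), 0.8))$mask))
})

test_that("opening removes specks, preserves blocks and large disks", {
  set.seed(61)
  speck <- matrix(FALSE, 20, 20)
  speck[cbind(sample(2:19, 8), sample(2:19, 8))] <- TRUE
  # isolated single pixels (no 3x3 square anywhere) vanish
  if (!any(erode3x3(binary_image(speck, 0.8))$mask)) {
    expect_false(any(morphological_open(binary_image(speck, 0.8))$mask))
  }

  blk <- matrix(FALSE, 9, 9)
  blk[3:7, 3:7] <- TRUE
  expect_identical(morphological_open(binary_image(blk, 0.8))$mask, blk)

  # disk of diameter 25 px: survives with < 15% pixel change
  rr <- outer((1:40) - 20.5, (1:40) - 20.5, function(a, b) a^2 + b^2)
  disk <- rr <= 12.5^2
  opened <- morphological_open(binary_image(disk, 0.8))$mask
  expect_gt(sum(opened), 0)
  expect_lt(abs(sum(opened) - sum(disk)) / sum(disk), 0.15)
})

test_that("opening is idempotent and anti-extensive on random masks", {
  for (s in 1:5) {
    b <- binary_image(random_blob_mask(30, 30, 0.55, seed = s), 0.8)
    o1 <- morphological_open(b)
    o2 <- morphological_open(o1)
    expect_identical(o2$mask, o1$mask)
    expect_true(all(!o1$mask | b$mask))  # open(b) subset of b
  }
})

test_that("erosion and dilation are dual under complementation", {
  for (s in 1:5) {
    m <- random_blob_mask(25, 25, 0.5, seed = 100 + s)
    b <- binary_image(m, 0.8)
    nb <- binary_image(!m, 0.8)
    # exact duality under the reflect convention
    expect_identical(dilate3x3(b, "reflect")$mask,
                     !erode3x3(nb, "reflect")$mask)
    # under the zero convention the two sides agree away from the border
    d0 <- dilate3x3(b)$mask
    e0 <- !erode3x3(nb)$mask
    expect_identical(d0[2:24, 2:24], e0[2:24, 2:24])
  }
})

test_that("morphology matches an independent image-processing implementation", {
  library(EBImage)
  for (s in 1:3) {
    m <- random_blob_mask(30, 30, 0.5, seed = 200 + s)
    brush <- makeBrush(3, "box")
    expect_identical(erode3x3(binary_image(m, 0.8), "reflect")$mask * 1,
                     erode(Image(m * 1), brush)@.Data)
    expect_identical(dilate3x3(binary_image(m, 0.8), "reflect")$mask * 1,
                     dilate(Image(m * 1), brush)@.Data)
  }
})

test_that("maximum Feret diameter matches the brute-force all-pairs oracle", {
  # single pixel has one-pitch diameter
  expect_equal(max_feret_diameter(cbind(5, 5), 0.8), 0.08)
  # horizontal run of 100 pixels at 0.8 mm: (99 + 1) * 0.8 mm = 8 cm
  run <- cbind(10, 1:100)
  expect_equal(max_feret_diameter(run, 0.8), 8.0)
  expect_equal(feret_bruteforce(run, 0.8), 8.0)

  # rasterized 5 cm disk at 0.8 mm pitch: within 2 pixels of truth
  r_px <- 5 * 10 / 0.8 / 2
  rr <- outer((1:80) - 40.5, (1:80) - 40.5, function(a, b) a^2 + b^2)
  disk <- rr <= r_px^2
  bnd <- which(disk, arr.ind = TRUE)
  expect_equal(max_feret_diameter(bnd, 0.8), 5.0, tolerance = 0.16 / 5)

  for (s in 1:5) {
    m <- random_blob_mask(25, 25, 0.3, seed = 300 + s)
    pts <- which(m, arr.ind = TRUE)
    expect_equal(max_feret_diameter(pts, 0.8), feret_bruteforce(pts, 0.8))
  }
  expect_error(max_feret_diameter(matrix(numeric(), ncol = 2), 0.8), "empty")
})

test_that("lesion extraction uses 8-connectivity inside the ROI", {
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE          # blob inside ROI
  m[12:14, 12:14] <- TRUE      # blob outside ROI
  roi <- matrix(FALSE, 20, 20)
  roi[1:10, 1:10] <- TRUE
  les <- extract_lesions(binary_image(m, 0.8), roi_mask(roi))
  expect_length(les, 1)
  expect_identical(les[[1]]$pixel_count, 9L)
  expect_equal(les[[1]]$area_cm2, 9 * 0.08^2)

  # diagonal chain is one component under 8-connectivity
  dg <- matrix(FALSE, 12, 12)
  dg[cbind(2:7, 2:7)] <- TRUE
  les2 <- extract_lesions(binary_image(dg, 0.8), roi_mask(matrix(TRUE, 12, 12)),
                          min_pixels = 1)
  expect_length(les2, 1)
  expect_identical(les2[[1]]$pixel_count, 6L)

  # two equal blobs: both reported, min_pixels filter drops small residue
  two <- matrix(FALSE, 20, 20)
  two[2:4, 2:5] <- TRUE
  two[10:12, 10:13] <- TRUE
  two[18, 18] <- TRUE
  les3 <- extract_lesions(binary_image(two, 0.8),
                          roi_mask(matrix(TRUE, 20, 20)))
  expect_length(les3, 2)

  expect_error(extract_lesions(binary_image(two, 0.8),
                               roi_mask(matrix(FALSE, 20, 20))), "empty ROI")
})

test_that("lesion measurements satisfy their geometric invariants", {
  set.seed(77)
  m <- random_blob_mask(40, 40, 0.45, seed = 9)
  opened <- morphological_open(binary_image(m, 0.8))
  les <- extract_lesions(opened, roi_mask(matrix(TRUE, 40, 40)),
                         min_pixels = 1)
  for (l in les) {
    expect_gte(l$max_diameter_cm, 0.8 / 10)
    expect_lte(l$area_cm2, l$max_diameter_cm^2)
  }
  # returned in descending pixel-count order
  counts <- vapply(les, `[[`, integer(1), "pixel_count")
  expect_identical(counts, sort(counts, decreasing = TRUE))
})

test_that("pipeline detects a noiseless disk and nothing on a blank phantom", {
  roi <- full_roi()
  ph <- generate_phantom(single_disk_spec(4.0, seed = 5), noiseless = TRUE)
  les <- run_pipeline(ph$slice, roi)
  expect_length(les, 1)
  expect_equal(les[[1]]$max_diameter_cm, 4.0, tolerance = 0.32 / 4)

  blank <- generate_phantom(phantom_spec(seed = 5))
  expect_length(run_pipeline(blank$slice, roi), 0)
})

test_that("raising lesion contrast never shrinks the detected lesion", {
  roi <- full_roi(c(128L, 128L))
  counts <- sapply(c(75, 90, 110), function(mu_c) {
    ts <- tissue_intensity_model(55, 10, mu_c, 11)
    sp <- phantom_spec(field_shape = c(128L, 128L),
                       tissue = ts,
                       lesions = data.frame(center_row = 64.5,
                                            center_col = 64.5,
                                            diameter_cm = 3),
                       seed = 8)
    ph <- generate_phantom(sp, noiseless = TRUE)
    les <- run_pipeline(ph$slice, roi)
    if (length(les) == 0) 0L else les[[1]]$pixel_count
  })
  expect_true(all(diff(counts) >= 0))
})
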