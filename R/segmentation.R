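#' Binary image with physical pixel pitch
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_pitch Pixel pitch in mm.
#' @return Object of class `binary_image`.
#' @export
binary_image <- function(mask, pixel_pitch) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive", call. = FALSE)
  structure(list(mask = mask, pixel_pitch = as.numeric(pixel_pitch)),
            class = "binary_image")
}

#' Threshold an HU image
#'
#' Marks every pixel strictly brighter than the threshold as enhanced
#' tissue candidate.
#'
#' @param image Numeric matrix in HU (typically the approximation-only
#'   reconstruction from [reconstruct_approximation()]).
#' @param threshold HU threshold, usually [binarization_threshold()].
#' @param pixel_pitch Pixel pitch in mm, carried into the result.
#' @return A [binary_image()] with `mask = image > threshold`.
#' @export
binarize <- function(image, threshold, pixel_pitch) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  binary_image(as.matrix(image) > threshold, pixel_pitch)
}

# shift a logical matrix by (dr, dc), filling vacated cells with `fill`
.shift_mask <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  keep_r <- rs >= 1L & rs <= nr
  keep_c <- cs >= 1L & cs <= nc
  out[rs[keep_r], cs[keep_c]] <- m[which(keep_r), which(keep_c)]
  out
}

.morph3x3 <- function(mask, op, boundary_convention) {
  nr <- nrow(mask); nc <- ncol(mask)
  acc <- NULL
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (boundary_convention == "reflect") {
        # out-of-bounds neighbors replaced by the nearest edge pixel
        ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
        ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
        s <- mask[ri, ci, drop = FALSE]
      } else {
        # zero convention: out-of-bounds neighbors are background, which
        # shrinks eroded regions at the image border
        s <- .shift_mask(mask, -dr, -dc, FALSE)
      }
      acc <- if (is.null(acc)) s
             else if (op == "erode") acc & s else acc | s
    }
  }
  acc
}

#' 3x3 binary erosion
#'
#' Standard binary erosion with a 3x3 square structuring element: an output
#' pixel is set iff every pixel in its 3x3 neighborhood is set. Under the
#' default `"zero"` convention, out-of-bounds neighbors count as background,
#' so set regions shrink at the image border; `"reflect"` mirrors the edge
#' pixels instead.
#'
#' @param b A [binary_image()].
#' @param boundary_convention `"zero"` (default) or `"reflect"`.
#' @return Eroded [binary_image()].
#' @export
erode3x3 <- function(b, boundary_convention = c("zero", "reflect")) {
  stopifnot(inherits(b, "binary_image"))
  boundary_convention <- match.arg(boundary_convention)
  binary_image(.morph3x3(b$mask, "erode", boundary_convention),
               b$pixel_pitch)
}

#' 3x3 binary dilation
#'
#' Standard binary dilation with a 3x3 square structuring element: an
#' output pixel is set iff any pixel in its 3x3 neighborhood is set.
#' Out-of-bounds neighbors count as background under the default
#' convention.
#'
#' @inheritParams erode3x3
#' @return Dilated [binary_image()].
#' @export
dilate3x3 <- function(b, boundary_convention = c("zero", "reflect")) {
  stopifnot(inherits(b, "binary_image"))
  boundary_convention <- match.arg(boundary_convention)
  out <- .morph3x3(b$mask, "dilate", boundary_convention)
  binary_image(out, b$pixel_pitch)
}

#' Morphological opening (erosion then dilation)
#'
#' Removes connected components that do not contain a full 3x3 square and
#' smooths object boundaries; this is the cleanup step applied to the
#' binarized image before lesions are measured.
#'
#' @inheritParams erode3x3
#' @return Opened [binary_image()].
#' @export
morphological_open <- function(b, boundary_convention = c("zero", "reflect")) {
  boundary_convention <- match.arg(boundary_convention)
  dilate3x3(erode3x3(b, boundary_convention), boundary_convention)
}

# boundary pixels: set pixels with at least one unset 4-neighbor or on the
# image border; returned as a (row, col) matrix
.boundary_pixels <- function(mask) {
  interior <- .shift_mask(mask, 1L, 0L, FALSE) &
              .shift_mask(mask, -1L, 0L, FALSE) &
              .shift_mask(mask, 0L, 1L, FALSE) &
              .shift_mask(mask, 0L, -1L, FALSE)
  which(mask & !interior, arr.ind = TRUE)
}

#' Maximum Feret diameter of a pixel set
#'
#' Largest caliper distance across the region: the maximum center-to-center
#' Euclidean distance over all boundary-pixel pairs, plus one pixel pitch
#' so that the extent of the two end pixels is counted (a single pixel has
#' diameter one pitch). A convex-hull reduction is applied before the
#' pairwise search; the result is exact because the diameter of a finite
#' point set is attained on its convex hull.
#'
#' @param boundary Two-column matrix of (row, col) pixel coordinates.
#' @param pixel_pitch Pixel pitch in mm.
#' @return Maximum Feret diameter in cm.
#' @export
max_feret_diameter <- function(boundary, pixel_pitch) {
  boundary <- matrix(as.numeric(boundary), ncol = 2L)
  if (nrow(boundary) == 0L) stop("empty pixel set", call. = FALSE)
  pts <- unique(boundary)
  if (nrow(pts) > 3L) {
    hull <- tryCatch(chull(pts[, 2L], pts[, 1L]), error = function(e) NULL)
    if (!is.null(hull) && length(hull) >= 2L) pts <- pts[hull, , drop = FALSE]
  }
  d2max <- 0
  if (nrow(pts) > 1L) {
    dr <- outer(pts[, 1L], pts[, 1L], "-")
    dc <- outer(pts[, 2L], pts[, 2L], "-")
    d2max <- max(dr * dr + dc * dc)
  }
  (sqrt(d2max) + 1) * pixel_pitch / 10
}

#' Extract and measure enhanced lesions
#'
#' Labels the 8-connected components of the opened binary mask restricted
#' to the ROI, discards components smaller than `min_pixels`, and measures
#' each survivor: pixel count, area in cm^2, centroid (1-based row/col
#' pixel coordinates) and maximum Feret diameter.
#'
#' @param b A [binary_image()] (typically after [morphological_open()]).
#' @param roi An [roi_mask()] with at least one set pixel.
#' @param min_pixels Minimum component size in pixels (default 4); smaller
#'   residual specks are discarded.
#' @return List of `lesion_measurement` objects in descending pixel-count
#'   order, each with fields `label`, `pixel_count`, `area_cm2`,
#'   `max_diameter_cm`, `centroid`, `boundary_pixels`.
#' @export
extract_lesions <- function(b, roi, min_pixels = 4L) {
  stopifnot(inherits(b, "binary_image"), inherits(roi, "roi_mask"))
  if (!identical(dim(b$mask), dim(roi$mask))) {
    stop("binary image and ROI mask shapes differ", call. = FALSE)
  }
  if (!any(roi$mask)) {
    stop("empty ROI mask: no pixels available for measurement",
         call. = FALSE)
  }
  mask <- b$mask & roi$mask
  lab <- .cc_label_8(mask)
  k <- attr(lab, "n_components")
  if (k == 0L) return(list())

  counts <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(counts >= min_pixels)
  if (length(keep) == 0L) return(list())

  pitch <- b$pixel_pitch
  out <- lapply(keep, function(comp) {
    cmask <- lab == comp
    idx <- which(cmask, arr.ind = TRUE)
    bnd <- .boundary_pixels(cmask)
    structure(
      list(label = comp,
           pixel_count = counts[comp],
           area_cm2 = counts[comp] * (pitch / 10)^2,
           max_diameter_cm = max_feret_diameter(bnd, pitch),
           centroid = c(mean(idx[, 1L]), mean(idx[, 2L])),
           boundary_pixels = bnd),
      class = "lesion_measurement"
    )
  })
  out[order(-vapply(out, `[[`, numeric(1), "pixel_count"))]
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf(
    "<lesion %d> %d px, area %.2f cm^2, max diameter %.2f cm, centroid (%.1f, %.1f)\n",
    x$label, x$pixel_count, x$area_cm2, x$max_diameter_cm,
    x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Full lesion detection and measurement pipeline
#'
#' Runs the optimized measurement chain on one slice: level-J wavelet
#' decomposition and approximation-only reconstruction (noise
#' suppression), binarization at `mu_normal + threshold_sd_multiplier *
#' sd_normal`, 3x3 morphological opening, 8-connected component extraction
#' within the ROI, and per-lesion maximum Feret diameter.
#'
#' @param slice A [ct_slice()].
#' @param roi An [roi_mask()] matching the slice.
#' @param model A [tissue_intensity_model()]; defaults to the reference
#'   arterial-phase model (normal 55 +/- 10 HU).
#' @param mra An [mra_config()]; defaults to the 10-tap Daubechies wavelet
#'   at level 2 with symmetric boundaries.
#' @param threshold_sd_multiplier SDs of normal tissue added to the normal
#'   mean to form the threshold (default 1, i.e. 65 HU for the reference
#'   model; 0 thresholds at the normal mean alone).
#' @param min_pixels Minimum lesion size in pixels after opening.
#' @param boundary_convention Morphology border handling, see [erode3x3()].
#' @return List of lesion measurements, largest (by pixel count) first.
#' @export
run_pipeline <- function(slice, roi, model = default_model(),
                         mra = mra_config(), threshold_sd_multiplier = 1,
                         min_pixels = 4L,
                         boundary_convention = c("zero", "reflect")) {
  stopifnot(inherits(slice, "ct_slice"), inherits(roi, "roi_mask"))
  boundary_convention <- match.arg(boundary_convention)
  if (!identical(dim(slice$pixels), dim(roi$mask))) {
    stop("slice and ROI mask shapes differ", call. = FALSE)
  }
  smoothed <- reconstruct_approximation(decompose(slice$pixels, mra))
  thr <- binarization_threshold(model, threshold_sd_multiplier)
  bin <- binarize(smoothed, thr, slice$pixel_pitch)
  opened <- morphological_open(bin, boundary_convention)
  extract_lesions(opened, roi, min_pixels = min_pixels)
}
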