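#' CT slice in Hounsfield units
#'
#' Container for a single CT slice: a rectangular matrix of attenuation
#' values in Hounsfield units (HU) plus the physical pixel pitch. All
#' downstream processing (denoising, thresholding, measurement) consumes
#' this type, so pixel values must already be rescaled to HU.
#'
#' @param pixels Numeric matrix of HU values; must be finite.
#' @param pixel_pitch Physical pixel spacing in mm (scalar, isotropic).
#' @param source_id Free-text provenance label.
#' @return An object of class `ct_slice` with fields `pixels`,
#'   `pixel_pitch` and `source_id`.
#' @export
ct_slice <- function(pixels, pixel_pitch, source_id = "unknown") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || !all(is.finite(pixels))) {
    stop("pixels must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L ||
      !is.finite(pixel_pitch) || pixel_pitch <= 0) {
    stop("pixel_pitch must be a single positive number (mm)", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_pitch = as.numeric(pixel_pitch),
         source_id = as.character(source_id)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, pitch %.3f mm, source '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch, x$source_id))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Binary mask delimiting the liver (or any region in which lesions are to
#' be measured) on a given slice. The mask must match the slice shape; an
#' all-false mask is legal to hold but rejected when measurement is
#' attempted.
#'
#' @param mask Logical (or coercible 0/1) matrix.
#' @param slice Optional [ct_slice()] to validate the shape against.
#' @return Object of class `roi_mask` wrapping a logical matrix.
#' @export
roi_mask <- function(mask, slice = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (!is.null(slice)) {
    if (!identical(dim(mask), dim(slice$pixels))) {
      stop(sprintf("ROI mask shape %dx%d does not match slice shape %dx%d",
                   nrow(mask), ncol(mask), nrow(slice$pixels),
                   ncol(slice$pixels)), call. = FALSE)
    }
  }
  structure(list(mask = mask), class = "roi_mask")
}

#' Read a single-frame CT DICOM file
#'
#' Reads a single-frame CT image stored as Explicit VR Little Endian DICOM
#' and converts stored pixel values to Hounsfield units using the file's
#' rescale slope and intercept. The pixel pitch is taken from the
#' PixelSpacing attribute; when the row and column spacings differ, their
#' arithmetic mean is used and a warning is emitted (downstream geometry
#' assumes isotropic pixels).
#'
#' @param path Path to the DICOM file.
#' @return A [ct_slice()].
#' @export
read_ct_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  elems <- .dicom_read_file(path)

  nframes <- elems[["0028,0008"]]
  if (!is.null(nframes)) {
    nf <- suppressWarnings(as.integer(.raw_to_str(nframes$value)))
    if (!is.na(nf) && nf > 1L) {
      stop("multi-frame DICOM input is not supported (NumberOfFrames = ",
           nf, ")", call. = FALSE)
    }
  }

  need <- function(key, name) {
    el <- elems[[key]]
    if (is.null(el)) {
      stop("missing required DICOM attribute ", name, " (", key, ")",
           call. = FALSE)
    }
    el
  }
  rows <- .u16(need("0028,0010", "Rows")$value)
  cols <- .u16(need("0028,0011", "Columns")$value)
  spacing <- as.numeric(strsplit(.raw_to_str(
    need("0028,0030", "PixelSpacing")$value), "\\\\")[[1]])
  intercept <- as.numeric(.raw_to_str(
    need("0028,1052", "RescaleIntercept")$value))
  slope <- as.numeric(.raw_to_str(need("0028,1053", "RescaleSlope")$value))
  pix_el <- need("7FE0,0010", "PixelData")

  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (abs(spacing[1] - spacing[2]) > 1e-9) {
    warning(sprintf(
      "anisotropic pixel spacing %.4g x %.4g mm; using mean %.4g mm",
      spacing[1], spacing[2], mean(spacing)), call. = FALSE)
  }
  pitch <- mean(spacing)

  pixrep <- elems[["0028,0103"]]
  signed <- !is.null(pixrep) && .u16(pixrep$value) == 1L
  stored <- readBin(pix_el$value, "integer", n = rows * cols, size = 2L,
                    endian = "little", signed = signed)
  hu <- slope * stored + intercept
  pixels <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)

  ct_slice(pixels, pitch, source_id = basename(path))
}

#' Write a CT slice as single-frame DICOM
#'
#' Inverse of [read_ct_slice()] for the package's Explicit VR Little Endian
#' dialect. Pixels are stored as unsigned 16-bit with rescale slope 1 and
#' intercept -1024, so HU values must be integers in `[-1024, 64511]` for an
#' exact round trip.
#'
#' @param slice A [ct_slice()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  intercept <- -1024
  stored <- round(slice$pixels - intercept)
  if (any(stored < 0 | stored > 65535)) {
    stop("HU values outside storable range [-1024, 64511]", call. = FALSE)
  }
  px <- as.integer(t(stored))  # DICOM is row-major
  spacing <- sprintf("%.6f\\%.6f", slice$pixel_pitch, slice$pixel_pitch)
  elements <- c(
    .dicom_str(0x0008L, 0x0060L, "CS", "CT"),
    .dicom_us(0x0028L, 0x0002L, 1L),
    .dicom_us(0x0028L, 0x0010L, nrow(slice$pixels)),
    .dicom_us(0x0028L, 0x0011L, ncol(slice$pixels)),
    .dicom_str(0x0028L, 0x0030L, "DS", spacing),
    .dicom_us(0x0028L, 0x0100L, 16L),
    .dicom_us(0x0028L, 0x0101L, 16L),
    .dicom_us(0x0028L, 0x0102L, 15L),
    .dicom_us(0x0028L, 0x0103L, 0L),
    .dicom_str(0x0028L, 0x1052L, "DS", as.character(intercept)),
    .dicom_str(0x0028L, 0x1053L, "DS", "1"),
    .dicom_element(0x7FE0L, 0x0010L, "OW", .raw_u16(px))
  )
  .dicom_write_file(path, elements)
}

#' Read an ROI mask from an image file
#'
#' Accepts PNG or TIFF; any nonzero pixel (in any channel) marks the inside
#' of the region. The mask shape is validated against the slice.
#'
#' @param path Path to a PNG or TIFF mask image.
#' @param slice The [ct_slice()] the mask belongs to.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path, slice) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  roi_mask(img > 0, slice = slice)
}

#' Write lesion measurements to CSV
#'
#' Writes one row per lesion with columns `source_id`, `lesion_index`,
#' `area_cm2`, `max_diameter_cm`, `centroid_row`, `centroid_col` (1-based
#' pixel coordinates). Rows are ordered by descending area; ties broken by
#' centroid row, then column. An empty measurement list yields a header-only
#' file.
#'
#' @param measurements List of lesion measurements from [extract_lesions()]
#'   or [run_pipeline()].
#' @param path Output CSV path.
#' @param source_id Provenance label written in the first column.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path, source_id = "unknown") {
  df <- measurements_to_df(measurements, source_id)
  tryCatch(
    write.csv(df, path, row.names = FALSE),
    error = function(e) stop("cannot write measurements to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Convert a lesion measurement list to a data frame
#'
#' Applies the deterministic ordering used by [write_measurements()]:
#' descending area, ties broken by centroid row then column.
#'
#' @inheritParams write_measurements
#' @return A data frame with one row per lesion.
#' @export
measurements_to_df <- function(measurements, source_id = "unknown") {
  if (length(measurements) == 0L) {
    return(data.frame(source_id = character(), lesion_index = integer(),
                      area_cm2 = numeric(), max_diameter_cm = numeric(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  df <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(source_id = source_id, lesion_index = m$label,
               area_cm2 = m$area_cm2, max_diameter_cm = m$max_diameter_cm,
               centroid_row = m$centroid[1], centroid_col = m$centroid[2])
  }))
  ord <- order(-df$area_cm2, df$centroid_row, df$centroid_col)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
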