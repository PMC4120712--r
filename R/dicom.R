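# Minimal single-frame DICOM codec (Explicit VR Little Endian only).
# Covers the subset of the standard needed to exchange CT slices: file
# preamble, file meta group, and the data-set attributes that carry pixel
# geometry, rescale and pixel data. Not a general DICOM implementation.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit form uses a 2-byte reserved field + 4-byte length
.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(raw2) {
  readBin(raw2, "integer", n = 1L, size = 2L, endian = "little", signed = FALSE)
}

.u32 <- function(raw4) {
  lo <- .u16(raw4[1:2])
  hi <- .u16(raw4[3:4])
  hi * 65536 + lo
}

.raw_u16 <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

# One explicit-VR element as a raw vector; value already raw, padded to even
.dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% .vr_long) {
    len <- writeBin(length(value_raw), raw(), size = 4L, endian = "little")
    head <- c(head, as.raw(c(0L, 0L)), len)
  } else {
    head <- c(head, .raw_u16(length(value_raw)))
  }
  c(head, value_raw)
}

.dicom_str <- function(group, elem, vr, s) {
  .dicom_element(group, elem, vr, charToRaw(s))
}

.dicom_us <- function(group, elem, x) {
  .dicom_element(group, elem, "US", .raw_u16(x))
}

# Parse the full element stream of `bytes` starting at offset `pos` (1-based).
# Returns a list keyed by "gggg,eeee" with raw values (group 0002 skipped by
# caller if desired); errors on undefined lengths (sequences not supported).
.dicom_parse <- function(bytes, pos) {
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- .u16(bytes[pos:(pos + 1L)])
    elem <- .u16(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported DICOM encoding (implicit VR or corrupt element at byte ",
           pos, ")", call. = FALSE)
    }
    if (vr %in% .vr_long) {
      len <- .u32(bytes[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else {
      len <- .u16(bytes[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    }
    if (len == 4294967295) {
      stop("undefined-length DICOM element (", sprintf("%04X,%04X", group, elem),
           ") not supported", call. = FALSE)
    }
    if (pos + len - 1L > n) {
      stop("truncated DICOM element (", sprintf("%04X,%04X", group, elem), ")",
           call. = FALSE)
    }
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, value = if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
  }
  out
}

# DICOM string values carry space/NUL padding; drop it before decoding
.raw_to_str <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

.dicom_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  }
  elems <- .dicom_parse(bytes, pos)
  ts <- elems[["0002,0010"]]
  if (!is.null(ts)) {
    uid <- .raw_to_str(ts$value)
    if (uid != DICOM_EXPLICIT_LE) {
      stop("unsupported DICOM transfer syntax: ", uid, call. = FALSE)
    }
  }
  elems
}

.dicom_write_file <- function(path, elements) {
  meta <- c(
    .dicom_str(0x0002L, 0x0010L, "UI", DICOM_EXPLICIT_LE)
  )
  group_len <- .dicom_element(0x0002L, 0x0000L, "UL",
                              writeBin(length(meta), raw(), size = 4L,
                                       endian = "little"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, elements), con)
  invisible(path)
}
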