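# 2-D discrete wavelet multiresolution analysis (MRA).
#
# Separable orthogonal DWT: per level, 1-D low/high-pass filtering with
# decimation is applied along the horizontal direction, then the vertical,
# giving one approximation quadrant and three detail quadrants oriented at
# 0 (vertical edges), 90 (horizontal edges) and 45 degrees. Analysis uses
# inner products with the translated filters; synthesis is the adjoint
# (overlap-add of the upsampled coefficients), which gives exact
# reconstruction for every image size and boundary mode because boundary
# coefficients are retained redundantly under padded modes.

# Orthonormal scaling filters (classical order; published Daubechies values)
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
           0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
           -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
           0.0036065535669561697, -0.010733175483330575,
           0.001395351747052901, 0.001992405295185056,
           -0.0006858566949597116, -0.00011646685512928545,
           9.358867032006959e-05, -1.3264202894521244e-05)
)

.get_filters <- function(wavelet_name) {
  h <- .wavelet_filters[[wavelet_name]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet_name, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror high-pass
  list(h = h, g = g, L = L)
}

#' Multiresolution analysis configuration
#'
#' @param wavelet_name Mother wavelet identifier; one of `"haar"`, `"db5"`
#'   (the 10-tap Daubechies wavelet, the default used throughout the
#'   pipeline) or `"db10"` (20-tap).
#' @param pseudo_frequency Characteristic frequency of the mother wavelet in
#'   cycles/sample, used only by [band_center_frequency()] for reporting
#'   which spatial-frequency band a level captures; it does not affect
#'   filtering. The default 0.693 is the published value for the 10-tap
#'   Daubechies wavelet. Values above 0.5 cycles/sample exceed the Nyquist
#'   rate and are characteristic of short Daubechies filters.
#' @param level Decomposition depth J (>= 1); default 2.
#' @param boundary_mode `"symmetric"` (half-sample reflection, default;
#'   minimizes edge artifacts) or `"periodic"` (circular; non-redundant and
#'   exactly energy-preserving, but requires dimensions divisible by 2^J).
#' @return Object of class `mra_config`.
#' @export
mra_config <- function(wavelet_name = "db5", pseudo_frequency = 0.693,
                       level = 2L, boundary_mode = "symmetric") {
  .get_filters(wavelet_name)  # validates the name
  if (!is.numeric(level) || level < 1L || level != round(level)) {
    stop("level must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(pseudo_frequency) || pseudo_frequency <= 0 ||
      pseudo_frequency >= 1) {
    stop("pseudo_frequency must lie in (0, 1) cycles/sample", call. = FALSE)
  }
  boundary_mode <- match.arg(boundary_mode, c("symmetric", "periodic"))
  structure(
    list(wavelet_name = wavelet_name,
         pseudo_frequency = pseudo_frequency,
         level = as.integer(level),
         boundary_mode = boundary_mode),
    class = "mra_config"
  )
}

# ---- 1-D building blocks (vectorized over the columns of a matrix) ----

.pad_cols <- function(x, L, mode) {
  n <- nrow(x)
  if (mode == "symmetric") {
    if (n >= L - 1L) {
      top <- x[(L - 1L):1L, , drop = FALSE]
      bot <- x[n:(n - L + 2L), , drop = FALSE]
    } else {
      # whole-signal reflections tiled until the pad is long enough
      idx <- seq_len(n)
      refl <- c(rev(idx), idx)
      top <- x[rep(refl, length.out = L - 1L)[(L - 1L):1L], , drop = FALSE]
      bot <- x[rep(refl, length.out = L - 1L), , drop = FALSE]
    }
    rbind(top, x, bot)
  } else {  # periodic
    rbind(x, x[rep_len(seq_len(n), L - 2L), , drop = FALSE])
  }
}

# analysis along columns: a_i = sum_j f[j] x_ext[2(i-1)+j]
.dwt_cols <- function(x, h, g, mode) {
  L <- length(h)
  n <- nrow(x)
  if (mode == "periodic" && n %% 2L != 0L) {
    stop("periodic boundary mode requires even dimensions", call. = FALSE)
  }
  ext <- .pad_cols(x, L, mode)
  M <- if (mode == "periodic") n %/% 2L else (nrow(ext) - L) %/% 2L + 1L
  a <- matrix(0, M, ncol(x))
  d <- matrix(0, M, ncol(x))
  for (j in seq_len(L)) {
    rows <- seq.int(j, by = 2L, length.out = M)
    a <- a + h[j] * ext[rows, , drop = FALSE]
    d <- d + g[j] * ext[rows, , drop = FALSE]
  }
  list(a = a, d = d)
}

# synthesis along columns (adjoint of .dwt_cols), cropped to n rows
.idwt_cols <- function(a, d, h, g, mode, n) {
  L <- length(h)
  M <- nrow(a)
  next_len <- 2L * (M - 1L) + L
  y <- matrix(0, next_len, ncol(a))
  for (j in seq_len(L)) {
    rows <- seq.int(j, by = 2L, length.out = M)
    y[rows, ] <- y[rows, , drop = FALSE] + h[j] * a + g[j] * d
  }
  if (mode == "symmetric") {
    y[L:(L - 1L + n), , drop = FALSE]
  } else {  # periodic: wrap the tail back onto the head
    out <- y[seq_len(n), , drop = FALSE]
    tail_len <- next_len - n
    if (tail_len > 0L) {
      wrap <- y[(n + 1L):next_len, , drop = FALSE]
      idx <- rep_len(seq_len(n), tail_len)
      for (k in seq_len(tail_len)) out[idx[k], ] <- out[idx[k], ] + wrap[k, ]
    }
    out
  }
}

# one 2-D analysis level: horizontal filtering/decimation, then vertical
.analysis_step <- function(x, f, mode) {
  horiz <- .dwt_cols(t(x), f$h, f$g, mode)
  Lh <- t(horiz$a)
  Hh <- t(horiz$d)
  vl <- .dwt_cols(Lh, f$h, f$g, mode)
  vh <- .dwt_cols(Hh, f$h, f$g, mode)
  list(LL = vl$a,
       d90 = vl$d,   # low horizontal / high vertical: horizontal edges
       d0 = vh$a,    # high horizontal / low vertical: vertical edges
       d45 = vh$d)   # high/high: diagonal structure
}

.synthesis_step <- function(LL, d0, d90, d45, f, mode, shape) {
  Lh <- .idwt_cols(LL, d90, f$h, f$g, mode, shape[1])
  Hh <- .idwt_cols(d0, d45, f$h, f$g, mode, shape[1])
  t(.idwt_cols(t(Lh), t(Hh), f$h, f$g, mode, shape[2]))
}

#' Decompose an image by wavelet multiresolution analysis
#'
#' Runs `config$level` levels of the separable 2-D DWT. Each level yields
#' three detail quadrants (orientations 0, 90 and 45 degrees) and passes
#' its approximation on to the next level. The decomposition is lossless:
#' [reconstruct()] recovers the input to machine precision.
#'
#' @param image Numeric matrix (HU values).
#' @param config An [mra_config()].
#' @return Object of class `mra_decomposition` with fields `approximation`
#'   (level-J approximation plane), `details` (list of J levels, each with
#'   planes `d0`, `d90`, `d45`), `config`, `original_shape` and the
#'   per-level input shapes used for reconstruction.
#' @export
decompose <- function(image, config = mra_config()) {
  stopifnot(inherits(config, "mra_config"))
  image <- as.matrix(image)
  J <- config$level
  min_dim <- min(dim(image))
  if (min_dim < 2^J) {
    stop("image too small for level ", J, "; maximum feasible level is ",
         max(0L, floor(log2(min_dim))), call. = FALSE)
  }
  f <- .get_filters(config$wavelet_name)
  mode <- config$boundary_mode

  details <- vector("list", J)
  shapes <- vector("list", J)
  a <- image
  for (j in seq_len(J)) {
    shapes[[j]] <- dim(a)
    step <- .analysis_step(a, f, mode)
    details[[j]] <- step[c("d0", "d90", "d45")]
    a <- step$LL
  }
  structure(
    list(approximation = a, details = details, config = config,
         original_shape = dim(image), level_shapes = shapes),
    class = "mra_decomposition"
  )
}

#' @export
print.mra_decomposition <- function(x, ...) {
  cat(sprintf("<mra_decomposition> %s, J = %d, %s boundary, input %d x %d\n",
              x$config$wavelet_name, x$config$level, x$config$boundary_mode,
              x$original_shape[1], x$original_shape[2]))
  invisible(x)
}

#' Invert a wavelet decomposition
#'
#' @param decomp An `mra_decomposition`.
#' @param keep_details Logical; when `FALSE` all detail planes are zeroed,
#'   giving the approximation-only (denoised) reconstruction.
#' @return Numeric matrix with the original image shape.
#' @export
reconstruct <- function(decomp, keep_details = TRUE) {
  stopifnot(inherits(decomp, "mra_decomposition"))
  f <- .get_filters(decomp$config$wavelet_name)
  mode <- decomp$config$boundary_mode
  a <- decomp$approximation
  for (j in rev(seq_len(decomp$config$level))) {
    d <- decomp$details[[j]]
    if (keep_details) {
      a <- .synthesis_step(a, d$d0, d$d90, d$d45, f, mode,
                           decomp$level_shapes[[j]])
    } else {
      z <- matrix(0, nrow(d$d0), ncol(d$d0))
      a <- .synthesis_step(a, z, z, z, f, mode, decomp$level_shapes[[j]])
    }
  }
  a
}

#' Approximation-only reconstruction (wavelet denoising)
#'
#' Inverts the decomposition with every detail plane at levels `1..J`
#' zeroed, retaining only the level-J approximation. This suppresses
#' small-scale intensity fluctuations (noise) while preserving structures
#' larger than the level-J band, and is the image handed to binarization in
#' the lesion pipeline.
#'
#' @param decomp An `mra_decomposition`.
#' @return Smoothed numeric matrix with the original image shape.
#' @export
reconstruct_approximation <- function(decomp) {
  reconstruct(decomp, keep_details = FALSE)
}

#' Center spatial frequency of a wavelet band
#'
#' Maps the mother wavelet's pseudo-frequency (cycles/sample) to the
#' physical center frequency of the level-`s` band for a given pixel pitch:
#' `pseudo_frequency / (2^s * pixel_pitch)`, in mm^-1. With the 10-tap
#' Daubechies pseudo-frequency 0.693 and a 0.80 mm pitch, the level-2 band
#' is centered near 0.22 mm^-1 (the value is a spatial frequency even
#' though band sizes are often quoted loosely in mm).
#'
#' @param pseudo_frequency Mother-wavelet pseudo-frequency in cycles/sample.
#' @param level Decomposition level s (0 = the sampling band itself).
#' @param pixel_pitch Pixel pitch in mm.
#' @return Spatial frequency in mm^-1.
#' @export
band_center_frequency <- function(pseudo_frequency, level, pixel_pitch) {
  if (pseudo_frequency <= 0 || pixel_pitch <= 0 || level < 0) {
    stop("pseudo_frequency and pixel_pitch must be positive, level >= 0",
         call. = FALSE)
  }
  pseudo_frequency / (2^level * pixel_pitch)
}
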