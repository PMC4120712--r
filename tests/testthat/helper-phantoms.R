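# shared fixture builders (everything is generated in code at test time)

full_roi <- function(shape = c(256L, 512L)) {
  roi_mask(matrix(TRUE, shape[1], shape[2]))
}

single_disk_spec <- function(diameter_cm, seed = 1L,
                             shape = c(256L, 512L), pitch = 0.80) {
  phantom_spec(
    field_shape = shape, pixel_pitch = pitch,
    lesions = data.frame(center_row = (shape[1] + 1) / 2,
                         center_col = (shape[2] + 1) / 2,
                         diameter_cm = diameter_cm),
    seed = seed)
}

# brute-force all-pairs maximum Feret diameter (independent oracle)
feret_bruteforce <- function(boundary, pitch) {
  boundary <- matrix(as.numeric(boundary), ncol = 2)
  d2 <- 0
  n <- nrow(boundary)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      dr <- boundary[(i + 1):n, 1] - boundary[i, 1]
      dc <- boundary[(i + 1):n, 2] - boundary[i, 2]
      d2 <- max(d2, max(dr * dr + dc * dc))
    }
  }
  (sqrt(d2) + 1) * pitch / 10
}

random_blob_mask <- function(nr, nc, p = 0.5, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}
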