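# Shared fixtures, all built in code.

# Rasterized disk mask/label matrix.
raster_disk <- function(size, radius, value = 1L) {
  c0 <- (size + 1) / 2
  gx <- outer(seq_len(size), rep(1, size)) - c0
  gy <- outer(rep(1, size), seq_len(size)) - c0
  matrix(as.integer(sqrt(gx^2 + gy^2) <= radius) * value, size, size)
}

# Rasterized (possibly rotated) ellipse label matrix.
raster_ellipse_img <- function(size, a, b, theta = 0, value = 1L) {
  c0 <- (size + 1) / 2
  gx <- outer(seq_len(size), rep(1, size)) - c0
  gy <- outer(rep(1, size), seq_len(size)) - c0
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1) * value, size, size)
}

# Default reference set and windows reused across Raman tests.
test_refs <- make_reference_set(seed = 1L)
test_windows <- band_windows()

# Write text lines to a temp file, returning its path.
write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
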