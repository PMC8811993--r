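#' Grayscale image containers and input/output
#'
#' All imaging operators in this package work on plain numeric matrices
#' holding 8-bit intensities in `[0, 255]`, row = image row, column = image
#' column, origin at the top-left. Coordinates are given as `(row, col)` and
#' are 1-based, following R's matrix indexing.
#'
#' @param x a numeric matrix, or an array with a trailing channel dimension
#'   (converted to luminance with Rec. 601 weights).
#' @return `as_gray_image()` returns a numeric matrix with values clamped to
#'   `[0, 255]`.
#' @examples
#' img <- as_gray_image(matrix(runif(64, 0, 255), 8, 8))
#' range(img)
#' @export
as_gray_image <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    x <- if (nc >= 3L) {
      0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x[, , 1L]
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix")
  }
  if (any(!is.finite(x))) stop("gray image contains non-finite values")
  clamp255(x)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# round + clamp: the 8-bit quantization applied whenever a frame is "stored"
quantize8 <- function(x) clamp255(round(x))

#' Read and write 8-bit grayscale images
#'
#' Thin wrappers around \pkg{png} and \pkg{tiff} dispatching on the file
#' extension. Images on disk are stored in the usual `[0, 1]` range and are
#' rescaled to `[0, 255]` on read; colour inputs are collapsed to luminance.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img numeric matrix in `[0, 255]` (rounded to 8 bits on write).
#' @return `read_gray()` returns a numeric matrix in `[0, 255]`;
#'   `write_gray()` returns `path` invisibly.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (use png/tif/tiff)")
  )
  as_gray_image(raw * 255)
}

#' @rdname read_gray
#' @export
write_gray <- function(img, path) {
  img <- quantize8(as_gray_image(img)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: '", ext, "' (use png/tif/tiff)")
  )
  invisible(path)
}

# Bilinear sampling of img at (possibly fractional) coordinates; out-of-field
# positions take `fill`. r and c are equal-length vectors or matrices.
bilinear_sample <- function(img, r, c, fill = 0) {
  n <- nrow(img)
  m <- ncol(img)
  dm <- dim(r)
  r <- as.vector(r)
  c <- as.vector(c)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    v <- rep.int(fill, length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
  if (!is.null(dm)) dim(v) <- dm
  v
}

#' Apply a rigid transform to an image
#'
#' Applies the motion "rotate by `rotation` degrees about the image centre,
#' then translate by `(dy, dx)` pixels" and resamples bilinearly. Pixels
#' mapped from outside the field are filled with `fill`.
#'
#' @param img numeric matrix.
#' @param rotation rotation in degrees (positive = row axis towards column
#'   axis).
#' @param dy,dx translation in pixels along rows and columns.
#' @param fill value for out-of-field pixels.
#' @return transformed numeric matrix of the same shape.
#' @export
warp_rigid <- function(img, rotation = 0, dy = 0, dx = 0, fill = 0) {
  n <- nrow(img)
  m <- ncol(img)
  cr <- (n + 1) / 2
  cc <- (m + 1) / 2
  th <- rotation * pi / 180
  co <- cos(th)
  si <- sin(th)
  qr <- matrix(seq_len(n), n, m) - cr - dy
  qc <- matrix(seq_len(m), n, m, byrow = TRUE) - cc - dx
  # inverse rotation takes output coords back to source coords
  pr <- co * qr + si * qc + cr
  pc <- -si * qr + co * qc + cc
  bilinear_sample(img, pr, pc, fill)
}

# compose: translation expressed after rotating by `rotation` degrees
rotate_vec <- function(v, rotation) {
  th <- rotation * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}
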