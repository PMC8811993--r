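#' Rigid alignment of the 5-min frame onto the 1-min frame
#'
#' Estimates the rigid motion (rotation about the image centre plus
#' translation) between the early reference frame and the late moving frame,
#' and resamples the moving frame into the reference coordinate system. The
#' early frame is the reference because the leakage map is defined as the
#' late frame minus the early frame.
#'
#' Registration is dense and Fourier-based: both frames are Hann-windowed and
#' the translation is read off the phase-correlation peak (with parabolic
#' sub-pixel refinement). Rotation is found by maximising the
#' phase-correlation peak height over a coarse grid of candidate angles
#' (evaluated at half resolution) followed by golden-section refinement at
#' full resolution. When the best peak is weaker than `min_quality` the two
#' frames share too little structure and an alignment failure is raised;
#' callers may catch it and fall back to the identity transform.
#'
#' @param reference_1min,moving_5min numeric matrices of identical shape.
#' @param max_rotation search half-range for rotation, degrees. `0` skips the
#'   rotation search (translation-only registration).
#' @param rotation_step coarse grid step, degrees.
#' @param min_quality minimum acceptable phase-correlation peak height
#'   (1 for identical images, near 0 for unrelated ones).
#' @return a list with `aligned` (the resampled 5-min frame, out-of-field
#'   pixels 0) and `transform`, itself a list with `rotation` (degrees),
#'   `translation` (`c(dy, dx)` pixels) and `quality` (peak height).
#' @export
align_pair <- function(reference_1min, moving_5min, max_rotation = 2,
                       rotation_step = 0.5, min_quality = 0.01) {
  if (!all(dim(reference_1min) == dim(moving_5min))) {
    stop("frames must have identical shape")
  }
  ref <- as_gray_image(reference_1min)
  mov <- as_gray_image(moving_5min)
  wref <- hann_window(ref)

  peak_for <- function(rot, ref_w, mov_img) {
    m <- if (rot != 0) warp_rigid(mov_img, rotation = -rot) else mov_img
    phase_correlate(ref_w, hann_window(m))
  }

  rot <- 0
  if (max_rotation > 0) {
    # coarse grid at half resolution, then golden-section at full resolution
    ref_s <- downscale2(ref)
    mov_s <- downscale2(mov)
    wref_s <- hann_window(ref_s)
    grid <- seq(-max_rotation, max_rotation, by = rotation_step)
    qual <- vapply(grid, function(g) peak_for(g, wref_s, mov_s)$peak,
                   numeric(1))
    best <- grid[which.max(qual)]
    lo <- max(best - rotation_step, -max_rotation)
    hi <- min(best + rotation_step, max_rotation)
    opt <- stats::optimize(function(g) peak_for(g, wref, mov)$peak,
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 0.01)
    rot <- if (opt$objective >= peak_for(best, wref, mov)$peak) opt$maximum else best
    if (abs(rot) < 0.02) rot <- 0
  }

  pc <- peak_for(rot, wref, mov)
  if (!is.finite(pc$peak) || pc$peak < min_quality) {
    stop("alignment failure: phase-correlation peak ",
         formatC(pc$peak, digits = 3, format = "g"),
         " below quality floor ", min_quality)
  }
  # un-rotating the moving frame leaves a residual shift s with
  # mov_unrot(q) = scene(q - s); the motion's translation is R(rot) s
  s <- pc$shift
  tr <- rotate_vec(s, rot)
  inv_t <- -rotate_vec(tr, -rot)
  aligned <- warp_rigid(mov, rotation = -rot, dy = inv_t[1], dx = inv_t[2])
  list(
    aligned = clamp255(aligned),
    transform = list(rotation = rot, translation = tr, quality = pc$peak)
  )
}

# Phase correlation: returns the translation t (c(dy, dx)) such that
# mov(q) = ref(q - t), plus the normalized correlation peak height.
phase_correlate <- function(ref, mov) {
  n <- nrow(ref)
  m <- ncol(ref)
  fr <- stats::fft(ref)
  fm <- stats::fft(mov)
  cross <- fr * Conj(fm)
  cross <- cross / pmax(Mod(cross), 1e-12)
  cc <- Re(stats::fft(cross, inverse = TRUE)) / (n * m)
  idx <- arrayInd(which.max(cc), dim(cc))
  peak <- cc[idx]
  # wrap indices into signed shifts; peak sits at -t
  wrap <- function(i, size) ifelse(i - 1 > size / 2, i - 1 - size, i - 1)
  dr <- wrap(idx[1], n)
  dc <- wrap(idx[2], m)
  sub <- function(i, size, along_row) {
    at <- function(k) {
      k <- ((k - 1) %% size) + 1
      if (along_row) cc[k, idx[2]] else cc[idx[1], k]
    }
    y0 <- at(i - 1)
    y1 <- at(i)
    y2 <- at(i + 1)
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  dr <- dr + sub(idx[1], n, TRUE)
  dc <- dc + sub(idx[2], m, FALSE)
  list(shift = c(-dr, -dc), peak = peak)
}

hann_window <- function(img) {
  n <- nrow(img)
  m <- ncol(img)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  img * outer(wr, wc)
}

downscale2 <- function(img) {
  n <- 2L * (nrow(img) %/% 2L)
  m <- 2L * (ncol(img) %/% 2L)
  x <- img[seq_len(n), seq_len(m), drop = FALSE]
  0.25 * (x[seq(1, n, 2), seq(1, m, 2)] + x[seq(2, n, 2), seq(1, m, 2)] +
          x[seq(1, n, 2), seq(2, m, 2)] + x[seq(2, n, 2), seq(2, m, 2)])
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the surface
#' traced by a ball of the given radius rolled under the intensity landscape
#' (a grayscale opening by a ball-shaped, non-flat structuring element) and
#' subtracts it. For radii above 10 px the classical
#' shrink--smooth--roll--expand approximation is used: the image is smoothed
#' with a 3x3 mean filter, reduced by block minima, the ball is rolled on the
#' reduced image, and the background is expanded back by bilinear
#' interpolation and clamped into `[0, img]` so the subtraction can never
#' push a pixel below zero.
#'
#' @param img numeric matrix, intensities in `[0, 255]`.
#' @param radius_px ball radius in pixels (default 50).
#' @return background-subtracted image, 8-bit quantized; never exceeds the
#'   input pixelwise.
#' @export
rolling_ball_subtract <- function(img, radius_px = 50L) {
  img <- as_gray_image(img)
  if (radius_px < 1) stop("radius_px must be >= 1")
  bg <- rolling_ball_background(img, radius_px)
  quantize8(img - bg)
}

rolling_ball_background <- function(img, radius_px) {
  shrink <- if (radius_px <= 10) 1L
            else if (radius_px <= 30) 2L
            else if (radius_px <= 100) 4L
            else 8L
  if (shrink == 1L) {
    bg <- ball_opening(img, radius_px)
  } else {
    small <- block_min(mean_filter3(img), shrink)
    bg_small <- ball_opening(small, radius_px / shrink)
    # expand back: small pixel k covers full rows (k-1)*s+1 .. k*s
    s <- shrink
    r_full <- seq_len(nrow(img))
    c_full <- seq_len(ncol(img))
    r_small <- (r_full - 0.5) / s + 0.5
    c_small <- (c_full - 0.5) / s + 0.5
    r_small <- pmin(pmax(r_small, 1), nrow(bg_small))
    c_small <- pmin(pmax(c_small, 1), ncol(bg_small))
    bg <- bilinear_sample(bg_small,
                          matrix(r_small, nrow(img), ncol(img)),
                          matrix(c_small, nrow(img), ncol(img), byrow = TRUE))
  }
  pmax(pmin(bg, img), 0)
}

# Grayscale opening by the non-flat ball dome z(o) = sqrt(r^2 - |o|^2):
# erosion (min of img - z) followed by dilation (max of eroded + z).
ball_opening <- function(img, radius) {
  off <- ball_offsets(radius)
  ero <- shift_reduce(img, off, erode = TRUE)
  shift_reduce(ero, off, erode = FALSE)
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r)
  d2 <- g$i^2 + g$j^2
  keep <- d2 <= radius^2
  list(i = g$i[keep], j = g$j[keep],
       z = sqrt(pmax(radius^2 - d2[keep], 0)), r = r)
}

shift_reduce <- function(img, off, erode) {
  n <- nrow(img)
  m <- ncol(img)
  r <- off$r
  # edge-replicated padding
  ri <- c(rep(1L, r), seq_len(n), rep(n, r))
  ci <- c(rep(1L, r), seq_len(m), rep(m, r))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(if (erode) Inf else -Inf, n, m)
  for (k in seq_along(off$i)) {
    blk <- pad[(r + off$i[k]) + seq_len(n), (r + off$j[k]) + seq_len(m)]
    out <- if (erode) pmin(out, blk - off$z[k]) else pmax(out, blk + off$z[k])
  }
  out
}

mean_filter3 <- function(img) {
  n <- nrow(img)
  m <- ncol(img)
  ri <- c(1L, seq_len(n), n)
  ci <- c(1L, seq_len(m), m)
  pad <- img[ri, ci, drop = FALSE]
  acc <- matrix(0, n, m)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + pad[di + seq_len(n), dj + seq_len(m)]
  }
  acc / 9
}

block_min <- function(img, s) {
  n <- nrow(img)
  m <- ncol(img)
  ns <- ceiling(n / s)
  ms <- ceiling(m / s)
  # pad to a multiple of s by edge replication
  ri <- c(seq_len(n), rep(n, ns * s - n))
  ci <- c(seq_len(m), rep(m, ms * s - m))
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(Inf, ns, ms)
  for (di in seq_len(s)) for (dj in seq_len(s)) {
    out <- pmin(out, pad[seq(di, by = s, length.out = ns),
                         seq(dj, by = s, length.out = ms)])
  }
  out
}

#' Crop a square window centred on a point
#'
#' For an even window size `s` centred at 1-based coordinate `c`, the window
#' spans rows/columns `c - s/2` to `c + s/2 - 1` (the half-open convention
#' `[c - s/2, c + s/2)`), so nested crops compose exactly.
#'
#' @param img numeric matrix.
#' @param center `c(row, col)`, 1-based.
#' @param size_px window side length in pixels.
#' @return the `size_px` x `size_px` sub-image.
#' @export
crop_centered <- function(img, center, size_px) {
  h0 <- floor(size_px / 2)
  h1 <- size_px - h0 - 1
  r0 <- center[1] - h0
  r1 <- center[1] + h1
  c0 <- center[2] - h0
  c1 <- center[2] + h1
  if (r0 < 1 || c0 < 1 || r1 > nrow(img) || c1 > ncol(img)) {
    stop("crop out of bounds: window [", r0, ",", r1, "] x [", c0, ",", c1,
         "] exceeds image ", nrow(img), "x", ncol(img))
  }
  img[r0:r1, c0:c1, drop = FALSE]
}

#' IsoData ("default") automatic threshold
#'
#' The iterative intermeans threshold on the 256-bin intensity histogram:
#' starting from the midpoint of the occupied intensity range, the threshold
#' is repeatedly replaced by `round((mean below + mean above) / 2)` until it
#' no longer moves. Pixels are binned by their integer part. When more than
#' half of all pixels sit in the extreme bin 0 or 255 (a saturated image),
#' that bin is ignored while computing the threshold, matching the common
#' behaviour of the method's "default" dialect.
#'
#' @param img numeric matrix with at least two distinct intensity bins.
#' @return integer threshold `t` in 0..254; foreground is `> t`.
#' @seealso [binarize()]
#' @export
isodata_default_threshold <- function(img) {
  h <- tabulate(floor(clamp255(img)) + 1L, nbins = 256L)
  isodata_from_hist(h)
}

isodata_from_hist <- function(h) {
  total <- sum(h)
  if (sum(h > 0L) < 2L) stop("degenerate histogram: fewer than 2 occupied bins")
  hh <- h
  if (h[1L] > total / 2) hh[1L] <- 0L
  if (h[256L] > total / 2) hh[256L] <- 0L
  if (sum(hh > 0L) < 2L) hh <- h
  vals <- 0:255
  occ <- vals[hh > 0L]
  t <- floor((min(occ) + max(occ)) / 2)
  for (iter in 1:256) {
    below <- vals <= t
    w1 <- sum(hh[below])
    w2 <- sum(hh[!below])
    m1 <- if (w1 > 0) sum(hh[below] * vals[below]) / w1 else min(occ)
    m2 <- if (w2 > 0) sum(hh[!below] * vals[!below]) / w2 else max(occ)
    t_new <- round((m1 + m2) / 2)
    if (t_new == t) break
    t <- t_new
  }
  as.integer(t)
}

#' Binarize an image at a threshold
#'
#' Pixels strictly above the threshold become 255, all others 0.
#'
#' @param img numeric matrix.
#' @param threshold integer in 0..255.
#' @return matrix with values in `{0, 255}`.
#' @export
binarize <- function(img, threshold) {
  if (threshold < 0 || threshold > 255) stop("threshold must lie in [0, 255]")
  (img > threshold) * 255
}

#' Leakage map: late-frame hyperfluorescence absent in the early frame
#'
#' The clamped difference `max(b5 - b1, 0)` of two binarized frames. A pixel
#' is "leaking" when it is hyperfluorescent at 5 min but was not at 1 min;
#' vessels and other structures bright in both frames cancel.
#'
#' @param binary_5min,binary_1min matrices with values in `{0, 255}`, same
#'   shape.
#' @return matrix with values in `{0, 255}`.
#' @export
leakage_map <- function(binary_5min, binary_1min) {
  if (!all(dim(binary_5min) == dim(binary_1min))) {
    stop("shape mismatch between the two binary frames")
  }
  pmax(binary_5min - binary_1min, 0)
}
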