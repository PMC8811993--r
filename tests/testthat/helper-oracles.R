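# Independent brute-force oracles used to validate the fast implementations.

# All intermeans fixed points t in 0..254 of the 256-bin histogram
# (same saturated-extreme trimming rule as the implementation's dialect).
intermeans_fixed_points <- function(img) {
  h <- tabulate(floor(pmin(pmax(img, 0), 255)) + 1L, nbins = 256L)
  total <- sum(h)
  hh <- h
  if (h[1L] > total / 2) hh[1L] <- 0L
  if (h[256L] > total / 2) hh[256L] <- 0L
  if (sum(hh > 0L) < 2L) hh <- h
  vals <- 0:255
  fp <- integer()
  for (t in 0:254) {
    below <- vals <= t
    w1 <- sum(hh[below])
    w2 <- sum(hh[!below])
    if (w1 == 0L || w2 == 0L) next
    m1 <- sum(hh[below] * vals[below]) / w1
    m2 <- sum(hh[!below] * vals[!below]) / w2
    if (t == round((m1 + m2) / 2)) fp <- c(fp, t)
  }
  fp
}

# AUC by explicit counting over all positive x negative pairs, ties one-half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Permutation oracle for the paired AUC contrast: under H0 the two
# predictors are exchangeable within subject, so flip the (a, b) pairing.
perm_delong_p <- function(a, b, labels, reps = 10000, seed = 1) {
  obs <- pair_count_auc(a, labels) - pair_count_auc(b, labels)
  set.seed(seed)
  hits <- 0L
  n <- length(labels)
  for (r in seq_len(reps)) {
    sw <- stats::runif(n) < 0.5
    aa <- ifelse(sw, b, a)
    bb <- ifelse(sw, a, b)
    d <- pair_count_auc(aa, labels) - pair_count_auc(bb, labels)
    if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  hits / reps
}

# Truncated-at-0 normal moments by numerical integration (independent of
# the closed form used inside the generator).
tn0_moments <- function(mean, sd) {
  z <- 1 - stats::pnorm(0, mean, sd)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                         0, Inf)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd),
                         0, Inf)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Exact full-resolution rolling-ball subtraction: grayscale opening by the
# non-flat ball dome, no shrinking or smoothing.
brute_rolling_ball <- function(img, radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r)
  d2 <- g$i^2 + g$j^2
  keep <- d2 <= radius^2
  oi <- g$i[keep]
  oj <- g$j[keep]
  oz <- sqrt(pmax(radius^2 - d2[keep], 0))
  n <- nrow(img)
  m <- ncol(img)
  pad_idx_r <- c(rep(1L, r), seq_len(n), rep(n, r))
  pad_idx_c <- c(rep(1L, r), seq_len(m), rep(m, r))
  sweep_min <- function(x, sign) {
    pad <- x[pad_idx_r, pad_idx_c, drop = FALSE]
    out <- matrix(if (sign < 0) Inf else -Inf, n, m)
    for (k in seq_along(oi)) {
      blk <- pad[(r + oi[k]) + seq_len(n), (r + oj[k]) + seq_len(m)]
      out <- if (sign < 0) pmin(out, blk - oz[k]) else pmax(out, blk + oz[k])
    }
    out
  }
  bg <- sweep_min(sweep_min(img, -1), +1)
  bg <- pmax(pmin(bg, img), 0)
  pmin(pmax(round(img - bg), 0), 255)
}

# Small textured test scene: smooth gradient + one broad bump + a thin
# bright diagonal ridge + mild noise, quantized to 8 bits.
make_test_scene <- function(n = 128, seed = 5, noise_sd = 2) {
  set.seed(seed)
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  scene <- 30 * exp(-((r - 0.3 * n)^2 + (c - 0.55 * n)^2) / (2 * (0.2 * n)^2)) +
    25 * c / n + 10
  ridge <- abs(r - c) < 2
  scene[ridge] <- scene[ridge] + 120
  pmin(pmax(round(scene + stats::rnorm(n * n, 0, noise_sd)), 0), 255)
}

# Compact image-pair scenarios used across tests (small frames keep the
# suite fast; fovea margins still satisfy the 384-crop requirement).
test_scenario <- function(seed, ...) {
  scenario_params(image_size = 416L, seed = seed, noise_sd = 4,
                  inter_frame_shift = c(3, 2), inter_frame_rotation = 0, ...)
}
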