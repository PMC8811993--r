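#' Macular analysis windows
#'
#' The leakage statistic is read over two nested square windows centred on
#' the fovea (i.e. on the centre of the 384-crop): a 120 x 120 px
#' *parafoveal* window and a 240 x 240 px *perifoveal* window,
#' approximating the central 3 mm and 6 mm of the macula. Both are full
#' squares by default — the parafoveal pixels are a subset of the perifoveal
#' ones; setting `perifoveal_annulus = TRUE` in [quantify_config()] scores
#' the perifoveal window with its central 120-square excluded instead.
#'
#' @param parafoveal_px,perifoveal_px window side lengths in pixels.
#' @return named integer vector of window sizes.
#' @export
region_spec <- function(parafoveal_px = 120L, perifoveal_px = 240L) {
  if (parafoveal_px >= perifoveal_px) {
    stop("the parafoveal window must nest inside the perifoveal window")
  }
  c(parafoveal = as.integer(parafoveal_px),
    perifoveal = as.integer(perifoveal_px))
}

#' Mean gray value of an image
#'
#' The arithmetic mean of all pixel values — the leakage severity statistic.
#' On a `{0, 255}` leakage map this equals 255 times the fraction of leaking
#' pixels.
#'
#' @param img nonempty numeric matrix.
#' @return a single number in `[0, 255]`.
#' @export
mean_gray_value <- function(img) {
  if (length(img) == 0) stop("empty image")
  mean(img)
}

#' Configuration of the per-eye quantification pipeline
#'
#' @param rolling_radius_px rolling-ball radius for background removal.
#' @param crop_px side of the fovea-centred crop on which thresholds are
#'   computed.
#' @param regions window sizes from [region_spec()].
#' @param shared_threshold if `TRUE`, one threshold is computed on the
#'   pooled histogram of both cropped frames (per-stack); the default
#'   thresholds each frame independently (per-frame).
#' @param perifoveal_annulus if `TRUE`, score the perifoveal window over the
#'   annulus excluding the parafoveal square.
#' @param max_rotation,rotation_step,min_quality alignment settings, see
#'   [align_pair()].
#' @param align_fallback_identity on alignment failure, fall back to the
#'   identity transform with a warning instead of failing the eye.
#' @return a list of class `"quantify_config"`.
#' @export
quantify_config <- function(rolling_radius_px = 50L, crop_px = 384L,
                            regions = region_spec(),
                            shared_threshold = FALSE,
                            perifoveal_annulus = FALSE,
                            max_rotation = 2, rotation_step = 0.5,
                            min_quality = 0.01,
                            align_fallback_identity = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "quantify_config"
  cfg
}

#' Quantify leakage for one eye
#'
#' Runs the full imaging chain on a registered/unregistered frame pair:
#' align the 5-min frame onto the 1-min frame, subtract the rolling-ball
#' background from both, crop the fovea-centred square, auto-threshold and
#' binarize each frame, cut the parafoveal and perifoveal windows, form the
#' leakage map (5-min minus 1-min, clamped) per window, and read its mean
#' gray value.
#'
#' @param pair an `fa_pair` (frames, fovea, eye id), e.g. from
#'   [generate_fa_pair()] or assembled from [read_gray()] images.
#' @param config a [quantify_config()].
#' @param grader_id label stored in the result.
#' @return a list of class `"leakage_result"`: `eye_id`, `grader_id`,
#'   `parafoveal_mgv`, `perifoveal_mgv`, `threshold_1min`, `threshold_5min`,
#'   `alignment` (rotation, translation, quality).
#' @export
quantify_eye <- function(pair, config = quantify_config(),
                         grader_id = "grader1") {
  stopifnot(inherits(pair, "fa_pair"))
  al <- tryCatch(
    align_pair(pair$frame_1min, pair$frame_5min,
               max_rotation = config$max_rotation,
               rotation_step = config$rotation_step,
               min_quality = config$min_quality),
    error = function(e) {
      if (config$align_fallback_identity &&
          grepl("alignment failure", conditionMessage(e))) {
        warning("eye ", pair$eye_id, ": ", conditionMessage(e),
                "; falling back to identity transform")
        list(aligned = pair$frame_5min,
             transform = list(rotation = 0, translation = c(0, 0),
                              quality = NA_real_))
      } else {
        stop("eye ", pair$eye_id, ": ", conditionMessage(e))
      }
    }
  )

  f1 <- rolling_ball_subtract(pair$frame_1min, config$rolling_radius_px)
  f5 <- rolling_ball_subtract(al$aligned, config$rolling_radius_px)

  c1 <- tryCatch(crop_centered(f1, pair$fovea, config$crop_px),
                 error = function(e) stop("eye ", pair$eye_id, ": ",
                                          conditionMessage(e)))
  c5 <- crop_centered(f5, pair$fovea, config$crop_px)

  if (config$shared_threshold) {
    h <- tabulate(floor(clamp255(c1)) + 1L, 256L) +
      tabulate(floor(clamp255(c5)) + 1L, 256L)
    t1 <- t5 <- isodata_from_hist(h)
  } else {
    t1 <- isodata_default_threshold(c1)
    t5 <- isodata_default_threshold(c5)
  }
  b1 <- binarize(c1, t1)
  b5 <- binarize(c5, t5)

  centre <- rep(config$crop_px %/% 2L + 1L, 2)
  score <- function(size) {
    w1 <- crop_centered(b1, centre, size)
    w5 <- crop_centered(b5, centre, size)
    mp <- leakage_map(w5, w1)
    mean_gray_value(mp)
  }
  para <- score(config$regions[["parafoveal"]])
  peri <- if (config$perifoveal_annulus) {
    annulus_mgv(b5, b1, centre, config$regions[["perifoveal"]],
                config$regions[["parafoveal"]])
  } else {
    score(config$regions[["perifoveal"]])
  }

  structure(
    list(eye_id = pair$eye_id, grader_id = grader_id,
         parafoveal_mgv = para, perifoveal_mgv = peri,
         threshold_1min = t1, threshold_5min = t5,
         alignment = al$transform),
    class = "leakage_result"
  )
}

annulus_mgv <- function(b5, b1, centre, outer_px, inner_px) {
  w1 <- crop_centered(b1, centre, outer_px)
  w5 <- crop_centered(b5, centre, outer_px)
  mp <- leakage_map(w5, w1)
  keep <- matrix(TRUE, outer_px, outer_px)
  h0 <- floor(inner_px / 2)
  mid <- outer_px %/% 2L + 1L
  keep[(mid - h0):(mid + inner_px - h0 - 1),
       (mid - h0):(mid + inner_px - h0 - 1)] <- FALSE
  mean(mp[keep])
}

#' Average the measurements of two graders
#'
#' @param a,b `leakage_result` objects for the same eye.
#' @return a `leakage_result` with per-region arithmetic means and
#'   `grader_id = "averaged"`.
#' @export
average_graders <- function(a, b) {
  stopifnot(inherits(a, "leakage_result"), inherits(b, "leakage_result"))
  if (!identical(a$eye_id, b$eye_id)) {
    stop("grader results refer to different eyes: ",
         a$eye_id, " vs ", b$eye_id)
  }
  out <- a
  out$grader_id <- "averaged"
  out$parafoveal_mgv <- (a$parafoveal_mgv + b$parafoveal_mgv) / 2
  out$perifoveal_mgv <- (a$perifoveal_mgv + b$perifoveal_mgv) / 2
  out
}

#' @export
print.leakage_result <- function(x, ...) {
  cat(sprintf(
    "<leakage_result> eye %s (%s): parafoveal %.1f, perifoveal %.1f (thresholds %d/%d)\n",
    x$eye_id, x$grader_id, x$parafoveal_mgv, x$perifoveal_mgv,
    x$threshold_1min, x$threshold_5min))
  invisible(x)
}
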