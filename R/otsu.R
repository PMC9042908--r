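#' Otsu threshold of a set of intensities
#'
#' Classic between-class-variance maximization over a 256-level histogram.
#' Intensities are binned to integers 0..255: images already in [0, 255] are
#' rounded in place; anything else is linearly rescaled first. Candidate
#' thresholds are the 256 levels; the chosen threshold t maximizes
#' w0(t) * w1(t) * (mu0(t) - mu1(t))^2, with pixels classified as foreground
#' when level > t. Ties take the lowest maximizing t.
#'
#' @param x numeric vector of intensities (e.g. ROI pixels).
#' @return threshold on the original intensity scale, with attributes
#'   `"level"` (0..255 bin) and `"between_var"` (maximized criterion).
#' @export
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("constant intensity: Otsu has no separable classes", call. = FALSE)
  in_byte_range <- rng[1] >= 0 && rng[2] <= 255
  lev <- if (in_byte_range) round(x) else
    round((x - rng[1]) / (rng[2] - rng[1]) * 255)
  h <- tabulate(lev + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                       # P(level <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  # between-class variance for threshold t (foreground = level > t)
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_lev <- which.max(sigma_b) - 1L
  thr <- if (in_byte_range) t_lev else
    rng[1] + t_lev / 255 * (rng[2] - rng[1])
  structure(thr, level = t_lev, between_var = max(sigma_b))
}

#' Binarize an en-face image inside a region of interest
#'
#' The Otsu threshold is computed over ROI pixels only — the lesion is
#' cropped before thresholding, so surrounding tissue does not drag the
#' threshold. Pixels strictly above the threshold, inside the ROI, become
#' vessel pixels. The returned mask carries the magnification-corrected
#' pixel size.
#'
#' @param image an [en_face_image()].
#' @param roi an [roi_mask()] congruent with the image.
#' @param reference_axial_length passed to [correct_magnification()].
#' @return a [binary_mask()] with attributes `"threshold"` carrying the cut.
#' @export
binarize_otsu <- function(image, roi, reference_axial_length = 23.95) {
  stopifnot(inherits(image, "en_face_image"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), dim(image$pixels)))
    stop("ROI dimensions do not match image", call. = FALSE)
  vals <- image$pixels[roi$mask]
  thr <- otsu_threshold(vals)
  mask <- roi$mask & image$pixels > as.numeric(thr)
  px <- correct_magnification(image, reference_axial_length)
  out <- binary_mask(mask, pixel_size = as.numeric(px), roi = roi)
  attr(out, "threshold") <- thr
  out
}
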