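# Synthetic vessel networks with exact ground truth. Branches are thick
# polylines with a sinusoidal perpendicular wiggle; this exercises the whole
# morphometry chain (thresholding, thinning, branch tracing, tortuosity)
# without pretending to model angiogenesis.

#' Specification of a synthetic vessel network
#'
#' @param image_size raster side in pixels (square image; the 3 x 3 mm cube
#'   default is 304).
#' @param n_branches number of primary branches (disjoint wiggly vessels).
#' @param thickness vessel thickness in pixels (>= 1).
#' @param wiggle_amplitude perpendicular sine amplitude in pixels; 0 gives
#'   straight vessels (tortuosity exactly 1).
#' @param wiggle_frequency number of full sine periods along each branch.
#' @param loop_probability chance that a branch is replaced by a closed
#'   elliptical loop (anastomotic arcade); loops have chord 0 and are
#'   excluded from tortuosity.
#' @param background_mean,vessel_mean grayscale means (0-255 scale).
#' @param noise_sd additive Gaussian noise SD; 0 gives a two-level image.
#' @param seed integer; fixes the whole draw.
#' @return list of class `vessel_network_spec`.
#' @export
vessel_network_spec <- function(image_size = 304L, n_branches = 6L,
                                thickness = 3L, wiggle_amplitude = 6,
                                wiggle_frequency = 2, loop_probability = 0,
                                background_mean = 30, vessel_mean = 200,
                                noise_sd = 0, seed = 1L) {
  stopifnot(image_size >= 32, n_branches >= 1, thickness >= 1,
            wiggle_amplitude >= 0, wiggle_frequency >= 0,
            loop_probability >= 0, loop_probability <= 1,
            background_mean >= 0, vessel_mean <= 255,
            background_mean < vessel_mean, noise_sd >= 0)
  structure(as.list(environment()), class = "vessel_network_spec")
}

#' Draw a synthetic vessel network with ground truth
#'
#' Branches run roughly horizontally in separated lanes so they never touch:
#' the drawn branch count, centerline, per-branch arc/chord ratio and vessel
#' pixel count are then exact ground truth for the recovered metrics.
#'
#' @param spec a [vessel_network_spec()].
#' @return list with `image` (numeric matrix, grayscale), `mask` (logical,
#'   the exact drawn vessels), `truth`: list with `n_branches`,
#'   `vessel_pixels`, `centerline_length` (px), `branch_tortuosity`
#'   (per-branch arc/chord), `mean_tortuosity`, `n_loops`.
#' @export
make_vessel_network <- function(spec = vessel_network_spec()) {
  stopifnot(inherits(spec, "vessel_network_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  mask <- matrix(FALSE, n, n)
  margin <- ceiling(spec$thickness + spec$wiggle_amplitude + 4)
  lane_h <- (n - 2 * margin) / spec$n_branches
  if (lane_h < 2 * (spec$thickness + spec$wiggle_amplitude) + 2)
    stop("branches do not fit: reduce n_branches, thickness or amplitude",
         call. = FALSE)
  ratios <- numeric(0)
  center_len <- 0
  n_loops <- 0L
  for (b in seq_len(spec$n_branches)) {
    y0 <- margin + (b - 0.5) * lane_h
    if (stats::runif(1) < spec$loop_probability) {
      # closed elliptical loop in this lane
      cx <- n / 2 + stats::runif(1, -n / 8, n / 8)
      rx <- stats::runif(1, n / 10, n / 6)
      ry <- min(lane_h / 2 - spec$thickness - 1, rx / 2)
      t <- seq(0, 2 * pi, length.out = 600)
      xs <- cx + rx * cos(t); ys <- y0 + ry * sin(t)
      mask <- paint_polyline(mask, xs, ys, spec$thickness)
      center_len <- center_len + polyline_length(xs, ys)
      n_loops <- n_loops + 1L
    } else {
      x <- seq(margin, n - margin, length.out = 4L * n)
      phase <- stats::runif(1, 0, 2 * pi)
      y <- y0 + spec$wiggle_amplitude *
        sin(2 * pi * spec$wiggle_frequency * (x - margin) /
              (n - 2 * margin) + phase)
      mask <- paint_polyline(mask, x, y, spec$thickness)
      arc <- polyline_length(x, y)
      chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
      ratios <- c(ratios, arc / chord)
      center_len <- center_len + arc
    }
  }
  noise <- if (spec$noise_sd > 0)
    matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n) else 0
  image <- matrix(spec$background_mean, n, n)
  image[mask] <- spec$vessel_mean
  image <- pmin(pmax(image + noise, 0), 255)
  list(image = image, mask = mask,
       truth = list(n_branches = spec$n_branches,
                    vessel_pixels = sum(mask),
                    centerline_length = center_len,
                    branch_tortuosity = ratios,
                    mean_tortuosity = if (length(ratios)) mean(ratios)
                                      else NA_real_,
                    n_loops = n_loops))
}

polyline_length <- function(x, y)
  sum(sqrt(diff(x)^2 + diff(y)^2))

paint_polyline <- function(mask, xs, ys, thickness) {
  # stamp a disc of diameter `thickness` at dense samples along the path
  r <- thickness / 2
  n <- nrow(mask)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  ri <- round(ys); ci <- round(xs)
  keep <- !duplicated(cbind(ri, ci))
  ri <- ri[keep]; ci <- ci[keep]
  for (k in seq_len(nrow(off))) {
    rr <- ri + off$dr[k]; cc <- ci + off$dc[k]
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}
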