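# The seven quantitative lesion biomarkers. All ratio metrics are pure pixel
# ratios (magnification-invariant); only lesion size uses the corrected
# pixel size.

#' Lesion (CNV complex) footprint area
#'
#' ROI pixel count times the squared corrected pixel size.
#'
#' @param mask a [binary_mask()] carrying the corrected pixel size.
#' @param roi an [roi_mask()].
#' @return area in mm^2.
#' @export
cnv_size <- function(mask, roi) {
  stopifnot(inherits(mask, "binary_mask"), inherits(roi, "roi_mask"))
  sum(roi$mask) * (mask$pixel_size / 1000)^2
}

#' Vessel density (VD)
#'
#' Percent of the ROI occupied by binarized vessel pixels.
#'
#' @inheritParams cnv_size
#' @return percent in [0, 100].
#' @export
vessel_density <- function(mask, roi) {
  stopifnot(inherits(mask, "binary_mask"), inherits(roi, "roi_mask"))
  100 * sum(mask$mask & roi$mask) / sum(roi$mask)
}

#' Vessel length density (VLD)
#'
#' Percent of the ROI occupied by the one-pixel-wide skeleton.
#'
#' @param skeleton a [skeletonize()] result (or logical matrix).
#' @param roi an [roi_mask()].
#' @return percent in [0, 100]; always <= the vessel density of the source
#'   mask because the skeleton is a subset of it.
#' @export
vessel_length_density <- function(skeleton, roi) {
  sk <- if (inherits(skeleton, "skeleton_graph")) skeleton$skeleton_mask
        else as_logical_mask(skeleton, "skeleton")
  stopifnot(inherits(roi, "roi_mask"))
  100 * sum(sk & roi$mask) / sum(roi$mask)
}

#' Vessel diameter index
#'
#' VD / VLD: the mean number of vessel pixels per unit of centerline, a
#' calibre surrogate (1 = one-pixel-wide network).
#'
#' @param vd vessel density, percent.
#' @param vld vessel length density, percent.
#' @return dimensionless ratio; `NA` (with a warning) when `vld` is 0, where
#'   the index is undefined.
#' @export
vessel_diameter_index <- function(vd, vld) {
  stopifnot(is.numeric(vd), is.numeric(vld))
  if (vld == 0) {
    warning("vessel length density is 0: diameter index undefined")
    return(NA_real_)
  }
  vd / vld
}

#' Mean branch tortuosity
#'
#' For every branch of the skeleton graph, the ratio of its path length to
#' the straight (chord) distance between its two terminal nodes; reported as
#' the unweighted mean over eligible branches. Closed loops (chord 0) and
#' branches shorter than `min_branch_length` are excluded and counted in the
#' attached QC attributes.
#'
#' @param skeleton a [skeletonize()] result.
#' @param min_branch_length minimum branch path length in pixels (default 3).
#' @return mean arc/chord ratio >= 1, with attributes `n_branches`,
#'   `n_eligible`, `n_excluded_short`, `n_excluded_loops`; `NA` with a
#'   warning when no branch is eligible.
#' @export
vessel_tortuosity <- function(skeleton, min_branch_length = 3) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  br <- skeleton$branches
  if (length(br) == 0L) {
    warning("skeleton has no branches: tortuosity undefined")
    return(structure(NA_real_, n_branches = 0L, n_eligible = 0L,
                     n_excluded_short = 0L, n_excluded_loops = 0L))
  }
  plen <- vapply(br, `[[`, numeric(1), "path_length")
  chord <- vapply(br, `[[`, numeric(1), "chord_length")
  loop <- vapply(br, `[[`, logical(1), "is_loop") | chord <= 0
  short <- !loop & plen < min_branch_length
  ok <- !loop & !short
  val <- if (any(ok)) mean(pmax(plen[ok] / chord[ok], 1)) else NA_real_
  if (is.na(val)) warning("no eligible branch: tortuosity undefined")
  structure(val, n_branches = length(br), n_eligible = sum(ok),
            n_excluded_short = sum(short), n_excluded_loops = sum(loop))
}

#' Default box-size ladder
#'
#' Powers of two from 2 px up to `floor(min(dim) / 4)`, the conventional
#' box-counting range that keeps at least four boxes along the short side.
#'
#' @param dims integer vector (rows, cols) of the analysed grid.
#' @return integer vector of box sizes.
#' @export
box_ladder <- function(dims) {
  top <- floor(min(dims) / 4)
  if (top < 2) return(integer(0))
  2L^(1:floor(log2(top)))
}

crop_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mask[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

box_counts <- function(mask, sizes) {
  # boxes tile from the foreground bounding-box origin; a box counts if it
  # contains any foreground pixel
  m <- crop_bbox(mask)
  vapply(sizes, function(s) {
    rb <- (seq_len(nrow(m)) - 1L) %/% s
    cb <- (seq_len(ncol(m)) - 1L) %/% s
    sum(t(rowsum(t(rowsum(m * 1, rb)), cb)) > 0)
  }, numeric(1))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes over a ladder of box sizes (grid anchored at the
#' foreground bounding-box origin) and fits log(count) against
#' log(1 / size) by least squares; the slope is the fractal dimension.
#'
#' @param mask logical matrix with at least 2 foreground pixels (a
#'   [binary_mask()] or [skeletonize()] result is also accepted).
#' @param sizes box-size ladder; default [box_ladder()] of the grid.
#' @param min_r_squared warn when the log-log fit is poorer than this.
#' @return fractal dimension in [0, 2] with attributes `r_squared`, `sizes`,
#'   `counts`.
#' @export
fractal_dimension <- function(mask, sizes = NULL, min_r_squared = 0.95) {
  mask <- extract_mask(mask)
  if (sum(mask) < 2) stop("need >= 2 foreground pixels", call. = FALSE)
  if (is.null(sizes)) sizes <- box_ladder(dim(mask))
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) < 3L)
    stop("fewer than 3 usable box sizes; grid too small for box counting",
         call. = FALSE)
  counts <- box_counts(mask, sizes)
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  if (is.finite(r2) && r2 < min_r_squared)
    warning(sprintf("box-count fit R^2 = %.3f < %.2f; FD unreliable",
                    r2, min_r_squared))
  structure(min(max(slope, 0), 2), r_squared = r2, sizes = sizes,
            counts = counts)
}

extract_mask <- function(x) {
  if (inherits(x, "binary_mask")) x$mask
  else if (inherits(x, "skeleton_graph")) x$skeleton_mask
  else as_logical_mask(x, "mask")
}

window_sums <- function(m, s) {
  # sums of all s x s windows (stride 1) via a summed-area table
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- m
  S <- apply(S, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  ri <- 1:(nr - s + 1); ci <- 1:(nc - s + 1)
  S[ri + s, ci + s, drop = FALSE] - S[ri, ci + s, drop = FALSE] -
    S[ri + s, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Gliding-box lacunarity
#'
#' For each box size r, boxes of r x r pixels glide with stride 1 over the
#' whole grid; Lambda(r) = variance / mean^2 of the box mass (foreground
#' pixel count) over all positions, using the population variance. A
#' translation-invariant pattern has Lambda = 0; clumped patterns score
#' higher. The reported summary is the unweighted mean of Lambda(r) over
#' the ladder.
#'
#' @param mask logical matrix with at least 1 foreground pixel.
#' @param sizes box-size ladder; default [box_ladder()] of the grid.
#' @return mean lacunarity with attributes `sizes` and `lambda` (per-size
#'   values).
#' @export
lacunarity <- function(mask, sizes = NULL) {
  mask <- extract_mask(mask)
  if (!any(mask)) stop("need >= 1 foreground pixel", call. = FALSE)
  if (is.null(sizes)) sizes <- box_ladder(dim(mask))
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes <= min(dim(mask))]
  if (length(sizes) == 0L)
    stop("no box size fits the grid", call. = FALSE)
  lam <- vapply(sizes, function(s) {
    w <- as.numeric(window_sums(mask * 1, s))
    mu <- mean(w)
    if (mu == 0) return(0)
    v <- mean(w^2) - mu^2
    v / mu^2
  }, numeric(1))
  structure(mean(lam), sizes = sizes, lambda = lam)
}

#' The seven-biomarker set for one lesion
#'
#' Container with invariant checks: densities in [0, 100], VLD <= VD,
#' diameter index = VD / VLD, tortuosity >= 1.
#'
#' @param cnv_size mm^2.
#' @param vessel_density percent.
#' @param vessel_length_density percent.
#' @param vessel_diameter_index dimensionless (or NA).
#' @param vessel_tortuosity dimensionless >= 1 (or NA).
#' @param fractal_dimension dimensionless in [0, 2].
#' @param lacunarity dimensionless >= 0.
#' @return object of class `biomarker_set`.
#' @export
biomarker_set <- function(cnv_size, vessel_density, vessel_length_density,
                          vessel_diameter_index, vessel_tortuosity,
                          fractal_dimension, lacunarity) {
  stopifnot(cnv_size >= 0,
            vessel_density >= 0, vessel_density <= 100,
            vessel_length_density >= 0,
            vessel_length_density <= vessel_density + 1e-9,
            is.na(vessel_tortuosity) || vessel_tortuosity >= 1 - 1e-9,
            fractal_dimension >= 0, fractal_dimension <= 2,
            lacunarity >= 0)
  if (!is.na(vessel_diameter_index) && vessel_length_density > 0)
    stopifnot(abs(vessel_diameter_index -
                    vessel_density / vessel_length_density) < 1e-9)
  structure(list(cnv_size = as.numeric(cnv_size),
                 vessel_density = as.numeric(vessel_density),
                 vessel_length_density = as.numeric(vessel_length_density),
                 vessel_diameter_index = as.numeric(vessel_diameter_index),
                 vessel_tortuosity = as.numeric(vessel_tortuosity),
                 fractal_dimension = as.numeric(fractal_dimension),
                 lacunarity = as.numeric(lacunarity)),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Compute all lesion biomarkers from an image and ROI
#'
#' Runs the full chain: magnification correction, Otsu binarization inside
#' the ROI, skeletonization, then the seven metrics. Fractal dimension and
#' lacunarity are computed on the skeleton by default (switchable to the
#' binarized lesion); both substrates share the ROI bounding-box ladder.
#'
#' @param image an [en_face_image()].
#' @param roi an [roi_mask()].
#' @param config a [morphometry_config()]; individual fields may be
#'   overridden.
#' @return a [biomarker_set()] with attribute `"qc"`: list with the Otsu
#'   threshold, branch exclusion counts, FD fit R-squared, per-size
#'   lacunarity, and the conventions used.
#' @export
compute_biomarkers <- function(image, roi, config = morphometry_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("binarize", binarize_otsu(image, roi,
                                          config$reference_axial_length))
  skel <- stage("skeletonize", skeletonize(mask))
  vd <- vessel_density(mask, roi)
  vld <- vessel_length_density(skel, roi)
  vdi <- if (vld > 0) vd / vld else NA_real_
  tort <- stage("tortuosity",
                suppressWarnings(vessel_tortuosity(skel,
                                                   config$min_branch_length)))
  substrate <- if (config$fd_substrate == "binary") mask$mask
               else skel$skeleton_mask
  # ladder over the ROI bounding box, shared by FD and lacunarity
  roi_bb <- crop_bbox(roi$mask)
  sizes <- if (is.null(config$box_sizes)) box_ladder(dim(roi_bb))
           else config$box_sizes
  fd <- stage("fractal_dimension",
              suppressWarnings(fractal_dimension(substrate, sizes = sizes)))
  lac_mask <- substrate & roi$mask
  lac <- stage("lacunarity", lacunarity(crop_roi_bbox(lac_mask, roi$mask),
                                        sizes = sizes))
  bm <- biomarker_set(
    cnv_size = cnv_size(mask, roi),
    vessel_density = vd,
    vessel_length_density = vld,
    vessel_diameter_index = vdi,
    vessel_tortuosity = as.numeric(tort),
    fractal_dimension = as.numeric(fd),
    lacunarity = as.numeric(lac))
  attr(bm, "qc") <- list(
    otsu_threshold = as.numeric(attr(mask, "threshold")),
    pixel_size_um = mask$pixel_size,
    n_branches = attr(tort, "n_branches"),
    n_excluded_short = attr(tort, "n_excluded_short"),
    n_excluded_loops = attr(tort, "n_excluded_loops"),
    fd_r_squared = attr(fd, "r_squared"),
    fd_substrate = config$fd_substrate,
    box_sizes = attr(fd, "sizes"),
    lacunarity_by_size = as.numeric(attr(lac, "lambda")),
    lacunarity_convention = "gliding-box var/mean^2, mean over ladder")
  bm
}

crop_roi_bbox <- function(mask, roi) {
  idx <- which(roi, arr.ind = TRUE)
  mask[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
       drop = FALSE]
}

#' Morphometry configuration
#'
#' @param reference_axial_length device calibration axial length, mm.
#' @param fd_substrate `"skeleton"` (default) or `"binary"`: which mask the
#'   fractal dimension and lacunarity are computed on.
#' @param min_branch_length minimum branch path length (px) for tortuosity.
#' @param box_sizes explicit box-size ladder, or NULL for [box_ladder()].
#' @return list of class `morphometry_config`.
#' @export
morphometry_config <- function(reference_axial_length = 23.95,
                               fd_substrate = c("skeleton", "binary"),
                               min_branch_length = 3,
                               box_sizes = NULL) {
  fd_substrate <- match.arg(fd_substrate)
  stopifnot(reference_axial_length > 0, min_branch_length >= 0)
  structure(list(reference_axial_length = reference_axial_length,
                 fd_substrate = fd_substrate,
                 min_branch_length = min_branch_length,
                 box_sizes = box_sizes),
            class = "morphometry_config")
}
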