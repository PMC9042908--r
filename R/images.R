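#' En-face OCTA image
#'
#' Bundles a 2-D grayscale raster with the physical pixel size quoted by the
#' device and the eye's axial length, which together determine the true
#' (magnification-corrected) pixel size.
#'
#' @param pixels numeric matrix of intensities (arbitrary units); rows are
#'   image rows (y), columns are x.
#' @param nominal_pixel_size nominal micrometres per pixel before
#'   magnification correction. A 3 x 3 mm cube sampled at 304 x 304 A-scans
#'   gives the default 3000 / 304 = 9.87 um/px.
#' @param axial_length axial length of the imaged eye in millimetres.
#' @param al_bounds plausible axial-length range (mm); values outside are
#'   rejected.
#' @return object of class `en_face_image`.
#' @export
en_face_image <- function(pixels, nominal_pixel_size = 3000 / 304,
                          axial_length = 23.95, al_bounds = c(20, 36)) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(pixels)) stop("`pixels` contains missing values", call. = FALSE)
  if (!is.numeric(nominal_pixel_size) || length(nominal_pixel_size) != 1L ||
      nominal_pixel_size <= 0)
    stop("`nominal_pixel_size` must be a single positive number", call. = FALSE)
  check_axial_length(axial_length, al_bounds, "axial_length")
  structure(
    list(pixels = pixels,
         nominal_pixel_size = nominal_pixel_size,
         axial_length = axial_length,
         al_bounds = al_bounds),
    class = "en_face_image")
}

check_axial_length <- function(al, bounds, field) {
  if (!is.numeric(al) || length(al) != 1L || !is.finite(al))
    stop(sprintf("`%s` must be a single finite number", field), call. = FALSE)
  if (al < bounds[1] || al > bounds[2])
    stop(sprintf("`%s` = %.2f mm outside plausible range [%.1f, %.1f] mm",
                 field, al, bounds[1], bounds[2]), call. = FALSE)
  invisible(al)
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf("<en_face_image> %d x %d px, %.3f um/px nominal, AL %.2f mm\n",
              nrow(x$pixels), ncol(x$pixels), x$nominal_pixel_size,
              x$axial_length))
  invisible(x)
}

#' Region of interest (cropped CNV complex)
#'
#' A logical mask congruent with the image, TRUE inside the reader-drawn CNV
#' complex. The ROI is always supplied, never inferred.
#'
#' @param mask logical matrix (or 0/1 numeric) with at least one TRUE pixel.
#' @param image optional `en_face_image` to check dimensions against.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, image = NULL) {
  mask <- as_logical_mask(mask, "mask")
  if (!any(mask)) stop("ROI mask has no TRUE pixel", call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image$pixels)))
    stop(sprintf("ROI dimensions %dx%d do not match image %dx%d",
                 nrow(mask), ncol(mask),
                 nrow(image$pixels), ncol(image$pixels)), call. = FALSE)
  structure(list(mask = mask), class = "roi_mask")
}

as_logical_mask <- function(m, name) {
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1)))
      stop(sprintf("`%s` must be logical or 0/1", name), call. = FALSE)
    m <- array(m != 0, dim(m))
  }
  if (!is.logical(m) || !is.matrix(m) || length(m) == 0L)
    stop(sprintf("`%s` must be a non-empty logical matrix", name),
         call. = FALSE)
  if (anyNA(m)) stop(sprintf("`%s` contains NA", name), call. = FALSE)
  m
}

#' Binary vessel mask
#'
#' Result of binarization: TRUE = vessel pixel, restricted to the ROI, with
#' the magnification-corrected pixel size attached.
#'
#' @param mask logical matrix, TRUE on vessel pixels.
#' @param pixel_size micrometres per pixel after magnification correction.
#' @param roi optional `roi_mask`; vessel pixels must lie inside it.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, pixel_size, roi = NULL) {
  mask <- as_logical_mask(mask, "mask")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  if (!is.null(roi)) {
    if (!identical(dim(mask), dim(roi$mask)))
      stop("vessel mask and ROI dimensions differ", call. = FALSE)
    if (any(mask & !roi$mask))
      stop("vessel pixels found outside the ROI", call. = FALSE)
  }
  structure(list(mask = mask, pixel_size = pixel_size), class = "binary_mask")
}

# ---- plain-text raster I/O -------------------------------------------------
# Core formats are text so fixtures and pipelines survive text-only transport:
# ASCII PGM (P2) and headerless CSV matrices. PNG (8/16-bit grayscale) is
# supported when the `png` package is installed.

#' Read a 2-D grayscale raster
#'
#' Dispatches on extension: `.pgm` (ASCII P2), `.csv` (numeric matrix,
#' no header), `.png` (grayscale; requires the `png` package; 8- or 16-bit
#' values are rescaled back to integer counts).
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = read_pgm(path),
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("PNG input requires the `png` package; use PGM or CSV",
             call. = FALSE)
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]  # first channel
      round(a * 255)
    },
    stop("unsupported raster format: .", ext, " (use pgm, csv or png)",
         call. = FALSE))
}

#' Write a 2-D raster as ASCII PGM or CSV
#'
#' @param m numeric or logical matrix; logical is written as 0/255.
#' @param path destination; extension selects the format (`.pgm` or `.csv`).
#' @export
write_raster <- function(m, path) {
  if (is.logical(m)) m <- m * 255L
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "pgm") {
    write_pgm(m, path)
  } else {
    stop("unsupported output raster format: .", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2")
    stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h)
    stop("PGM pixel count mismatch in ", path, call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(m, path) {
  m <- round(m)
  maxv <- max(1, max(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxv)), con)
  apply(m, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
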