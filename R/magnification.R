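#' Axial-length magnification correction
#'
#' OCT(A) devices assume a standard eye; in long (highly myopic) eyes the
#' true retinal extent of a pixel is larger than nominal. Following the
#' Bennett-style approximation, the transverse scaling of the fundus image is
#' proportional to (AL - 1.82) where 1.82 mm is the distance between the
#' eye's second principal plane and the nominal corneal vertex, so
#'
#'   corrected = nominal * (AL - 1.82) / (AL_ref - 1.82)
#'
#' with `AL_ref` the device's calibration axial length (default 23.95 mm).
#' Areas scale with the square of this factor.
#'
#' @param image an [en_face_image()].
#' @param reference_axial_length calibration axial length in mm.
#' @param al_bounds plausible range for both axial lengths.
#' @return corrected pixel size in micrometres per pixel, with the scale
#'   factor attached as attribute `"factor"`.
#' @examples
#' img <- en_face_image(matrix(0, 4, 4), nominal_pixel_size = 9.87,
#'                      axial_length = 29.20)
#' correct_magnification(img)  # ~12.21 um/px
#' @export
correct_magnification <- function(image, reference_axial_length = 23.95,
                                  al_bounds = image$al_bounds) {
  stopifnot(inherits(image, "en_face_image"))
  check_axial_length(image$axial_length, al_bounds, "axial_length")
  check_axial_length(reference_axial_length, al_bounds,
                     "reference_axial_length")
  factor <- (image$axial_length - 1.82) / (reference_axial_length - 1.82)
  structure(image$nominal_pixel_size * factor, factor = factor)
}
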