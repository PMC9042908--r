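#' Pipeline configuration
#'
#' One validated bundle of every tunable the pipeline uses. All fields are
#' checked against their documented ranges before any stage runs.
#'
#' @param reference_axial_length device calibration axial length, mm
#'   (20-36).
#' @param al_bounds plausible axial-length range, mm.
#' @param fd_substrate `"skeleton"` or `"binary"` for fractal dimension and
#'   lacunarity.
#' @param box_sizes explicit box ladder or NULL for the automatic one.
#' @param min_branch_length minimum branch length (px) for tortuosity.
#' @param entry_alpha univariable p-value threshold for multivariable entry.
#' @param continuity continuity correction in the Mann-Whitney normal
#'   approximation.
#' @param seed integer seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_axial_length = 23.95,
                            al_bounds = c(20, 36),
                            fd_substrate = c("skeleton", "binary"),
                            box_sizes = NULL,
                            min_branch_length = 3,
                            entry_alpha = 0.1,
                            continuity = FALSE,
                            seed = 1L) {
  fd_substrate <- match.arg(fd_substrate)
  stopifnot(length(al_bounds) == 2L, al_bounds[1] < al_bounds[2])
  check_axial_length(reference_axial_length, al_bounds,
                     "reference_axial_length")
  stopifnot(min_branch_length >= 0,
            entry_alpha > 0, entry_alpha <= 1,
            is.logical(continuity))
  if (!is.null(box_sizes)) {
    box_sizes <- as.integer(box_sizes)
    stopifnot(all(box_sizes >= 1))
  }
  structure(list(reference_axial_length = reference_axial_length,
                 al_bounds = al_bounds,
                 fd_substrate = fd_substrate,
                 box_sizes = box_sizes,
                 min_branch_length = min_branch_length,
                 entry_alpha = entry_alpha,
                 continuity = isTRUE(continuity),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' JSON always works; YAML works when the `yaml` package is installed.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the `yaml` package; use JSON",
           call. = FALSE)
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext, call. = FALSE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, lst)
}
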