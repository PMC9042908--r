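# File-based pipeline: batch morphometry over image/ROI pairs and the full
# cohort analysis, each leaving a machine-readable run report.
# Exit-status contract: 0 = clean, 1 = partial per-eye failures,
# 2 = configuration or schema error (enforced by the CLI wrapper).

write_run_report <- function(out_dir, stage, files, log, status) {
  files <- files[file.exists(files)]
  rep <- list(stage = stage,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(
                utils::packageVersion("octacnv")),
              r_version = R.version.string,
              status = status,
              log = log,
              outputs = lapply(seq_along(files), function(i)
                list(path = unname(files[i]),
                     md5 = unname(tools::md5sum(files[i])))))
  path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Batch lesion morphometry over image files
#'
#' Processes each (image, ROI) pair with [compute_biomarkers()]; axial
#' lengths come from a per-eye table. Per-eye failures are logged and the
#' run continues; the result carries an `exit_status` attribute following
#' the 0/1/2 contract.
#'
#' @param images character vector of raster paths (PGM/CSV/PNG).
#' @param rois matching vector of ROI mask paths.
#' @param al_table data.frame (or CSV path) with columns `eye_id`,
#'   `axial_length` and optional `nominal_pixel_size`; rows match `images`
#'   by position when `eye_id` is absent from filenames, otherwise by the
#'   file's base name.
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if needed. Writes
#'   `biomarkers.csv`, `biomarkers.json` (with QC sidecars) and
#'   `run_report.json`.
#' @return invisibly, a data.frame of biomarker rows with attribute
#'   `exit_status`.
#' @export
run_morphometry <- function(images, rois, al_table,
                            config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(images) != length(rois))
    stop("`images` and `rois` must have equal length", call. = FALSE)
  if (is.character(al_table)) al_table <- utils::read.csv(al_table)
  if (!all(c("eye_id", "axial_length") %in% names(al_table)))
    stop("AL table needs columns eye_id, axial_length", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mcfg <- morphometry_config(
    reference_axial_length = config$reference_axial_length,
    fd_substrate = config$fd_substrate,
    min_branch_length = config$min_branch_length,
    box_sizes = config$box_sizes)
  log <- character(0)
  rows <- list(); qcs <- list()
  for (i in seq_along(images)) {
    id <- tools::file_path_sans_ext(basename(images[i]))
    res <- tryCatch({
      at <- if (id %in% al_table$eye_id)
        al_table[al_table$eye_id == id, ][1, ] else al_table[i, ]
      px <- if ("nominal_pixel_size" %in% names(at) &&
                is.finite(at$nominal_pixel_size))
        at$nominal_pixel_size else 3000 / 304
      img <- en_face_image(read_raster(images[i]),
                           nominal_pixel_size = px,
                           axial_length = at$axial_length,
                           al_bounds = config$al_bounds)
      roi <- roi_mask(read_raster(rois[i]) > 0, img)
      bm <- compute_biomarkers(img, roi, mcfg)
      qcs[[id]] <- attr(bm, "qc")
      cbind(eye_id = id, as.data.frame(bm))
    }, error = function(e) {
      log <<- c(log, sprintf("FAIL %s: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rows[[id]] <- res
      log <- c(log, sprintf("ok %s", id))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eye_id = character(0))
  rownames(out) <- NULL
  csv <- file.path(out_dir, "biomarkers.csv")
  utils::write.csv(format_num_df(out), csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(biomarkers = out, qc = qcs), file.path(out_dir, "biomarkers.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = 6)
  n_fail <- sum(grepl("^FAIL", log))
  status <- if (n_fail == 0L) 0L else 1L
  write_run_report(out_dir, "morphometry",
                   file.path(out_dir, c("biomarkers.csv",
                                        "biomarkers.json")),
                   log, status)
  attr(out, "exit_status") <- status
  invisible(out)
}

format_num_df <- function(d) {
  for (nm in names(d))
    if (is.numeric(d[[nm]])) d[[nm]] <- signif(d[[nm]], 6)
  d
}

.cohort_required <- c("eye_id", "bcva_baseline", "bcva_12m")

#' Full cohort analysis from a CSV (or data.frame)
#'
#' Validates the schema, derives the outcome group with
#' [classify_outcome()] when absent, then produces the group-comparison
#' table, the univariable and multivariable logistic tables, the
#' SFCT/letter-change linear regression and the EZ-subgroup comparison.
#'
#' @param cohort CSV path or data.frame following the column dictionary
#'   (see `system.file("extdata", "cohort_columns.csv",
#'   package = "octacnv")`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory: writes `table1_comparison.csv`,
#'   `table2_univariable.csv`, `table2_multivariable.csv`,
#'   `analyses.json`, `run_report.json`.
#' @param predictors candidate predictors for logistic screening.
#' @return invisibly, list with `comparison`, `logistic`, `linear_sfct`,
#'   `ez_subgroup`, `excluded`, and attribute `exit_status`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), out_dir,
                       predictors = c("age", "axial_length",
                                      "spherical_equivalent",
                                      "bcva_baseline", "sfct", "cft",
                                      "ez_grade", "elm_grade",
                                      "srf_present", "morphology",
                                      "branching", "loops", "dark_halo",
                                      "cnv_size", "vessel_density",
                                      "vessel_length_density",
                                      "vessel_diameter",
                                      "vessel_tortuosity",
                                      "fractal_dimension", "lacunarity",
                                      "n_injections")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  miss <- setdiff(.cohort_required, names(cohort))
  if (length(miss))
    stop("cohort schema violation; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  log <- character(0)
  if (!"group" %in% names(cohort)) {
    cohort$group <- classify_outcome(cohort$bcva_baseline, cohort$bcva_12m)
    log <- c(log, "group derived from BCVA change (>= 15 letters)")
  }
  excl <- is.na(cohort$group)
  if (any(excl)) {
    log <- c(log, sprintf("excluded (missing outcome): %s",
                          paste(cohort$eye_id[excl], collapse = ", ")))
    cohort <- cohort[!excl, , drop = FALSE]
  }
  cohort <- cohort[order(cohort$eye_id), , drop = FALSE]  # order-invariant
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  comparison <- compare_groups(cohort)
  predictors <- intersect(predictors, c(names(cohort), "age"))
  logi <- screen_and_fit_multivariable(cohort, predictors,
                                       entry_alpha = config$entry_alpha)
  lin <- if ("sfct" %in% names(cohort))
    linear_regression_change(cohort, "sfct") else NULL
  ez <- if ("ez_grade" %in% names(cohort) &&
            all(c(0, 1) %in% cohort$ez_grade))
    ez_subgroup_change(cohort) else NULL

  f1 <- file.path(out_dir, "table1_comparison.csv")
  utils::write.csv(format_num_df(as.data.frame(comparison)), f1,
                   row.names = FALSE)
  f2 <- file.path(out_dir, "table2_univariable.csv")
  utils::write.csv(format_num_df(logi$univariable), f2, row.names = FALSE)
  f3 <- file.path(out_dir, "table2_multivariable.csv")
  if (!is.null(logi$multivariable))
    utils::write.csv(format_num_df(logi$multivariable), f3,
                     row.names = FALSE)
  f4 <- file.path(out_dir, "analyses.json")
  jsonlite::write_json(list(linear_sfct = lin, ez_subgroup = ez,
                            selected = logi$selected),
                       f4, auto_unbox = TRUE, pretty = TRUE, digits = 6)
  write_run_report(out_dir, "cohort", c(f1, f2, f3, f4), log, 0L)
  out <- list(comparison = comparison, logistic = logi, linear_sfct = lin,
              ez_subgroup = ez, excluded = sum(excl))
  attr(out, "exit_status") <- 0L
  invisible(out)
}
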