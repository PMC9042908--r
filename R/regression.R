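#' Linear regression of BCVA change on a baseline covariate
#'
#' Ordinary least squares of the 12-month letter change on `x` (default
#' subfoveal choroidal thickness), with the Pearson correlation and its
#' two-sided p-value.
#'
#' @param cohort data.frame with `bcva_baseline`, `bcva_12m` and the
#'   covariate.
#' @param x covariate column name.
#' @return list with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
linear_regression_change <- function(cohort, x = "sfct") {
  xv <- cohort[[x]]
  if (is.null(xv)) stop("unknown covariate: ", x, call. = FALSE)
  dy <- cohort$bcva_12m - cohort$bcva_baseline
  keep <- !is.na(xv) & !is.na(dy)
  xv <- xv[keep]; dy <- dy[keep]
  if (length(xv) < 3L) stop("need >= 3 complete records", call. = FALSE)
  if (stats::sd(xv) == 0) stop("covariate `", x, "` is constant",
                               call. = FALSE)
  fit <- stats::lm(dy ~ xv)
  ct <- stats::cor.test(xv, dy)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}

#' Compare BCVA change between ellipsoid-zone grades
#'
#' The 12-month letter change is compared between EZ grade 0 (intact or
#' mild disruption) and grade 1 (severe) eyes with the Mann-Whitney U test.
#'
#' @param cohort data.frame with `bcva_baseline`, `bcva_12m`, `ez_grade`.
#' @return list with per-grade summaries (`mean`, `sd`, `n`) and `p_value`.
#' @export
ez_subgroup_change <- function(cohort) {
  dy <- cohort$bcva_12m - cohort$bcva_baseline
  gr <- cohort$ez_grade
  keep <- !is.na(dy) & !is.na(gr)
  dy <- dy[keep]; gr <- gr[keep]
  if (!all(c(0, 1) %in% gr))
    stop("both EZ grades must be present", call. = FALSE)
  d0 <- dy[gr == 0]; d1 <- dy[gr == 1]
  mw <- mann_whitney(d0, d1)
  list(grade0 = list(mean = mean(d0), sd = stats::sd(d0), n = length(d0)),
       grade1 = list(mean = mean(d1), sd = stats::sd(d1), n = length(d1)),
       U = mw$U, p_value = mw$p_value)
}
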