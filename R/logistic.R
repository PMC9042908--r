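# Logistic-regression predictor screening. Binary predictors are coded so
# the odds ratio reads "odds of improvement for the favourable/flagged
# level": EZ and ELM grade 0 = 1, age < 55 years = 1, subretinal fluid
# absent = 1, medusa/sea-fan morphology = 1, and the qualitative OCTA flags
# (branching, loops, dark halo) present = 1. Continuous predictors enter
# per unit.

.predictor_codings <- list(
  age = list(fun = function(d) as.numeric(d$age < 55),
             label = "age < 55 years = 1"),
  age_ge_55 = list(fun = function(d) as.numeric(!d$age_ge_55),
                   label = "age < 55 years = 1"),
  ez_grade = list(fun = function(d) as.numeric(d$ez_grade == 0),
                  label = "EZ grade 0 = 1"),
  elm_grade = list(fun = function(d) as.numeric(d$elm_grade == 0),
                   label = "ELM grade 0 = 1"),
  srf_present = list(fun = function(d) as.numeric(!d$srf_present),
                     label = "subretinal fluid absent = 1"),
  morphology = list(fun = function(d)
    as.numeric(d$morphology == "medusa_seafan"),
    label = "medusa/sea-fan = 1"),
  branching = list(fun = function(d) as.numeric(d$branching != 0),
                   label = "branching vessels present = 1"),
  loops = list(fun = function(d) as.numeric(d$loops != 0),
               label = "anastomotic loops present = 1"),
  dark_halo = list(fun = function(d) as.numeric(d$dark_halo != 0),
                   label = "dark halo present = 1"),
  sex = list(fun = function(d) as.numeric(d$sex == "F"),
             label = "female = 1"))

predictor_vector <- function(cohort, variable) {
  if (variable %in% names(.predictor_codings)) {
    cd <- .predictor_codings[[variable]]
    list(x = cd$fun(cohort), label = cd$label)
  } else {
    x <- cohort[[variable]]
    if (is.null(x)) stop("unknown variable: ", variable, call. = FALSE)
    list(x = as.numeric(x), label = paste0(variable, " per unit"))
  }
}

outcome_vector <- function(cohort) {
  if (!"group" %in% names(cohort))
    stop("cohort must have a `group` column", call. = FALSE)
  as.numeric(cohort$group == "improved")
}

#' Univariable logistic regression for one predictor
#'
#' Maximum-likelihood logistic fit of improved-vs-not on a single
#' predictor. The odds ratio is per unit for continuous predictors and
#' versus the reference level for binary ones (see the coding table in the
#' package source; it is echoed in `predictor_coding`). The 95\% CI is the
#' Wald interval exp(coef +/- 1.96 SE). For a binary predictor with all
#' four 2x2 cells positive this equals the closed form OR = ad/bc with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d).
#'
#' @param cohort data.frame with `group` and the predictor columns.
#' @param variable predictor name.
#' @return object of class `logistic_result`: list with `variable`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `coef`, `se`,
#'   `predictor_coding`, `separation` flag, `n`.
#' @export
univariable_logistic <- function(cohort, variable) {
  y <- outcome_vector(cohort)
  pv <- predictor_vector(cohort, variable)
  keep <- !is.na(y) & !is.na(pv$x)
  y <- y[keep]; x <- pv$x[keep]
  if (length(unique(y)) < 2L)
    stop("outcome is constant", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("predictor `", variable, "` is constant", call. = FALSE)
  sep <- FALSE
  if (all(x %in% c(0, 1))) {
    cells <- c(sum(y & x), sum(y & !x), sum(!y & x), sum(!y & !x))
    sep <- any(cells == 0)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  p <- co["x", "Pr(>|z|)"]
  res <- list(variable = variable,
              odds_ratio = exp(beta),
              ci_low = if (sep) NA_real_ else exp(beta - 1.96 * se),
              ci_high = if (sep) NA_real_ else exp(beta + 1.96 * se),
              p_value = p, coef = beta, se = se,
              predictor_coding = pv$label,
              separation = sep, n = length(y),
              converged = fit$converged)
  class(res) <- "logistic_result"
  if (sep) warning("separation (empty 2x2 cell) for `", variable,
                   "`: Wald CI not reported")
  res
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (%.3f-%.3f), p = %.3f  [%s]\n",
              x$variable, x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
              x$predictor_coding))
  invisible(x)
}

#' Screen predictors and fit the multivariable logistic model
#'
#' Every candidate is first fitted univariably; those with p below
#' `entry_alpha` (default 0.1) enter one joint maximum-likelihood logistic
#' model. Adjusted odds ratios, Wald CIs and p-values are reported per
#' retained variable.
#'
#' @param cohort data.frame with `group` and predictors.
#' @param variables candidate predictor names.
#' @param entry_alpha univariable p-value threshold for entry.
#' @return list with `univariable` (data.frame), `selected` (names),
#'   `multivariable` (data.frame, NULL when nothing is selected) and
#'   `converged`.
#' @export
screen_and_fit_multivariable <- function(cohort, variables,
                                         entry_alpha = 0.1) {
  uni <- lapply(variables, function(v)
    tryCatch(suppressWarnings(univariable_logistic(cohort, v)),
             error = function(e) NULL))
  ok <- !vapply(uni, is.null, logical(1))
  uni <- uni[ok]; variables <- variables[ok]
  uni_df <- do.call(rbind, lapply(uni, function(r)
    data.frame(variable = r$variable, odds_ratio = r$odds_ratio,
               ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
               predictor_coding = r$predictor_coding,
               separation = r$separation, stringsAsFactors = FALSE)))
  selected <- uni_df$variable[uni_df$p_value < entry_alpha]
  if (length(selected) == 0L) {
    message("no variable passed univariable screening at alpha = ",
            entry_alpha)
    return(list(univariable = uni_df, selected = character(0),
                multivariable = NULL, converged = NA))
  }
  y <- outcome_vector(cohort)
  X <- vapply(selected, function(v) predictor_vector(cohort, v)$x,
              numeric(nrow(cohort)))
  X <- as.data.frame(X)
  keep <- stats::complete.cases(cbind(y, X))
  dat <- cbind(y = y[keep], X[keep, , drop = FALSE])
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  multi <- do.call(rbind, lapply(selected, function(v) {
    beta <- co[v, "Estimate"]; se <- co[v, "Std. Error"]
    data.frame(variable = v, odds_ratio = exp(beta),
               ci_low = exp(beta - 1.96 * se),
               ci_high = exp(beta + 1.96 * se),
               p_value = co[v, "Pr(>|z|)"],
               predictor_coding = uni_df$predictor_coding[
                 uni_df$variable == v],
               stringsAsFactors = FALSE)
  }))
  if (!fit$converged)
    warning("multivariable logistic model did not converge")
  list(univariable = uni_df, selected = selected, multivariable = multi,
       converged = fit$converged)
}
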