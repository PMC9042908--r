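# Two-group cohort statistics: outcome grouping, 2x2 chi-square,
# Mann-Whitney U, and the combined group-comparison table.

#' Classify the visual outcome of one eye
#'
#' Clinically significant improvement is a gain of at least 15 ETDRS
#' letters (three lines) at 12 months; the boundary is inclusive.
#'
#' @param bcva_baseline,bcva_12m ETDRS letter scores in [0, 100].
#' @return "improved" or "maintained_worse"; `NA` when either score is
#'   missing (the record is then excluded upstream).
#' @export
classify_outcome <- function(bcva_baseline, bcva_12m) {
  ok <- function(v) is.na(v) | (v >= 0 & v <= 100)
  if (!all(ok(bcva_baseline)) || !all(ok(bcva_12m)))
    stop("ETDRS letter scores must lie in [0, 100]", call. = FALSE)
  ifelse(is.na(bcva_baseline) | is.na(bcva_12m), NA_character_,
         ifelse(bcva_12m - bcva_baseline >= 15, "improved",
                "maintained_worse"))
}

#' A 2x2 contingency table
#'
#' Rows are outcome groups (improved first), columns predictor levels
#' (coded level first): counts (a, b; c, d).
#'
#' @param a,b,c,d non-negative integer counts.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("empty 2x2 table", call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

tbl_margins <- function(t)
  c(row1 = t$a + t$b, row2 = t$c + t$d, col1 = t$a + t$c, col2 = t$b + t$d)

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), compared against the
#' 1-df chi-square distribution.
#'
#' @param t a [two_by_two()] table (or 2x2 matrix).
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(t) {
  if (is.matrix(t)) t <- two_by_two(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  stopifnot(inherits(t, "two_by_two"))
  m <- tbl_margins(t)
  if (any(m == 0))
    stop("zero margin (", paste(names(m)[m == 0], collapse = ", "),
         "): chi-square undefined", call. = FALSE)
  n <- t$a + t$b + t$c + t$d
  stat <- n * (t$a * t$d - t$b * t$c)^2 / prod(m)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Two-sided. With `n1 + n2 <= 12` and no ties the p-value is computed by
#' exact enumeration of all group labelings; otherwise by the normal
#' approximation with tie correction (continuity correction off by
#' default).
#'
#' @param x,y numeric samples (non-empty).
#' @param continuity apply a 0.5 continuity correction in the normal
#'   approximation.
#' @return list with `U` (for the first sample), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, continuity = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (n1 + n2 <= 12L && !has_ties) {
    # exact: distribution of U over all C(n1+n2, n1) labelings
    combs <- utils::combn(n1 + n2, n1)
    r_all <- rank(pooled)
    Us <- apply(combs, 2L, function(ix) sum(r_all[ix]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu)
  if (continuity) z <- sign(z) * max(abs(z) - 0.5, 0)
  z <- z / sqrt(sigma2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

# variable dictionary: type drives the test and the Table-1-style summary
.cohort_continuous <- c("age", "axial_length", "spherical_equivalent",
                        "bcva_baseline", "bcva_12m", "sfct", "cft",
                        "cnv_size", "vessel_density",
                        "vessel_length_density", "vessel_diameter",
                        "vessel_tortuosity", "fractal_dimension",
                        "lacunarity", "n_injections")
.cohort_categorical <- c("age_ge_55", "sex", "ez_grade", "elm_grade",
                         "srf_present", "morphology", "branching", "loops",
                         "dark_halo")

#' Compare the two outcome groups variable by variable
#'
#' Continuous variables are compared with the Mann-Whitney U test and
#' summarized as mean +/- SD; categorical variables with the uncorrected
#' chi-square test and summarized as counts. Records missing a variable are
#' dropped for that variable only (complete-case per analysis) and counted
#' in `n_excluded`.
#'
#' @param cohort data.frame with a `group` column
#'   ("improved" / "maintained_worse") and any subset of the standard
#'   variables (see [make_cohort()] for the dictionary).
#' @param variables which variables to compare; default every dictionary
#'   variable present in `cohort`.
#' @return data.frame of class `comparison_report`: variable, type, test,
#'   group summaries, statistic, p_value, n_excluded, note.
#' @export
compare_groups <- function(cohort, variables = NULL) {
  if (!"group" %in% names(cohort))
    stop("cohort must have a `group` column", call. = FALSE)
  g <- cohort$group
  if (length(unique(g[!is.na(g)])) < 2L)
    stop("both outcome groups must be present", call. = FALSE)
  imp <- g == "improved"
  if (is.null(variables))
    variables <- intersect(c(.cohort_continuous, .cohort_categorical),
                           names(cohort))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(g)
    n_exc <- sum(!keep)
    x <- x[keep]; gi <- imp[keep]
    type <- if (v %in% .cohort_continuous ||
                (is.numeric(x) && !v %in% .cohort_categorical))
      "continuous" else "categorical"
    if (sum(gi) == 0L || sum(!gi) == 0L)
      return(data.frame(variable = v, type = type, test = "none",
                        improved = NA_character_,
                        maintained_worse = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        n_excluded = n_exc, note = "a group is empty",
                        stringsAsFactors = FALSE))
    if (type == "continuous") {
      s1 <- sprintf("%.2f ± %.2f", mean(x[gi]), stats::sd(x[gi]))
      s2 <- sprintf("%.2f ± %.2f", mean(x[!gi]), stats::sd(x[!gi]))
      if (length(unique(x)) < 2L)
        return(data.frame(variable = v, type = type, test = "none",
                          improved = s1, maintained_worse = s2,
                          statistic = NA_real_, p_value = NA_real_,
                          n_excluded = n_exc, note = "constant variable",
                          stringsAsFactors = FALSE))
      mw <- mann_whitney(x[gi], x[!gi])
      data.frame(variable = v, type = type, test = "mann_whitney",
                 improved = s1, maintained_worse = s2,
                 statistic = mw$U, p_value = mw$p_value,
                 n_excluded = n_exc, note = mw$method,
                 stringsAsFactors = FALSE)
    } else {
      xf <- factor(x)
      if (nlevels(xf) < 2L)
        return(data.frame(variable = v, type = type, test = "none",
                          improved = as.character(sum(gi)),
                          maintained_worse = as.character(sum(!gi)),
                          statistic = NA_real_, p_value = NA_real_,
                          n_excluded = n_exc, note = "constant variable",
                          stringsAsFactors = FALSE))
      if (nlevels(xf) > 2L)
        stop("variable `", v, "` has more than 2 levels", call. = FALSE)
      lev1 <- levels(xf)[2L]   # "success" level: TRUE/1/second factor level
      t <- two_by_two(sum(gi & xf == lev1), sum(gi & xf != lev1),
                      sum(!gi & xf == lev1), sum(!gi & xf != lev1))
      cs <- tryCatch(chi_square_2x2(t), error = function(e)
        list(statistic = NA_real_, p_value = NA_real_,
             note = conditionMessage(e)))
      data.frame(variable = v, type = type, test = "chi_square",
                 improved = sprintf("%d/%d", t$a, t$b),
                 maintained_worse = sprintf("%d/%d", t$c, t$d),
                 statistic = cs$statistic, p_value = cs$p_value,
                 n_excluded = n_exc,
                 note = if (is.null(cs$note)) paste0("level=", lev1)
                        else cs$note,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", class(out))
  out
}
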