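# Synthetic two-group cohorts. Defaults reproduce the published group
# means/SDs and category proportions of a 17 + 17 eye anti-VEGF outcome
# cohort, so the group-comparison and regression machinery can be exercised
# (and power-checked) without patient data.

.grp_improved <- list(
  continuous = list(
    age = c(53.71, 18.98), axial_length = c(28.79, 1.59),
    spherical_equivalent = c(-12.18, 3.10), bcva_baseline = c(49.12, 21.08),
    bcva_12m = c(72.35, 15.62), sfct = c(79.97, 33.15),
    cft = c(267.33, 119.62), cnv_size = c(0.329, 0.257),
    vessel_density = c(41.31, 13.23), vessel_length_density = c(21.21, 8.18),
    vessel_tortuosity = c(1.22, 0.062), fractal_dimension = c(1.45, 0.101),
    lacunarity = c(0.367, 0.066), n_injections = c(2.41, 1.23)),
  proportions = c(sex_female = 15 / 17, ez_grade0 = 10 / 17,
                  elm_grade0 = 11 / 17, srf_present = 2 / 17,
                  morph_medusa = 6 / 17, branching = 8 / 17,
                  loops = 6 / 17, dark_halo = 11 / 17))

.grp_worse <- list(
  continuous = list(
    age = c(60.24, 15.73), axial_length = c(29.19, 0.94),
    spherical_equivalent = c(-12.18, 4.45), bcva_baseline = c(53.53, 19.67),
    bcva_12m = c(48.82, 23.69), sfct = c(50.66, 18.31),
    cft = c(211.69, 82.52), cnv_size = c(0.481, 0.234),
    vessel_density = c(43.69, 7.66), vessel_length_density = c(21.75, 4.52),
    vessel_tortuosity = c(1.21, 0.097), fractal_dimension = c(1.53, 0.082),
    lacunarity = c(0.391, 0.079), n_injections = c(2.76, 1.75)),
  proportions = c(sex_female = 15 / 17, ez_grade0 = 4 / 17,
                  elm_grade0 = 6 / 17, srf_present = 3 / 17,
                  morph_medusa = 4 / 17, branching = 6 / 17,
                  loops = 7 / 17, dark_halo = 8 / 17))

#' Specification of a synthetic two-group cohort
#'
#' Per-group means/SDs for continuous variables and proportions for binary
#' ones. Defaults are the published group summaries of a 17-vs-17 eye
#' cohort (visual gain >= 15 ETDRS letters vs less).
#'
#' @param n_per_group length-2 integer, eyes in (improved, maintained/worse).
#' @param improved,worse per-group parameter lists with elements
#'   `continuous` (named list of c(mean, sd)) and `proportions` (named
#'   vector in [0, 1]).
#' @param constrain_outcome when TRUE (default) the 12-month BCVA is drawn
#'   so that the letter gain is >= 15 exactly in the improved group,
#'   making the outcome label consistent with [classify_outcome()]; when
#'   FALSE the 12-month value is drawn independently (use for null
#'   calibration).
#' @param seed integer seed fixing the draw.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(17L, 17L),
                        improved = .grp_improved, worse = .grp_worse,
                        constrain_outcome = TRUE, seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 0))
  if (sum(n_per_group) == 0) stop("empty cohort spec", call. = FALSE)
  for (g in list(improved, worse)) {
    stopifnot(is.list(g$continuous), is.numeric(g$proportions))
    if (any(g$proportions < 0 | g$proportions > 1))
      stop("proportions must lie in [0, 1]", call. = FALSE)
    sds <- vapply(g$continuous, `[`, numeric(1), 2L)
    if (any(sds <= 0)) stop("SDs must be positive", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 improved = improved, worse = worse,
                 constrain_outcome = isTRUE(constrain_outcome),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null (zero-effect) cohort specification
#'
#' Both groups share the pooled parameters, so every group comparison tests
#' a true null; used for type-I-error calibration.
#'
#' @inheritParams cohort_spec
#' @return a [cohort_spec()] with identical groups and unconstrained
#'   outcome.
#' @export
null_cohort_spec <- function(n_per_group = c(17L, 17L), seed = 1L) {
  pool <- .grp_improved
  for (nm in names(pool$continuous))
    pool$continuous[[nm]] <- c(
      mean(c(.grp_improved$continuous[[nm]][1],
             .grp_worse$continuous[[nm]][1])),
      mean(c(.grp_improved$continuous[[nm]][2],
             .grp_worse$continuous[[nm]][2])))
  pool$proportions <- (.grp_improved$proportions + .grp_worse$proportions) / 2
  cohort_spec(n_per_group, improved = pool, worse = pool,
              constrain_outcome = FALSE, seed = seed)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.trunc_bounds <- list(
  age = c(18, 95), axial_length = c(24, 35.9),
  spherical_equivalent = c(-30, -0.5), bcva_baseline = c(0, 100),
  bcva_12m = c(0, 100), sfct = c(10, 400), cft = c(50, 900),
  cnv_size = c(0.01, 3), vessel_density = c(5, 95),
  vessel_length_density = c(1, 95), vessel_tortuosity = c(1, 2.5),
  fractal_dimension = c(0.8, 2), lacunarity = c(0.01, 1.5),
  n_injections = c(0, 12))

draw_group <- function(n, pars, group_label, constrain_outcome) {
  cont <- pars$continuous
  draw <- function(nm) {
    b <- .trunc_bounds[[nm]]
    rtrunc_norm(n, cont[[nm]][1], cont[[nm]][2], b[1], b[2])
  }
  age <- draw("age")
  bcva_baseline <- draw("bcva_baseline")
  if (constrain_outcome) {
    dmean <- cont$bcva_12m[1] - cont$bcva_baseline[1]
    if (group_label == "improved") {
      bcva_baseline <- pmin(bcva_baseline, 85)
      delta <- rtrunc_norm(n, dmean, 10, 15, 100)
      bcva_12m <- pmin(bcva_baseline + delta, 100)
      # clipping at 100 letters must not drop the gain below 15
      bcva_baseline <- pmin(bcva_baseline, bcva_12m - 15)
    } else {
      delta <- rtrunc_norm(n, dmean, 12, -100, 15 - 1e-6)
      bcva_12m <- pmin(pmax(bcva_baseline + delta, 0), 100)
    }
  } else {
    bcva_12m <- draw("bcva_12m")
  }
  vd <- draw("vessel_density")
  vld_raw <- draw("vessel_length_density")
  vld <- pmin(vld_raw, vd)   # skeleton cannot exceed the mask
  pr <- pars$proportions
  bern <- function(nm) stats::runif(n) < pr[[nm]]
  data.frame(
    group = group_label,
    age = age,
    age_ge_55 = age >= 55,
    sex = ifelse(bern("sex_female"), "F", "M"),
    axial_length = draw("axial_length"),
    spherical_equivalent = draw("spherical_equivalent"),
    bcva_baseline = bcva_baseline,
    bcva_12m = bcva_12m,
    sfct = draw("sfct"),
    cft = draw("cft"),
    ez_grade = ifelse(bern("ez_grade0"), 0L, 1L),
    elm_grade = ifelse(bern("elm_grade0"), 0L, 1L),
    srf_present = bern("srf_present"),
    morphology = ifelse(bern("morph_medusa"), "medusa_seafan", "tangled"),
    branching = bern("branching"),
    loops = bern("loops"),
    dark_halo = bern("dark_halo"),
    cnv_size = draw("cnv_size"),
    vessel_density = vd,
    vessel_length_density = vld,
    vessel_diameter = vd / vld,
    vessel_tortuosity = draw("vessel_tortuosity"),
    fractal_dimension = draw("fractal_dimension"),
    lacunarity = draw("lacunarity"),
    n_injections = round(draw("n_injections")),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' One row per eye with clinical fields, OCT grades, qualitative OCTA flags,
#' quantitative biomarkers and the outcome group. Deterministic given the
#' spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per eye; column `group` is
#'   "improved" / "maintained_worse".
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (sum(spec$n_per_group) == 0L) stop("empty cohort", call. = FALSE)
  set.seed(spec$seed)
  d <- rbind(
    draw_group(spec$n_per_group[1], spec$improved, "improved",
               spec$constrain_outcome),
    draw_group(spec$n_per_group[2], spec$worse, "maintained_worse",
               spec$constrain_outcome))
  d <- cbind(eye_id = sprintf("eye%03d", seq_len(nrow(d))), d)
  rownames(d) <- NULL
  d
}
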