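#' Fraction of patients graded identically by every member parameter
#'
#' The "joint shock class" event: all member parameters assign the same class
#' to a patient. A small joint fraction is what makes the maximum-allocation
#' composite diverge from its members.
#'
#' @param classes a `shock_class_table` from [classify_cohort()].
#' @param members parameter subset (default the three traditional vital
#'   parameters).
#' @return fraction in `[0, 1]`.
#' @export
joint_class_fraction <- function(classes, members = c("hr", "sbp", "gcs")) {
  stopifnot(length(members) >= 1)
  if (nrow(classes) == 0L) stop("joint_class_fraction: empty table", call. = FALSE)
  m <- as.matrix(classes[paste0(members, "_class")])
  mean(apply(m, 1L, function(r) all(r == r[1L])))
}

# class labels used in all reports
roman_classes <- c("I", "II", "III", "IV")

scheme_classes <- function(classes, scheme) {
  cols <- c(hr = "hr_class", sbp = "sbp_class", gcs = "gcs_class",
            bd = "bd_class", composite = "composite_class")
  if (!scheme %in% names(cols))
    stop("unknown scheme '", scheme, "'", call. = FALSE)
  classes[[cols[[scheme]]]]
}

#' Per-class transfusion summary under one grading scheme
#'
#' @param cohort a `cohort_table`.
#' @param classes the row-aligned `shock_class_table`.
#' @param scheme `"composite"` or one of `"hr", "sbp", "gcs", "bd"`.
#' @return data.frame with one row per class I-IV: `class`, `n`, `mean`, `sd`
#'   (moments `NA` and flagged via `degenerate` when `n` is 0 or 1).
#' @export
group_transfusion_stats <- function(cohort, classes, scheme) {
  if (nrow(cohort) != nrow(classes))
    stop("group_transfusion_stats: cohort and class tables are misaligned", call. = FALSE)
  g <- scheme_classes(classes, scheme)
  out <- lapply(1:4, function(k) {
    x <- cohort$transfusion[g == k]
    data.frame(class = roman_classes[k], n = length(x),
               mean = if (length(x) >= 1) mean(x) else NA_real_,
               sd = if (length(x) >= 2) sd(x) else NA_real_,
               degenerate = length(x) < 2)
  })
  do.call(rbind, out)
}

#' Two-sample t-test (classical pooled-variance, or Welch)
#'
#' The textbook pooled statistic
#' `t = (mean(x) - mean(y)) / (s_p * sqrt(1/nx + 1/ny))` with
#' `s_p^2 = ((nx-1) s_x^2 + (ny-1) s_y^2) / (nx + ny - 2)`, two-sided p from
#' the t distribution on `nx + ny - 2` degrees of freedom. Degenerate input
#' (either group below 2 observations, or zero pooled variance) is flagged,
#' never fabricated: `t` is `NA` (or signed `Inf` when means differ with zero
#' pooled variance) and `p` is `NA`.
#'
#' @param x,y numeric samples.
#' @param welch use the Welch statistic and Satterthwaite df instead?
#' @return list `t`, `df`, `p`, `flag` (`"ok"`, `"degenerate-n"`, or
#'   `"zero-variance"`).
#' @export
pooled_t_test <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, flag = "degenerate-n"))
  vx <- var(x); vy <- var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) {
      d <- mean(x) - mean(y)
      return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_,
                  p = NA_real_, flag = "zero-variance"))
    }
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) {
      d <- mean(x) - mean(y)
      return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_,
                  p = NA_real_, flag = "zero-variance"))
    }
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df), flag = "ok")
}

#' Compare the singleton scheme against the composite, class by class
#'
#' For each shock class I-IV, compares transfusion quantity between the
#' patients assigned that class by the singleton parameter and the patients
#' assigned that class by the composite — the head-to-head design under
#' audit. The two groups overlap in membership (the same patients can appear
#' in both); the naive unpaired test is applied deliberately, exactly as in
#' the method under study, and the overlap caveat is recorded on the result.
#'
#' @param cohort a `cohort_table`.
#' @param classes the row-aligned `shock_class_table`.
#' @param singleton the single parameter (must not be a composite member).
#' @param welch use Welch's t-test?
#' @return data.frame with one row per class: group sizes, means, SDs,
#'   `t_statistic`, `df`, `p_value`, `flag`; attribute
#'   `caveat = "overlapping-groups"`.
#' @export
compare_schemes <- function(cohort, classes, singleton, welch = FALSE) {
  if (singleton %in% attr(classes, "composite_members"))
    stop("compare_schemes: singleton must not be a composite member", call. = FALSE)
  if (nrow(cohort) != nrow(classes))
    stop("compare_schemes: cohort and class tables are misaligned", call. = FALSE)
  gs <- scheme_classes(classes, singleton)
  gc <- scheme_classes(classes, "composite")
  rows <- lapply(1:4, function(k) {
    x <- cohort$transfusion[gs == k]  # singleton group
    y <- cohort$transfusion[gc == k]  # composite group
    tt <- pooled_t_test(x, y, welch = welch)
    data.frame(class = roman_classes[k],
               n_singleton = length(x), n_composite = length(y),
               mean_singleton = if (length(x)) mean(x) else NA_real_,
               mean_composite = if (length(y)) mean(y) else NA_real_,
               sd_singleton = if (length(x) >= 2) sd(x) else NA_real_,
               sd_composite = if (length(y) >= 2) sd(y) else NA_real_,
               t_statistic = tt$t, df = tt$df, p_value = tt$p, flag = tt$flag)
  })
  structure(do.call(rbind, rows), singleton = singleton,
            caveat = "overlapping-groups")
}

#' Post-processing Spearman correlations with transfusion
#'
#' Rank correlation (average ranks on ties) between each predictor and the
#' transfusion outcome, computed on the final truncated/rounded cohort — the
#' realized dependence after clipping and discretization have attenuated the
#' copula targets.
#'
#' @param cohort a `cohort_table` with at least 3 rows.
#' @return named numeric vector over `hr, sbp, gcs, bd` (`NA` with a warning
#'   for a constant column).
#' @export
postprocessing_spearman <- function(cohort) {
  if (nrow(cohort) < 3) stop("postprocessing_spearman: need n >= 3", call. = FALSE)
  vapply(c("hr", "sbp", "gcs", "bd"), function(v) {
    if (sd(cohort[[v]]) == 0 || sd(cohort$transfusion) == 0) {
      warning("postprocessing_spearman: constant column, correlation undefined")
      return(NA_real_)
    }
    cor(cohort[[v]], cohort$transfusion, method = "spearman")
  }, numeric(1))
}

#' Run one scenario end to end
#'
#' Simulates the cohort, classifies it, and collects every bias statistic:
#' per-class transfusion summaries under both schemes, singleton-vs-composite
#' per-class t-tests, post-processing Spearman correlations, and the
#' joint-class fraction (over the three traditional parameters and over all
#' four). Degenerate classes are flagged in place rather than aborting.
#'
#' @param config a [scenario_config()].
#' @return an object of class `experiment_summary`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cohort <- simulate_cohort(config)
  summarize_scenario(cohort, config, attr(cohort, "copula"))
}

# shared summary assembly: run_scenario() builds it from a fresh simulation,
# replay_run() from a saved cohort.csv; identical inputs give byte-identical
# serialized summaries
summarize_scenario <- function(cohort, config, copula_val) {
  classes <- classify_cohort(cohort, config$composite_members,
                             seed = config$seed, gcs_split = config$gcs_split)
  comparisons <- compare_schemes(cohort, classes, config$comparison_singleton,
                                 welch = config$welch)
  structure(list(
    scenario_id = config$scenario_id,
    n = config$n, seed = config$seed,
    comparisons = comparisons,
    singleton_stats = group_transfusion_stats(cohort, classes, config$comparison_singleton),
    composite_stats = group_transfusion_stats(cohort, classes, "composite"),
    postprocessing_spearman = postprocessing_spearman(cohort),
    joint_class_fraction = joint_class_fraction(classes, c("hr", "sbp", "gcs")),
    joint_class_fraction_all4 = joint_class_fraction(classes, c("hr", "sbp", "gcs", "bd")),
    copula = copula_val[c("repaired", "repair_distance", "min_eigenvalue")],
    config = list(scenario_id = config$scenario_id, n = config$n, seed = config$seed,
                  composite_members = config$composite_members,
                  comparison_singleton = config$comparison_singleton,
                  truncation = config$truncation, gcs_split = config$gcs_split,
                  welch = config$welch,
                  placeholder_marginals = config$placeholder_marginals,
                  marginals = lapply(config$marginals, unclass),
                  correlation = list(magnitudes = config$correlation$magnitudes,
                                     signs = config$correlation$signs)),
    warnings = c(if (config$placeholder_marginals) "placeholder-marginals",
                 if (copula_val$repaired) "pd-repair",
                 if (any(comparisons$flag != "ok")) "degenerate-classes",
                 "overlapping-groups-ttest")
  ), class = "experiment_summary")
}

#' Run the four scenarios of the bias experiment
#'
#' Per-scenario seeds are derived from the master seed by correlation
#' structure, not by scenario, so `equal` and `swap-equal` (and `unequal` and
#' `swap-unequal`) share the identical cohort draw — only the composite
#' membership differs. One scenario failing does not abort the rest.
#'
#' @param master_config list as produced by [default_config()] /
#'   [load_and_validate_config()].
#' @return named list of `experiment_summary` (or `try-error`) objects.
#' @export
run_all_scenarios <- function(master_config = default_config()) {
  scen <- c("equal", "unequal", "swap-equal", "swap-unequal")
  out <- lapply(scen, function(s) {
    try(run_scenario(config_for_scenario(master_config, s)), silent = TRUE)
  })
  names(out) <- scen
  out
}
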