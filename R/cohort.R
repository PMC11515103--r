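#' Scenario configuration
#'
#' Bundles everything needed to simulate and analyse one scenario: cohort
#' size, seed, marginals, dependence targets, which parameters form the
#' maximum-allocation composite and which single parameter is compared against
#' it.
#'
#' @param scenario_id `"equal"`, `"unequal"`, `"swap-equal"` or
#'   `"swap-unequal"`.
#' @param n cohort size (default 16305, the size of the registry cohort the
#'   original comparison analysed).
#' @param seed integer seed for this scenario. The copula draw and the GCS-15
#'   class-split draw use two substreams derived from it (see [derive_seed()]),
#'   so classification randomness never perturbs cohort values.
#' @param marginals list of five [marginal_spec()]s (default
#'   [default_marginals()], flagged as placeholders).
#' @param correlation a [correlation_spec()]; defaults to
#'   [scenario_correlation()] for `scenario_id`.
#' @param composite_members parameters pooled by the maximum rule; default
#'   `c("hr", "sbp", "gcs")`, or `c("bd", "sbp", "gcs")` for swap scenarios.
#' @param comparison_singleton the parameter compared against the composite;
#'   default `"bd"`, or `"hr"` for swap scenarios.
#' @param truncation `"quantile"` (inverse CDF of the truncated law; no point
#'   mass at the limits) or `"clip"` (post-hoc clipping).
#' @param gcs_split `"bernoulli"` (independent fair coin per GCS-15 patient)
#'   or `"exact-half"` (seeded permutation split).
#' @param welch use Welch's t-test instead of the classical pooled-variance
#'   test in scheme comparisons?
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_id = c("equal", "unequal", "swap-equal", "swap-unequal"),
                            n = 16305, seed = 1L,
                            marginals = default_marginals(),
                            correlation = NULL,
                            composite_members = NULL,
                            comparison_singleton = NULL,
                            truncation = c("quantile", "clip"),
                            gcs_split = c("bernoulli", "exact-half"),
                            welch = FALSE) {
  scenario_id <- match.arg(scenario_id)
  truncation <- match.arg(truncation)
  gcs_split <- match.arg(gcs_split)
  swap <- startsWith(scenario_id, "swap")
  if (is.null(composite_members))
    composite_members <- if (swap) c("bd", "sbp", "gcs") else c("hr", "sbp", "gcs")
  if (is.null(comparison_singleton))
    comparison_singleton <- if (swap) "hr" else "bd"
  if (is.null(correlation)) correlation <- scenario_correlation(scenario_id)
  stopifnot(inherits(correlation, "correlation_spec"))
  predictors <- c("hr", "sbp", "gcs", "bd")
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("scenario_config: n must be >= 2", call. = FALSE)
  if (comparison_singleton %in% composite_members ||
      !setequal(c(composite_members, comparison_singleton), predictors))
    stop("scenario_config: composite_members and comparison_singleton must be disjoint and cover hr, sbp, gcs, bd",
         call. = FALSE)
  stopifnot(setequal(names(marginals), var_order))
  for (m in marginals) stopifnot(inherits(m, "marginal_spec"))
  structure(list(scenario_id = scenario_id, n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals[var_order], correlation = correlation,
                 composite_members = composite_members,
                 comparison_singleton = comparison_singleton,
                 truncation = truncation, gcs_split = gcs_split, welch = welch,
                 placeholder_marginals = isTRUE(attr(marginals, "placeholder"))),
            class = "scenario_config")
}

#' Simulate one synthetic trauma cohort
#'
#' Validates the copula correlation matrix (repairing to the nearest feasible
#' PD matrix when the targets are jointly infeasible), samples copula
#' uniforms, and pushes each column through its marginal inverse CDF with
#' truncation and rounding. The result is a pure function of the config.
#'
#' @param config a [scenario_config()].
#' @return a data.frame of class `cohort_table` with columns
#'   `hr, sbp, gcs, bd, transfusion`, one row per patient, and attributes
#'   `copula` (the validation result, including any repair distance),
#'   `scenario_id`, `seed`, `truncation` and `placeholder_marginals`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n < 1) stop("simulate_cohort: empty cohort requested", call. = FALSE)
  val <- validate_correlation_matrix(config$correlation)
  U <- sample_copula(config$n, val$matrix, derive_seed(config$seed, 1L))
  cols <- lapply(var_order, function(v)
    inverse_marginal(config$marginals[[v]], U[, v], truncation = config$truncation))
  names(cols) <- var_order
  out <- as.data.frame(cols)
  structure(out, class = c("cohort_table", "data.frame"),
            copula = val, scenario_id = config$scenario_id, seed = config$seed,
            truncation = config$truncation,
            placeholder_marginals = config$placeholder_marginals)
}
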