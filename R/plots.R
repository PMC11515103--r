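#' Histograms of the five simulated variables
#'
#' Content mirror of the usual marginal-distribution panel for a simulated
#' cohort (value counts on the y axis); styling is deliberately plain.
#'
#' @param cohort a `cohort_table`.
#' @return invisibly, `NULL`. Called for its side effect.
#' @export
plot_cohort_histograms <- function(cohort) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  units <- c(hr = "beats/min", sbp = "mmHg", gcs = "score",
             bd = "mmol/L", transfusion = "units pRBC")
  for (v in names(units)) {
    if (v == "gcs") {
      tab <- table(factor(cohort$gcs, levels = 3:15))
      graphics::barplot(tab, main = "gcs", xlab = units[[v]], ylab = "count")
    } else {
      graphics::hist(cohort[[v]], breaks = 40, main = v, xlab = units[[v]],
                     ylab = "count")
    }
  }
  invisible(NULL)
}

#' Per-class mean transfusion under the two grading schemes
#'
#' Side-by-side per-class mean transfusion quantity for the singleton
#' parameter and the maximum-allocation composite — the content of the
#' scheme-comparison figure, without its styling.
#'
#' @param summary an `experiment_summary`.
#' @return invisibly, `NULL`. Called for its side effect.
#' @export
plot_class_means <- function(summary) {
  stopifnot(inherits(summary, "experiment_summary"))
  m <- rbind(singleton = summary$comparisons$mean_singleton,
             composite = summary$comparisons$mean_composite)
  colnames(m) <- summary$comparisons$class
  graphics::barplot(m, beside = TRUE, legend.text = c(
    summary$config$comparison_singleton,
    paste0("max(", paste(summary$config$composite_members, collapse = ","), ")")),
    xlab = "shock class", ylab = "mean transfusion (units pRBC)",
    main = summary$scenario_id)
  invisible(NULL)
}
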