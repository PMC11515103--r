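#' Shock-class threshold table
#'
#' Numeric interpretation of the four-class (I-IV) hypovolemic shock grading
#' for heart rate, systolic blood pressure and base deficit. Printed interval
#' endpoints overlap in the source table ("100-120" / "120-140"); the
#' conventions fixed here are the unique reading consistent with the
#' explicitly marked entries (class IV heart rate is "> 140", base deficit
#' uses "<= 2.0", "> 2.0-6.0", ...):
#' \itemize{
#'   \item hr (beats/min): `< 100` I, `[100, 120]` II, `(120, 140]` III, `> 140` IV
#'   \item sbp (mmHg): `>= 110` I, `[100, 110)` II, `[90, 100)` III, `< 90` IV
#'   \item bd (mmol/L): `<= 2` I, `(2, 6]` II, `(6, 10]` III, `> 10` IV
#' }
#' GCS is graded separately by [classify_gcs()] because class for a normal
#' GCS of 15 is split between I and II. The table is data — `strict[i]` says
#' whether the class steps at `value > breaks[i]` (TRUE) or
#' `value >= breaks[i]` (FALSE) — so an alternative boundary reading is a
#' one-line change.
#'
#' @return named list, per parameter: `breaks`, `strict` (per-break boundary
#'   convention), `ascending` (does class rise with the value?), and the
#'   admissible physiologic `range`.
#' @export
threshold_table <- function() {
  list(
    hr  = list(breaks = c(100, 120, 140), strict = c(FALSE, TRUE, TRUE),
               ascending = TRUE,  range = c(0, 300)),
    sbp = list(breaks = c(90, 100, 110),  strict = c(FALSE, FALSE, FALSE),
               ascending = FALSE, range = c(0, 300)),
    bd  = list(breaks = c(2, 6, 10),      strict = c(TRUE, TRUE, TRUE),
               ascending = TRUE,  range = c(-30, 50))
  )
}

#' Grade a continuous vital parameter into shock class I-IV
#'
#' @param parameter `"hr"`, `"sbp"` or `"bd"` (GCS has its own rule,
#'   [classify_gcs()]).
#' @param value numeric vector of measurements within the parameter's
#'   physiologic range.
#' @param thresholds a [threshold_table()].
#' @return integer vector of shock classes (1 = I ... 4 = IV).
#' @examples
#' classify_value("hr", c(95, 120, 145))  # 1 3 4
#' @export
classify_value <- function(parameter, value, thresholds = threshold_table()) {
  if (!parameter %in% names(thresholds))
    stop("classify_value: unknown parameter '", parameter, "'", call. = FALSE)
  th <- thresholds[[parameter]]
  if (any(!is.finite(value)) || any(value < th$range[1]) || any(value > th$range[2]))
    stop("classify_value(", parameter, "): value outside physiologic range [",
         th$range[1], ", ", th$range[2], "]", call. = FALSE)
  cnt <- rep(0L, length(value))
  for (i in seq_along(th$breaks))
    cnt <- cnt + if (th$strict[i]) (value > th$breaks[i]) else (value >= th$breaks[i])
  as.integer(if (th$ascending) cnt + 1L else 4L - cnt)
}

#' Grade the Glasgow Coma Scale into shock class I-IV
#'
#' GCS below 12 is class IV, 12-14 class III. A GCS of 15 corresponds to
#' either class I ("normal") or class II ("mildly anxious") in the source
#' grading, distinguished only by qualitative mental status; these patients
#' are redistributed half into class I and half into class II, here decided by
#' the supplied uniform draw (`< 0.5` gives class I).
#'
#' @param value integer GCS vector in `[3, 15]`.
#' @param split_draw uniform draws in (0, 1), recycled along `value`.
#' @return integer vector of shock classes.
#' @export
classify_gcs <- function(value, split_draw) {
  if (any(!is.finite(value)) || any(value != round(value)) ||
      any(value < 3) || any(value > 15))
    stop("classify_gcs: value must be an integer in [3, 15]", call. = FALSE)
  if (any(split_draw <= 0) || any(split_draw >= 1))
    stop("classify_gcs: split_draw must lie in (0, 1)", call. = FALSE)
  out <- ifelse(value < 12, 4L, ifelse(value <= 14, 3L, NA_integer_))
  at15 <- value == 15
  out[at15] <- ifelse(rep_len(split_draw, length(value))[at15] < 0.5, 1L, 2L)
  as.integer(out)
}

#' Maximum-allocation composite shock class
#'
#' The composite class of a patient is the highest (worst) class among the
#' member parameters — the allocation rule whose bias this package audits.
#'
#' @param classes integer matrix (rows = patients) or vector of member
#'   classes in 1..4.
#' @return integer vector of row maxima.
#' @export
composite_class <- function(classes) {
  if (is.null(dim(classes))) classes <- matrix(classes, nrow = 1L)
  if (ncol(classes) == 0L || nrow(classes) == 0L)
    stop("composite_class: no member classes supplied", call. = FALSE)
  stopifnot(all(classes %in% 1:4))
  as.integer(do.call(pmax, as.data.frame(classes)))
}

#' Classify a whole cohort and form the composite
#'
#' Applies [classify_value()] to hr, sbp and bd, [classify_gcs()] to gcs
#' (with split draws from a dedicated seed substream), and forms the
#' maximum-allocation composite over `composite_members`.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()] (or any data.frame
#'   with columns `hr, sbp, gcs, bd`).
#' @param composite_members character subset of `c("hr","sbp","gcs","bd")`.
#' @param seed integer seed; split draws come from substream 2 of it.
#' @param gcs_split `"bernoulli"` (independent fair coins) or `"exact-half"`
#'   (a seeded permutation assigns exactly half of the GCS-15 patients,
#'   rounding down, to class I).
#' @return a data.frame of class `shock_class_table` with columns
#'   `hr_class, sbp_class, gcs_class, bd_class, composite_class` and
#'   attribute `composite_members`.
#' @export
classify_cohort <- function(cohort, composite_members = c("hr", "sbp", "gcs"),
                            seed = 1L, gcs_split = c("bernoulli", "exact-half")) {
  gcs_split <- match.arg(gcs_split)
  stopifnot(all(c("hr", "sbp", "gcs", "bd") %in% names(cohort)))
  stopifnot(length(composite_members) >= 1,
            all(composite_members %in% c("hr", "sbp", "gcs", "bd")))
  n <- nrow(cohort)
  set.seed(derive_seed(seed, 2L), kind = "Mersenne-Twister", normal.kind = "Inversion")
  draws <- if (gcs_split == "bernoulli") {
    runif(n)
  } else {
    at15 <- which(cohort$gcs == 15)
    d <- rep(0.75, n)  # class II unless selected
    d[sample(at15, floor(length(at15) / 2))] <- 0.25
    d
  }
  cl <- data.frame(
    hr_class  = classify_value("hr",  cohort$hr),
    sbp_class = classify_value("sbp", cohort$sbp),
    gcs_class = classify_gcs(cohort$gcs, draws),
    bd_class  = classify_value("bd",  cohort$bd)
  )
  cl$composite_class <- composite_class(as.matrix(cl[paste0(composite_members, "_class")]))
  structure(cl, class = c("shock_class_table", "data.frame"),
            composite_members = composite_members, gcs_split = gcs_split)
}
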