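#' @importFrom stats cor pnorm pt qnorm rnorm runif sd setNames var
#' @importFrom utils read.csv
NULL

# full-precision CSV writer: doubles survive a write/read round trip exactly
# (17 significant digits), so replayed reports are byte-identical
write_csv_exact <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- formatC(x, digits = 17, format = "g")
      out <- sub("^\\s+", "", out)
      out[x == round(x) & abs(x) < 1e15] <- formatC(x[x == round(x) & abs(x) < 1e15],
                                                    format = "d")
      out
    } else as.character(x)
  }
  m <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply(m, 1L, paste, collapse = ","), con)
  invisible(path)
}

summary_to_list <- function(s) {
  list(schema_version = 1L,
       scenario_id = s$scenario_id, n = s$n, seed = s$seed,
       comparisons = s$comparisons,
       singleton_stats = s$singleton_stats,
       composite_stats = s$composite_stats,
       postprocessing_spearman = as.list(s$postprocessing_spearman),
       joint_class_fraction = s$joint_class_fraction,
       joint_class_fraction_all4 = s$joint_class_fraction_all4,
       copula = s$copula, config = s$config, warnings = as.list(s$warnings))
}

#' Render machine-readable reports for a set of scenario summaries
#'
#' Writes `summary.json` (schema-versioned list of all summaries) and
#' `comparisons.csv` (one row per scenario per shock class). Outputs are a
#' deterministic function of the summaries: no timestamps, full numeric
#' precision, LF line endings — regenerating a report from replayed inputs
#' reproduces it byte-for-byte.
#'
#' @param summaries list of `experiment_summary` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_report <- function(summaries, dir) {
  stopifnot(length(summaries) >= 1)
  if (inherits(summaries, "experiment_summary")) summaries <- list(summaries)
  summaries <- Filter(function(s) inherits(s, "experiment_summary"), summaries)
  if (!length(summaries)) stop("render_report: no successful summaries", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(lapply(summaries, summary_to_list),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, null = "null")
  comp <- do.call(rbind, lapply(summaries, function(s) {
    cbind(scenario = s$scenario_id, singleton = s$config$comparison_singleton,
          s$comparisons)
  }))
  write_csv_exact(comp, file.path(dir, "comparisons.csv"))
  invisible(dir)
}

#' Run the full experiment and write all artifacts
#'
#' Orchestrates the four scenarios from a master configuration. A run
#' manifest (tool version, config hash, master and derived seeds, timestamps,
#' PD-repair distances, warnings) is written before any statistic; each
#' scenario directory gets `cohort.csv`, `classes.csv` and a JSON sidecar
#' (seed, composite membership, split mode, truncation, copula matrix before
#' and after any repair); the combined report goes to the root of `out`.
#'
#' @param master a `shockbias_config` (see [default_config()],
#'   [load_and_validate_config()]).
#' @param out output directory.
#' @param config_path optional path of the source config file, hashed into
#'   the manifest.
#' @return invisibly, an integer exit status: 0 on success, 3 if every
#'   scenario produced only degenerate comparisons.
#' @export
run_experiment <- function(master, out, config_path = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  scen <- master$scenarios
  manifest <- list(
    tool = "shockbias",
    version = as.character(utils::packageVersion("shockbias")),
    config_hash = if (!is.null(config_path))
      fnv1a32(readBin(config_path, "raw", file.info(config_path)$size)) else NA,
    master_seed = master$master_seed,
    scenario_seeds = setNames(
      lapply(scen, function(s) derive_seed(master$master_seed, structure_stream(s))), scen),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = c(if (isTRUE(master$placeholder_marginals)) "placeholder-marginals")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  summaries <- list()
  for (s in scen) {
    res <- try({
      cfg <- config_for_scenario(master, s)
      cohort <- simulate_cohort(cfg)
      classes <- classify_cohort(cohort, cfg$composite_members,
                                 seed = cfg$seed, gcs_split = cfg$gcs_split)
      sdir <- file.path(out, s)
      dir.create(sdir, showWarnings = FALSE)
      write_csv_exact(cohort, file.path(sdir, "cohort.csv"))
      cl <- classes
      for (cc in names(cl)) cl[[cc]] <- roman_classes[cl[[cc]]]
      write_csv_exact(cl, file.path(sdir, "classes.csv"))
      cop <- attr(cohort, "copula")
      jsonlite::write_json(list(
        scenario_id = s, n = cfg$n, seed = cfg$seed,
        composite_members = cfg$composite_members,
        comparison_singleton = cfg$comparison_singleton,
        truncation = cfg$truncation, gcs_split = cfg$gcs_split, welch = cfg$welch,
        placeholder_marginals = cfg$placeholder_marginals,
        marginals = lapply(cfg$marginals, unclass),
        spearman_magnitudes = cfg$correlation$magnitudes,
        signs = cfg$correlation$signs,
        fixed = cfg$correlation$fixed,
        copula_matrix = cop$matrix, repaired = cop$repaired,
        repair_distance = cop$repair_distance
      ), file.path(sdir, "sidecar.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, null = "null")
      summarize_scenario(cohort, cfg, cop)
    }, silent = TRUE)
    summaries[[s]] <- res
  }
  ok <- Filter(function(x) inherits(x, "experiment_summary"), summaries)
  if (length(ok)) render_report(ok, out)
  degenerate_only <- length(ok) > 0 &&
    all(vapply(ok, function(s) all(s$comparisons$flag != "ok"), logical(1)))
  invisible(if (degenerate_only) 3L else 0L)
}

#' Replay a saved run from its artifacts
#'
#' Reads each scenario's `cohort.csv` and JSON sidecar, re-classifies with
#' the recorded seed and settings, recomputes every statistic, and renders
#' the report into `out`. Because reports are deterministic functions of the
#' cohort and settings, the replayed `summary.json` and `comparisons.csv`
#' match the originals byte-for-byte.
#'
#' @param dir directory written by [run_experiment()].
#' @param out output directory for the replayed report (default
#'   `file.path(dir, "replay")`).
#' @return `out`, invisibly.
#' @export
replay_run <- function(dir, out = file.path(dir, "replay")) {
  sdirs <- Filter(function(d) file.exists(file.path(dir, d, "sidecar.json")),
                  list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(sdirs)) stop("replay_run: no scenario artifacts under ", dir, call. = FALSE)
  order_ix <- order(match(sdirs, c("equal", "unequal", "swap-equal", "swap-unequal")))
  summaries <- lapply(sdirs[order_ix], function(s) {
    side <- jsonlite::read_json(file.path(dir, s, "sidecar.json"), simplifyVector = TRUE)
    cohort <- read.csv(file.path(dir, s, "cohort.csv"))
    class(cohort) <- c("cohort_table", "data.frame")
    marg <- lapply(side$marginals, function(m)
      marginal_spec(m$name, m$family, m$location %||% NA_real_, m$scale %||% NA_real_,
                    m$lower_bound, m$upper_bound, isTRUE(m$round_to_integer),
                    m$mixture))
    names(marg) <- names(side$marginals)
    attr(marg, "placeholder") <- isTRUE(side$placeholder_marginals)
    corr <- correlation_spec(as.matrix(side$spearman_magnitudes),
                             as.matrix(side$signs), side$scenario_id,
                             fixed = as.matrix(side$fixed))
    cfg <- scenario_config(side$scenario_id, n = side$n, seed = side$seed,
                           marginals = marg, correlation = corr,
                           composite_members = side$composite_members,
                           comparison_singleton = side$comparison_singleton,
                           truncation = side$truncation, gcs_split = side$gcs_split,
                           welch = isTRUE(side$welch))
    summarize_scenario(cohort, cfg, validate_correlation_matrix(corr))
  })
  names(summaries) <- sdirs[order_ix]
  render_report(summaries, out)
  invisible(out)
}
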