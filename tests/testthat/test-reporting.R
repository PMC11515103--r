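test_that("config loading: defaults, named errors, idempotent round trip", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"master_seed": 9}', p)
  expect_warning(cfg <- load_and_validate_config(p), "PLACEHOLDER")
  expect_identical(cfg$master_seed, 9L)
  expect_identical(cfg$n, 16305L)

  bad <- withr::local_tempfile(fileext = ".json")
  mag <- matrix(0.55, 5, 5); diag(mag) <- 1; mag[1, 2] <- mag[2, 1] <- 1.3
  jsonlite::write_json(list(master_seed = 1,
                            correlation = list(equal = list(magnitudes = mag))),
                       bad, auto_unbox = TRUE)
  expect_error(suppressWarnings(load_and_validate_config(bad)),
               "magnitudes\\[[12],[12]\\]")

  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"truncation": "chop"}', bad2)
  expect_error(suppressWarnings(load_and_validate_config(bad2)), "'truncation'")
  expect_error(load_and_validate_config("no/such/file.json"), "not found")

  # round trip: dump(load(cfg)) == dump(load(dump(load(cfg))))
  q1 <- withr::local_tempfile(fileext = ".json")
  q2 <- withr::local_tempfile(fileext = ".json")
  save_config(suppressWarnings(load_and_validate_config(p)), q1)
  save_config(suppressWarnings(load_and_validate_config(q1)), q2)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("run_experiment writes manifest, artifacts, and a valid report", {
  out <- withr::local_tempdir()
  master <- default_config(master_seed = 5, n = 300)
  code <- suppressWarnings(run_experiment(master, out))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$master_seed, 5L)
  expect_true("placeholder-marginals" %in% unlist(man$warnings))
  for (s in c("equal", "unequal", "swap-equal", "swap-unequal"))
    for (f in c("cohort.csv", "classes.csv", "sidecar.json"))
      expect_true(file.exists(file.path(out, s, f)), info = paste(s, f))
  # summary.json parses and echoes the scenarios
  smry <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(length(smry), 4L)
  expect_setequal(vapply(smry, function(s) s$scenario_id, character(1)),
                  c("equal", "unequal", "swap-equal", "swap-unequal"))
  expect_true(all(vapply(smry, function(s) "placeholder-marginals" %in% unlist(s$warnings),
                         logical(1))))
  # comparisons.csv: <= 4 scenarios x 4 classes rows
  comp <- read.csv(file.path(out, "comparisons.csv"))
  expect_lte(nrow(comp), 16L)
  expect_identical(sort(unique(comp$scenario)),
                   sort(c("equal", "unequal", "swap-equal", "swap-unequal")))
  # classes.csv uses roman numerals
  cls <- read.csv(file.path(out, "equal", "classes.csv"))
  expect_true(all(unlist(cls) %in% c("I", "II", "III", "IV")))
})

test_that("replay from saved artifacts reproduces the report byte-for-byte", {
  out <- withr::local_tempdir()
  suppressWarnings(run_experiment(default_config(master_seed = 23, n = 500), out))
  replay_run(out)
  for (f in c("summary.json", "comparisons.csv")) {
    a <- readBin(file.path(out, f), "raw", file.size(file.path(out, f)))
    b <- readBin(file.path(out, "replay", f), "raw",
                 file.size(file.path(out, "replay", f)))
    expect_identical(a, b, info = f)
  }
})

test_that("the CLI runs, replays, and reports config errors with exit code 2", {
  out <- file.path(withr::local_tempdir(), "run")
  code <- suppressMessages(shockbias_cli(
    c("run", "--scenario", "equal", "--seed", "3", "--out", out)))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "summary.json")))
  code2 <- suppressMessages(shockbias_cli(c("replay", out)))
  expect_identical(code2, 0L)
  expect_true(file.exists(file.path(out, "replay", "summary.json")))
  expect_identical(suppressMessages(shockbias_cli(
    c("run", "--scenario", "nonsense"))), 2L)
  expect_identical(suppressMessages(shockbias_cli(
    c("run", "--config", "missing.json"))), 2L)
  expect_output(shockbias_cli("--version"), "shockbias")
})

test_that("seed derivation is stable and stream-separated", {
  expect_identical(derive_seed(1, 1), derive_seed(1, 1))
  expect_false(derive_seed(1, 1) == derive_seed(1, 2))
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
  s <- vapply(0:50, function(k) derive_seed(123, k), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_identical(length(unique(s)), 51L)
})
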