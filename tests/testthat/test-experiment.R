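make_classified <- function(n = 500, seed = 21, scenario = "equal") {
  cfg <- small_config(n = n, seed = seed, scenario = scenario)
  cohort <- simulate_cohort(cfg)
  list(cfg = cfg, cohort = cohort,
       classes = classify_cohort(cohort, cfg$composite_members, seed = cfg$seed))
}

test_that("joint_class_fraction counts exact agreement", {
  cl <- structure(data.frame(hr_class = c(2L, 1L, 3L, 4L),
                             sbp_class = c(2L, 2L, 3L, 1L),
                             gcs_class = c(2L, 3L, 3L, 2L),
                             bd_class = c(1L, 1L, 3L, 1L)),
                  class = c("shock_class_table", "data.frame"))
  expect_equal(joint_class_fraction(cl, c("hr", "sbp", "gcs")), 0.5)
  expect_equal(joint_class_fraction(cl, "hr"), 1.0)   # singleton agrees with itself
  expect_equal(joint_class_fraction(cl, c("hr", "sbp", "gcs", "bd")), 0.25)
  expect_error(joint_class_fraction(cl[0, ], c("hr", "sbp")), "empty")
})

test_that("group_transfusion_stats: hand case, partition, degenerate flags", {
  co <- toy_cohort(hr = c(110, 110, 110), sbp = 120, gcs = 13, bd = 1,
                   transfusion = c(0, 2, 4))
  cl <- classify_cohort(co, c("hr", "sbp", "gcs"), seed = 1)
  st <- group_transfusion_stats(co, cl, "hr")
  expect_equal(st$n, c(0L, 3L, 0L, 0L))
  expect_equal(st$mean[2], 2); expect_equal(st$sd[2], 2)
  expect_true(st$degenerate[1] && !st$degenerate[2])

  x <- make_classified(400)
  for (scheme in c("composite", "bd", "hr")) {
    st <- group_transfusion_stats(x$cohort, x$classes, scheme)
    expect_identical(sum(st$n), 400L)   # partition conservation
  }
  expect_error(group_transfusion_stats(x$cohort[1:10, ], x$classes, "bd"),
               "misaligned")
})

test_that("pooled t-test: null identity, hand oracle, degenerate flags", {
  tt <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  # 8-number hand oracle, cross-checked against stats::t.test
  x <- c(0, 0, 0, 1); y <- c(2, 2, 2, 3)
  got <- pooled_t_test(x, y)
  want <- naive_pooled_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # Welch flavor agrees with stats::t.test default
  gw <- pooled_t_test(x, y, welch = TRUE)
  rw <- t.test(x, y)
  expect_equal(gw$t, unname(rw$statistic), tolerance = 1e-12)
  expect_equal(gw$p, rw$p.value, tolerance = 1e-12)
  # degenerate inputs flagged, not fabricated
  expect_identical(pooled_t_test(1, c(1, 2))$flag, "degenerate-n")
  zv <- pooled_t_test(c(0, 0, 0, 0), c(2, 2, 2, 2))
  expect_identical(zv$flag, "zero-variance")
  expect_identical(zv$t, -Inf)
  expect_true(is.na(zv$p))
})

test_that("compare_schemes enforces membership and aligns rows", {
  x <- make_classified(300)
  expect_error(compare_schemes(x$cohort, x$classes, "hr"), "composite member")
  cmp <- compare_schemes(x$cohort, x$classes, "bd")
  expect_identical(nrow(cmp), 4L)
  expect_identical(attr(cmp, "caveat"), "overlapping-groups")
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
})

test_that("postprocessing_spearman: perfect monotone and constant columns", {
  co <- toy_cohort(hr = c(60, 80, 100, 120), sbp = c(120, 110, 100, 90),
                   gcs = c(15, 14, 13, 12), bd = c(1, 2, 3, 4),
                   transfusion = c(60, 80, 100, 120))
  rho <- postprocessing_spearman(co)
  expect_equal(unname(rho["hr"]), 1)
  expect_equal(unname(rho["sbp"]), -1)
  co$bd <- 1
  expect_warning(rho2 <- postprocessing_spearman(co), "constant")
  expect_true(is.na(rho2["bd"]))
  expect_error(postprocessing_spearman(co[1:2, ]), "n >= 3")
})

test_that("summary statistics agree with naive-loop oracles to 1e-10", {
  x <- make_classified(n = 1000, seed = 8)
  co <- x$cohort; cl <- x$classes
  # spearman
  rho <- postprocessing_spearman(co)
  for (v in c("hr", "sbp", "gcs", "bd"))
    expect_equal(unname(rho[v]), naive_spearman(co[[v]], co$transfusion),
                 tolerance = 1e-10)
  # joint fraction
  expect_equal(joint_class_fraction(cl, c("hr", "sbp", "gcs")),
               naive_joint_fraction(as.matrix(cl[c("hr_class", "sbp_class", "gcs_class")])),
               tolerance = 1e-10)
  # per-class stats under both schemes
  for (scheme in c("bd", "composite")) {
    g <- if (scheme == "bd") cl$bd_class else cl$composite_class
    st <- group_transfusion_stats(co, cl, scheme)
    ref <- naive_group_stats(co$transfusion, g)
    for (k in 1:4) {
      expect_equal(st$n[k], unname(ref[[k]]["n"]))
      if (st$n[k] >= 1) expect_equal(st$mean[k], unname(ref[[k]]["mean"]), tolerance = 1e-10)
      if (st$n[k] >= 2) expect_equal(st$sd[k], unname(ref[[k]]["sd"]), tolerance = 1e-10)
    }
  }
  # t statistics per class
  cmp <- compare_schemes(co, cl, "bd")
  for (k in 1:4) {
    xk <- co$transfusion[cl$bd_class == k]
    yk <- co$transfusion[cl$composite_class == k]
    if (length(xk) >= 2 && length(yk) >= 2 && cmp$flag[k] == "ok") {
      want <- naive_pooled_t(xk, yk)
      expect_equal(cmp$t_statistic[k], want$t, tolerance = 1e-10)
      expect_equal(cmp$p_value[k], want$p, tolerance = 1e-10)
    }
  }
})

test_that("run_scenario: determinism, small-n robustness, structure", {
  s1 <- run_scenario(small_config(n = 50, seed = 6))
  s2 <- run_scenario(small_config(n = 50, seed = 6))
  expect_identical(s1$comparisons, s2$comparisons)
  expect_identical(s1$postprocessing_spearman, s2$postprocessing_spearman)
  expect_s3_class(s1, "experiment_summary")
  expect_true(s1$joint_class_fraction >= 0 && s1$joint_class_fraction <= 1)
  expect_identical(length(s1$postprocessing_spearman), 4L)
  # degenerate classes at n = 50 are allowed but must be flagged
  expect_true(all(s1$comparisons$flag[is.na(s1$comparisons$p_value)] != "ok"))
  expect_true("placeholder-marginals" %in% s1$warnings)
})

test_that("mean transfusion rises with class under every single-parameter scheme", {
  x <- make_classified(n = 16305, seed = 12)
  for (scheme in c("hr", "sbp", "gcs", "bd")) {
    st <- group_transfusion_stats(x$cohort, x$classes, scheme)
    m <- st$mean[st$n > 0]
    expect_true(all(diff(m) >= 0), info = scheme)
  }
})

test_that("run_all_scenarios: seed sharing between swap twins, bias persists", {
  out <- run_all_scenarios(default_config(master_seed = 3, n = 4000))
  expect_named(out, c("equal", "unequal", "swap-equal", "swap-unequal"))
  # equal and swap-equal share the cohort draw: identical spearman vectors
  expect_identical(out$equal$postprocessing_spearman,
                   out$`swap-equal`$postprocessing_spearman)
  expect_identical(out$unequal$postprocessing_spearman,
                   out$`swap-unequal`$postprocessing_spearman)
  # swap scenarios favor hr over the {bd, sbp, gcs} composite
  cmp <- out$`swap-equal`$comparisons
  expect_true(all(cmp$mean_singleton[2:4] > cmp$mean_composite[2:4]))
})

test_that("the bias is a property of the allocation rule, not of base deficit", {
  # with all correlations equal, the singleton beats the composite in classes
  # II-IV whichever predictor takes the singleton role
  signs <- c()
  for (single in c("hr", "bd")) {
    members <- setdiff(c("hr", "sbp", "gcs", "bd"), single)
    cfg <- scenario_config("equal", n = 8000, seed = 14,
                           composite_members = members,
                           comparison_singleton = single)
    s <- run_scenario(cfg)
    d <- s$comparisons$mean_singleton[2:4] - s$comparisons$mean_composite[2:4]
    signs <- c(signs, sign(d))
  }
  expect_true(all(signs == 1))
})
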