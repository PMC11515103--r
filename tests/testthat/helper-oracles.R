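# Naive reference implementations: plain loops over rows, independent of the
# package's vectorized paths. Used as oracles at small n.

naive_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- less + (ties + 1) / 2
  }
  r
}

naive_spearman <- function(x, y) {
  rx <- naive_rank(x); ry <- naive_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

naive_group_stats <- function(transfusion, g) {
  out <- list()
  for (k in 1:4) {
    xs <- c()
    for (i in seq_along(g)) if (g[i] == k) xs <- c(xs, transfusion[i])
    m <- if (length(xs) >= 1) sum(xs) / length(xs) else NA_real_
    s <- if (length(xs) >= 2) {
      ss <- 0
      for (v in xs) ss <- ss + (v - m)^2
      sqrt(ss / (length(xs) - 1))
    } else NA_real_
    out[[k]] <- c(n = length(xs), mean = m, sd = s)
  }
  out
}

naive_joint_fraction <- function(class_matrix) {
  hits <- 0
  for (i in seq_len(nrow(class_matrix))) {
    row <- class_matrix[i, ]
    same <- TRUE
    for (v in row) if (v != row[1]) same <- FALSE
    if (same) hits <- hits + 1
  }
  hits / nrow(class_matrix)
}

naive_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# tiny hand-built cohort with known values
toy_cohort <- function(hr, sbp, gcs, bd, transfusion) {
  structure(data.frame(hr = hr, sbp = sbp, gcs = gcs, bd = bd,
                       transfusion = transfusion),
            class = c("cohort_table", "data.frame"))
}

small_config <- function(n = 400, seed = 5, scenario = "equal", ...) {
  scenario_config(scenario, n = n, seed = seed, ...)
}
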