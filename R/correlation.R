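#' Convert a Spearman target to the Gaussian-copula correlation parameter
#'
#' For a bivariate Gaussian copula with parameter r, the population Spearman
#' rank correlation of the (continuous) margins is (6 / pi) * asin(r / 2).
#' Inverting gives r = 2 * sin(pi * rho_s / 6), so targets expressed on the
#' rank scale are matched exactly before truncation or rounding.
#'
#' @param rho_s Spearman correlation(s) in `[-1, 1]`.
#' @return copula correlation parameter(s) in `[-1, 1]`.
#' @examples
#' spearman_to_copula_param(0.55)  # ~0.568
#' @export
spearman_to_copula_param <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) > 1))
    stop("spearman_to_copula_param: |rho_s| must be <= 1", call. = FALSE)
  2 * sin(pi * rho_s / 6)
}

var_order <- c("hr", "sbp", "gcs", "bd", "transfusion")

#' Target Spearman dependence structure for a scenario
#'
#' Couples a symmetric matrix of Spearman magnitudes with a sign matrix.
#' Signs must be "sign-consistent": expressible as the outer product of a
#' per-variable sign vector, so flipping variables makes the matrix all
#' positive and the physiological direction conventions (SBP and GCS inversely
#' related to the rest) can never break positive-definiteness by themselves.
#'
#' @param magnitudes symmetric 5x5 matrix of Spearman magnitudes in `[0, 1]`
#'   with unit diagonal, variables ordered `hr, sbp, gcs, bd, transfusion`.
#' @param signs symmetric 5x5 matrix with entries in `{-1, +1}`.
#' @param scenario_id one of `"equal"`, `"unequal"`, `"swap-equal"`,
#'   `"swap-unequal"`.
#' @param fixed optional logical 5x5 mask marking entries that an eventual
#'   positive-definiteness repair must leave untouched (see
#'   [validate_correlation_matrix()]).
#' @return an object of class `correlation_spec`.
#' @export
correlation_spec <- function(magnitudes, signs = default_signs(),
                             scenario_id = c("equal", "unequal", "swap-equal", "swap-unequal"),
                             fixed = NULL) {
  scenario_id <- match.arg(scenario_id)
  magnitudes <- as.matrix(magnitudes); signs <- as.matrix(signs)
  stopifnot(identical(dim(magnitudes), c(5L, 5L)), identical(dim(signs), c(5L, 5L)))
  if (any(abs(magnitudes - t(magnitudes)) > 1e-12) || any(diag(magnitudes) != 1))
    stop("correlation_spec: magnitudes must be symmetric with unit diagonal", call. = FALSE)
  if (any(magnitudes < 0) || any(magnitudes > 1))
    stop("correlation_spec: magnitudes must lie in [0, 1]", call. = FALSE)
  if (!all(signs %in% c(-1, 1)) || any(signs != t(signs)))
    stop("correlation_spec: signs must be symmetric in {-1, +1}", call. = FALSE)
  s <- signs[, 1L]
  if (any(outer(s, s) != signs))
    stop("correlation_spec: signs are not sign-consistent (not an outer product s %o% s)",
         call. = FALSE)
  if (is.null(fixed)) fixed <- matrix(FALSE, 5, 5)
  dimnames(magnitudes) <- dimnames(signs) <- dimnames(fixed) <- list(var_order, var_order)
  structure(list(labels = var_order, magnitudes = magnitudes, signs = signs,
                 scenario_id = scenario_id, fixed = fixed),
            class = "correlation_spec")
}

#' Default physiological sign conventions
#'
#' SBP and GCS fall as shock worsens while HR, BD and transfusion rise, so any
#' pair involving exactly one of `{sbp, gcs}` is negatively correlated.
#'
#' @return 5x5 sign matrix (outer product of `c(1, -1, -1, 1, 1)`).
#' @export
default_signs <- function() {
  s <- c(hr = 1, sbp = -1, gcs = -1, bd = 1, transfusion = 1)
  outer(s, s)
}

#' Built-in scenario dependence targets
#'
#' The `equal` structure sets every off-diagonal Spearman magnitude to 0.55.
#' The `unequal` structure lowers the bd-transfusion magnitude to 0.3 and
#' raises hr/sbp/gcs-transfusion to 0.8, leaving the (unstated)
#' predictor-predictor magnitudes at 0.55; the transfusion column is marked
#' `fixed` so the PD repair moves only unstated entries. The swap scenarios
#' reuse the corresponding structure unchanged (only the composite membership
#' differs downstream).
#'
#' @param scenario_id scenario name.
#' @return a [correlation_spec()].
#' @export
scenario_correlation <- function(scenario_id = c("equal", "unequal", "swap-equal", "swap-unequal")) {
  scenario_id <- match.arg(scenario_id)
  mag <- matrix(0.55, 5, 5); diag(mag) <- 1
  fixed <- matrix(FALSE, 5, 5)
  if (scenario_id %in% c("unequal", "swap-unequal")) {
    mag[1:3, 5] <- mag[5, 1:3] <- 0.8
    mag[4, 5] <- mag[5, 4] <- 0.3
    fixed[, 5] <- fixed[5, ] <- TRUE; diag(fixed) <- FALSE
  }
  correlation_spec(mag, default_signs(), scenario_id, fixed = fixed)
}

# Nearest PD correlation matrix subject to fixed entries, by Dykstra's
# alternating projections between the cone {eigenvalues >= delta} and the
# affine set {unit diagonal, fixed entries at their targets}. Both sets are
# convex and (for feasible anchors) intersect, so the iteration converges.
nearest_pd_fixed <- function(M, fixed, delta = 1e-8, maxit = 5000, tol = 1e-12) {
  target <- M; X <- M; P <- matrix(0, nrow(M), ncol(M))
  for (it in seq_len(maxit)) {
    Y <- X + P
    e <- eigen(Y, symmetric = TRUE)
    Xp <- e$vectors %*% (pmax(e$values, delta) * t(e$vectors))
    P <- Y - Xp
    Xn <- Xp
    Xn[fixed] <- target[fixed]
    diag(Xn) <- 1
    Xn <- (Xn + t(Xn)) / 2
    if (max(abs(Xn - X)) < tol) return(Xn)
    X <- Xn
  }
  X
}

#' Validate (and if necessary repair) the copula correlation matrix
#'
#' Applies [spearman_to_copula_param()] elementwise to the signed Spearman
#' targets, checks symmetry, unit diagonal, and positive-definiteness
#' (smallest eigenvalue > 1e-10). A non-PD matrix is projected to the nearest
#' PD correlation matrix: entries flagged `fixed` in the spec are held at
#' their targets (anchored Dykstra projection); with no fixed entries the
#' unconstrained projection of [Matrix::nearPD()] is used. The Frobenius
#' distance of the repair is recorded.
#'
#' @param spec a [correlation_spec()], or a plain symmetric matrix of signed
#'   Spearman targets with unit diagonal (any dimension; repairs are then
#'   unconstrained).
#' @return list with components `matrix` (the validated copula correlation
#'   matrix), `repaired` (logical), `repair_distance` (Frobenius norm of the
#'   adjustment), and `min_eigenvalue`.
#' @export
validate_correlation_matrix <- function(spec) {
  if (is.matrix(spec) && is.numeric(spec)) {
    if (nrow(spec) != ncol(spec) || any(abs(spec - t(spec)) > 1e-12) ||
        any(diag(spec) != 1))
      stop("validate_correlation_matrix: matrix must be symmetric with unit diagonal",
           call. = FALSE)
    spec <- list(magnitudes = abs(spec), signs = sign(spec) + (spec == 0),
                 fixed = matrix(FALSE, nrow(spec), ncol(spec)))
  } else stopifnot(inherits(spec, "correlation_spec"))
  R0 <- spec$signs * spearman_to_copula_param(spec$magnitudes)
  diag(R0) <- 1
  if (any(abs(R0 - t(R0)) > 1e-12) || any(diag(R0) != 1))
    stop("validate_correlation_matrix: matrix must be symmetric with unit diagonal",
         call. = FALSE)
  ev <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-10)
    return(list(matrix = R0, repaired = FALSE, repair_distance = 0,
                min_eigenvalue = min(ev)))
  R <- if (any(spec$fixed)) {
    nearest_pd_fixed(R0, spec$fixed)
  } else {
    as.matrix(Matrix::nearPD(R0, corr = TRUE, posd.tol = 1e-6)$mat)
  }
  dimnames(R) <- dimnames(R0)
  list(matrix = R, repaired = TRUE,
       repair_distance = norm(R - R0, "F"),
       min_eigenvalue = min(eigen(R, symmetric = TRUE, only.values = TRUE)$values))
}
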