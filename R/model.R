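#' Fit the estimable APC model by weighted least squares
#'
#' Minimizes `sum(w_i (y_i - x_i' b)^2)` over the design from
#' [build_design_matrix()] via QR on the weight-scaled matrix. The two
#' linear coefficients are the estimable combinations of the
#' non-identified linear age, period, and cohort effects:
#' `theta1 = alpha_L + pi_L` (age linear column) and
#' `theta2 = gamma_L + pi_L` (cohort linear column). All nonlinear
#' deviations and covariate effects are identified and reported with their
#' bases.
#'
#' @param design An `apc_design`.
#' @return An object of class `apc_fit` with `beta0`, `theta1`, `theta2`,
#'   `age_nl`, `period_nl`, `cohort_nl` (named coefficient vectors),
#'   `covariate_coefs`, `residual_sd` (weighted RMS residual), `n_obs`,
#'   `condition_number` (of the weight-scaled design), the full
#'   `coefficients` vector, and the `bases`/`scheme` carried from the
#'   design.
#' @export
fit_apc_model <- function(design) {
  stopifnot(inherits(design, "apc_design"))
  X <- design$X
  y <- design$y
  w <- design$w
  if (nrow(X) <= ncol(X)) {
    stop("need more observations (", nrow(X), ") than columns (", ncol(X), ")")
  }
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  if (fit$rank < ncol(X)) stop("rank-deficient fit; check the design")
  beta <- fit$coefficients
  if (any(!is.finite(beta))) stop("non-finite coefficients")

  sv <- svd(X * sqrt(w), nu = 0, nv = 0)$d
  resid <- y - drop(X %*% beta)
  pick <- function(prefix) beta[grep(paste0("^", prefix), names(beta))]
  structure(list(
    beta0 = unname(beta["(Intercept)"]),
    theta1 = unname(beta["age_L"]),
    theta2 = unname(beta["cohort_L"]),
    age_nl = pick("age_nl"),
    period_nl = pick("period_nl"),
    cohort_nl = pick("cohort_nl"),
    covariate_coefs = beta[grep("^(dow_|holiday_)", names(beta))],
    coefficients = beta,
    residual_sd = sqrt(sum(w * resid^2) / sum(w)),
    n_obs = nrow(X),
    condition_number = sv[1] / sv[length(sv)],
    bases = design$bases,
    scheme = design$scheme,
    linear_scale = design$linear_scale
  ), class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, digits = 4, ...) {
  cat("<apc_fit> weighted least squares, n =", x$n_obs, "\n")
  cat(sprintf("  beta0  (weighted grand mean): %.*f\n", digits, x$beta0))
  cat(sprintf("  theta1 (alpha_L + pi_L):      %.*f\n", digits, x$theta1))
  cat(sprintf("  theta2 (gamma_L + pi_L):      %.*f\n", digits, x$theta2))
  cat(sprintf("  residual sd %.*f, condition number %.3g\n", digits,
              x$residual_sd, x$condition_number))
  invisible(x)
}

#' Weighted descriptive means along one time dimension
#'
#' For each distinct value of the chosen dimension, the survey-weighted
#' mean outcome `sum(w y) / sum(w)`, with the weight total and record
#' count. This is the descriptive (pre-model) view of the age, period, and
#' cohort profiles.
#'
#' @param table An `apc_microdata` table.
#' @param dimension `"age"`, `"year"`, or `"cohort_year"`.
#' @return A data.frame with columns `value`, `mean`, `weight_sum`, `n`,
#'   sorted by `value`.
#' @export
weighted_group_means <- function(table,
                                 dimension = c("age", "year", "cohort_year")) {
  dimension <- match.arg(dimension)
  if (nrow(table) == 0) stop("empty table")
  v <- table[[dimension]]
  keys <- sort(unique(v))
  idx <- match(v, keys)
  wy <- rowsum(table$weight * table$minutes_alone, idx)
  ws <- rowsum(table$weight, idx)
  n <- tabulate(idx, nbins = length(keys))
  data.frame(value = keys, mean = drop(wy / ws), weight_sum = drop(ws),
             n = n, row.names = NULL)
}

# Normal-equations WLS solver. Kept deliberately independent of
# fit_apc_model (QR path) so tests can cross-check the two routes.
#' Solve weighted least squares by the normal equations
#'
#' `b = (X' W X)^{-1} X' W y`. A deliberately independent route from
#' [fit_apc_model()]'s QR factorization, retained for cross-checking.
#'
#' @param X Model matrix. @param y Outcome. @param w Positive weights.
#' @return Named coefficient vector.
#' @export
wls_normal_equations <- function(X, y, w) {
  XtW <- t(X * w)
  drop(solve(XtW %*% X, XtW %*% y))
}
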