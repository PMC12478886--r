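#' A point on the canonical solution line
#'
#' The linear age, period, and cohort effects are not separately
#' identified: only `theta1 = alpha_L + pi_L` and `theta2 = gamma_L + pi_L`
#' are estimable, so the triples consistent with the data form a line
#' parameterized by the linear period effect. `line_point` returns the
#' triple at a chosen `pi_L`:
#' `(alpha_L, pi_L, gamma_L) = (theta1 - pi_L, pi_L, theta2 - pi_L)`.
#'
#' @param theta1,theta2 Estimable linear combinations (outcome units per
#'   group step).
#' @param pi_L Linear period effect at which to evaluate the line.
#' @return A named numeric triple of class `apc_triple`:
#'   `alpha_L`, `pi_L`, `gamma_L`.
#' @export
line_point <- function(theta1, theta2, pi_L) {
  stopifnot(is.finite(theta1), is.finite(theta2), is.finite(pi_L))
  structure(c(alpha_L = theta1 - pi_L, pi_L = pi_L,
              gamma_L = theta2 - pi_L), class = "apc_triple")
}

#' Constraint specification for bounding the linear age effect
#'
#' Encodes the substantive restriction that the net total age effect (the
#' linear age effect plus the estimated nonlinear age deviations) attains
#' its minimum at the age group containing `target_min_age` — the
#' well-documented life-course fact that people are least likely to spend
#' time alone in their mid-30s.
#'
#' @param target_min_age Age in years whose group must hold the minimum
#'   (default 35, i.e. group 35-39 under the default scheme).
#' @param grid_lo,grid_hi,grid_step Candidate linear-age-effect grid
#'   (outcome units per group step); defaults -20..20 by 0.01 bracket any
#'   plausible minutes-per-group slope.
#' @param tie_policy `"target_attains_min"` (default: the target group's
#'   value equals the curve minimum, ties allowed, judged at a 1e-9
#'   relative tolerance) or `"unique_argmin"` (the target group must be the
#'   strict minimizer).
#' @return An object of class `apc_constraint`.
#' @export
constraint_spec <- function(target_min_age = 35L, grid_lo = -20,
                            grid_hi = 20, grid_step = 0.01,
                            tie_policy = c("target_attains_min",
                                           "unique_argmin")) {
  stopifnot(grid_lo < grid_hi, grid_step > 0)
  structure(list(target_min_age = as.integer(target_min_age),
                 grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_step = grid_step,
                 tie_policy = match.arg(tie_policy)),
            class = "apc_constraint")
}

#' Grid-search bounds on the linear age effect
#'
#' Scans candidate linear age effects `alpha` over the configured grid.
#' For each candidate the intercept-free net total age curve
#' `alpha * linear_g + sum_k ahat_k c_kg` is evaluated over the age groups
#' and the candidate is accepted when the group containing
#' `target_min_age` holds the curve's minimum under the tie policy. The
#' returned bounds are the smallest and largest accepted candidates.
#'
#' @param fit An `apc_fit` whose age basis covers the target group.
#' @param constraint An `apc_constraint`, default [constraint_spec()].
#' @return Numeric `c(lo, hi)` with attributes `n_accepted` and
#'   `target_group` (0-based index). Raises an infeasible-constraint error
#'   (with the argmin group at `grid_lo`, 0, and `grid_hi` for diagnosis)
#'   when no candidate is accepted.
#' @export
grid_search_age_bounds <- function(fit, constraint = constraint_spec()) {
  stopifnot(inherits(fit, "apc_fit"), inherits(constraint, "apc_constraint"))
  scheme <- fit$scheme
  tg <- (constraint$target_min_age - scheme$age_start) %/% scheme$age_width
  if (tg < 0 || tg >= scheme$n_age) {
    stop("target_min_age ", constraint$target_min_age,
         " falls outside the age grouping scheme")
  }
  basis <- fit$bases$age
  nl_curve <- rep(0, basis$n_groups)
  for (k in names(basis$nonlinear)) {
    co <- fit$age_nl[[paste0("age_", k)]]
    if (!is.null(co)) nl_curve <- nl_curve + co * basis$nonlinear[[k]]
  }
  alphas <- seq(constraint$grid_lo, constraint$grid_hi,
                by = constraint$grid_step)
  # curves: one column per candidate alpha
  curves <- outer(basis$linear, alphas) + nl_curve
  mins <- apply(curves, 2, min)
  tol <- 1e-9 * pmax(1, abs(mins))
  at_target <- curves[tg + 1L, ]
  if (constraint$tie_policy == "target_attains_min") {
    ok <- at_target <= mins + tol
  } else {
    other_min <- apply(curves[-(tg + 1L), , drop = FALSE], 2, min)
    ok <- at_target < other_min - tol
  }
  if (!any(ok)) {
    diag_at <- function(a) which.min(a * basis$linear + nl_curve) - 1L
    stop("infeasible constraint: no candidate linear age effect in [",
         constraint$grid_lo, ", ", constraint$grid_hi,
         "] puts the net age minimum in group ", tg,
         " (argmin group is ", diag_at(constraint$grid_lo), " at grid_lo, ",
         diag_at(0), " at 0, ", diag_at(constraint$grid_hi), " at grid_hi)")
  }
  structure(c(min(alphas[ok]), max(alphas[ok])),
            n_accepted = sum(ok), target_group = tg)
}

#' Propagate linear-age bounds along the canonical line
#'
#' Because the canonical solution line has slope minus one in
#' (alpha, pi) and plus one in (gamma, pi) coordinates, bounds on the
#' linear age effect translate directly into bounds on the linear period
#' and cohort effects:
#' `pi in [theta1 - alpha_hi, theta1 - alpha_lo]` and
#' `gamma in [theta2 - theta1 + alpha_lo, theta2 - theta1 + alpha_hi]`.
#' The midpoint triple sits at the center of the period range.
#'
#' @param theta1,theta2 Estimable combinations.
#' @param alpha_range Numeric `c(lo, hi)` from
#'   [grid_search_age_bounds()].
#' @return An object of class `apc_region`: `alpha_range`, `pi_range`,
#'   `gamma_range`, `midpoint` (an `apc_triple`), and the thetas.
#' @export
bounds_to_ranges <- function(theta1, theta2, alpha_range) {
  stopifnot(length(alpha_range) == 2, alpha_range[1] <= alpha_range[2])
  alpha_range <- as.numeric(alpha_range)
  pi_range <- c(theta1 - alpha_range[2], theta1 - alpha_range[1])
  gamma_range <- c(theta2 - theta1 + alpha_range[1],
                   theta2 - theta1 + alpha_range[2])
  structure(list(alpha_range = alpha_range, pi_range = pi_range,
                 gamma_range = gamma_range,
                 midpoint = line_point(theta1, theta2, mean(pi_range)),
                 theta1 = theta1, theta2 = theta2),
            class = "apc_region")
}

#' @export
print.apc_region <- function(x, digits = 3, ...) {
  f <- function(r) sprintf("[%.*f, %.*f]", digits, r[1], digits, r[2])
  cat("<apc_region> bounded segment of the canonical solution line\n")
  cat("  linear age    ", f(x$alpha_range), "\n")
  cat("  linear period ", f(x$pi_range), "\n")
  cat("  linear cohort ", f(x$gamma_range), "\n")
  cat(sprintf("  midpoint (%.*f, %.*f, %.*f)\n", digits,
              x$midpoint["alpha_L"], digits, x$midpoint["pi_L"], digits,
              x$midpoint["gamma_L"]))
  invisible(x)
}

#' Sample the canonical solution line
#'
#' Returns the (alpha, pi, gamma) triples along the line over a period
#' range, for 2-D APC plotting. Each row satisfies
#' `alpha + pi = theta1` and `gamma + pi = theta2` exactly.
#'
#' @param theta1,theta2 Estimable combinations.
#' @param pi_range Period-effect interval to sample, default centered on
#'   the unconstrained span `c(theta2 - 1, theta1 + 1)` reordered.
#' @param n Number of points, default 201.
#' @return A data.frame with columns `pi_L`, `alpha_L`, `gamma_L`.
#' @export
canonical_line <- function(theta1, theta2, pi_range = NULL, n = 201) {
  if (is.null(pi_range)) {
    span <- range(0, theta1, theta2)
    pad <- 0.25 * max(1, diff(span))
    pi_range <- c(span[1] - pad, span[2] + pad)
  }
  pis <- seq(pi_range[1], pi_range[2], length.out = n)
  data.frame(pi_L = pis, alpha_L = theta1 - pis, gamma_L = theta2 - pis)
}
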