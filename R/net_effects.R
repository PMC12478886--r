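factor_of <- function(dimension) {
  match.arg(dimension, c("age", "period", "cohort"))
}

nl_deviation <- function(fit, dimension) {
  basis <- fit$bases[[dimension]]
  coefs <- fit[[paste0(dimension, "_nl")]]
  out <- rep(0, basis$n_groups)
  for (k in names(basis$nonlinear)) {
    co <- coefs[[paste0(dimension, "_", k)]]
    if (!is.null(co)) out <- out + co * basis$nonlinear[[k]]
  }
  out
}

group_labels_of <- function(scheme, dimension) {
  switch(dimension, age = scheme$age_labels, period = scheme$period_labels,
         cohort = scheme$cohort_labels)
}

#' Net total effect curve for one dimension
#'
#' Combines a chosen linear effect with the estimated nonlinear deviations
#' for one dimension:
#' `value_g = beta0 + linear_value * linear_g + sum_k coef_k * contrast_kg`
#' (the intercept term optional). With the intercept included and
#' covariates at their weighted-effect zero, values read as mean outcome
#' minutes for an average diary day.
#'
#' @param fit An `apc_fit`.
#' @param dimension `"age"`, `"period"`, or `"cohort"`.
#' @param linear_value Linear effect to use (outcome units per group
#'   step) — any point on the canonical line for this dimension.
#' @param include_intercept Add `beta0`? Default `TRUE`.
#' @return Numeric vector over the dimension's groups, named by group
#'   label.
#' @export
net_total_curve <- function(fit, dimension, linear_value,
                            include_intercept = TRUE) {
  dimension <- factor_of(dimension)
  stopifnot(is.finite(linear_value))
  basis <- fit$bases[[dimension]]
  v <- linear_value * basis$linear + nl_deviation(fit, dimension)
  if (include_intercept) v <- v + fit$beta0
  names(v) <- group_labels_of(fit$scheme, dimension)
  v
}

#' Net total effect bands over the bounded region
#'
#' For each dimension, evaluates the net total curve at the region's
#' midpoint triple (the `mid` band) and at the two endpoints of that
#' dimension's linear-effect range. Curves are affine in the linear value,
#' so the per-group envelope over the whole region is attained at the
#' range endpoints; `min`/`max` are the pointwise envelope. Band width at
#' a group equals the range width times the absolute centered linear
#' contrast there, so bands pinch to zero where the contrast crosses zero.
#'
#' @param fit An `apc_fit`.
#' @param region An `apc_region` derived from the same fit.
#' @return A named list of three `apc_net_curve` data.frames (`age`,
#'   `period`, `cohort`) with columns `group`, `label`, `mid`, `min`,
#'   `max`.
#' @export
net_effect_bands <- function(fit, region) {
  stopifnot(inherits(fit, "apc_fit"), inherits(region, "apc_region"))
  one <- function(dimension, rng, mid_value) {
    lo <- net_total_curve(fit, dimension, rng[1])
    hi <- net_total_curve(fit, dimension, rng[2])
    mid <- net_total_curve(fit, dimension, mid_value)
    out <- data.frame(group = seq_along(mid) - 1L, label = names(mid),
                      mid = unname(mid), min = unname(pmin(lo, hi)),
                      max = unname(pmax(lo, hi)))
    structure(out, dimension = dimension,
              linear_range = rng, linear_mid = mid_value,
              class = c("apc_net_curve", "data.frame"))
  }
  list(
    age = one("age", region$alpha_range, region$midpoint[["alpha_L"]]),
    period = one("period", region$pi_range, region$midpoint[["pi_L"]]),
    cohort = one("cohort", region$gamma_range, region$midpoint[["gamma_L"]])
  )
}

#' Summarize a net effect curve
#'
#' Location and size of the extremes of the `mid` band: argmin/argmax
#' group labels (ties resolved to the lowest group index), minimum and
#' maximum values, first/last-group values, and the min-to-max gap.
#'
#' @param curve An `apc_net_curve`.
#' @return A list with `dimension`, `argmin_label`, `argmax_label`,
#'   `min`, `max`, `gap`, `first`, `last`.
#' @export
summarize_curve <- function(curve) {
  stopifnot(inherits(curve, "apc_net_curve"), nrow(curve) > 0)
  i_min <- which.min(curve$mid)   # which.min takes the first of any ties
  i_max <- which.max(curve$mid)
  list(dimension = attr(curve, "dimension"),
       argmin_label = curve$label[i_min],
       argmax_label = curve$label[i_max],
       min = curve$mid[i_min], max = curve$mid[i_max],
       gap = curve$mid[i_max] - curve$mid[i_min],
       first = curve$mid[1], last = curve$mid[nrow(curve)])
}
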