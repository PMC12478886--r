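#' Age/period/cohort grouping scheme
#'
#' Defines the grouped Lexis layout: five-year age groups 15-19 ... 75-79
#' (13 groups), five-year periods 2003-2007 ... 2018-2022 (4 groups), and
#' the implied cohort diagonals, of which there are always
#' `n_age + n_period - 1` (16 for the defaults). Cohort labels are the
#' birth-year spans realized on each diagonal (e.g. "1924-1932").
#'
#' @param age_start First age included (default 15).
#' @param age_width Width of each age group in years (default 5).
#' @param n_age Number of age groups (default 13).
#' @param period_start First calendar year included (default 2003).
#' @param period_width Width of each period group in years (default 5).
#' @param n_period Number of period groups (default 4).
#' @return An object of class `apc_grouping` with the derived `n_cohort`
#'   and human-readable labels per factor.
#' @export
grouping_scheme <- function(age_start = 15L, age_width = 5L, n_age = 13L,
                            period_start = 2003L, period_width = 5L,
                            n_period = 4L) {
  stopifnot(age_width >= 1, period_width >= 1, n_age >= 2, n_period >= 2)
  n_cohort <- n_age + n_period - 1L
  age_lo <- age_start + age_width * (0:(n_age - 1))
  per_lo <- period_start + period_width * (0:(n_period - 1))
  age_labels <- sprintf("%d-%d", age_lo, age_lo + age_width - 1L)
  period_labels <- sprintf("%d-%d", per_lo, per_lo + period_width - 1L)
  # cohort diagonal k collects (period_idx - age_idx + n_age - 1 == k);
  # birth years on it span [per_lo - age_hi, per_hi - age_lo] intersected
  # with realized combinations
  cohort_lo <- integer(n_cohort)
  cohort_hi <- integer(n_cohort)
  for (k in 0:(n_cohort - 1L)) {
    births <- integer(0)
    for (p in 0:(n_period - 1L)) {
      a <- p - k + n_age - 1L
      if (a >= 0 && a < n_age) {
        yrs <- per_lo[p + 1L]:(per_lo[p + 1L] + period_width - 1L)
        ags <- age_lo[a + 1L]:(age_lo[a + 1L] + age_width - 1L)
        births <- c(births, min(yrs) - max(ags), max(yrs) - min(ags))
      }
    }
    cohort_lo[k + 1L] <- min(births)
    cohort_hi[k + 1L] <- max(births)
  }
  structure(list(
    age_start = as.integer(age_start), age_width = as.integer(age_width),
    n_age = as.integer(n_age),
    period_start = as.integer(period_start),
    period_width = as.integer(period_width), n_period = as.integer(n_period),
    n_cohort = n_cohort,
    age_labels = age_labels, period_labels = period_labels,
    cohort_labels = sprintf("%d-%d", cohort_lo, cohort_hi)
  ), class = "apc_grouping")
}

#' Assign records to age, period, and cohort groups
#'
#' Adds 0-based `age_idx`, `period_idx`, and `cohort_idx` columns. The
#' cohort index is the Lexis diagonal
#' `period_idx - age_idx + (n_age - 1)`, so the oldest cohort (oldest age
#' group in the first period) gets index 0 and the youngest cohort gets
#' index `n_cohort - 1`.
#'
#' @param table An `apc_microdata` table whose ages and years all fall
#'   inside the scheme ranges (filter first; out-of-range records are an
#'   error naming the offenders).
#' @param scheme An `apc_grouping`, default [grouping_scheme()].
#' @return The table with index columns added and the scheme attached as
#'   attribute `scheme`.
#' @export
assign_groups <- function(table, scheme = grouping_scheme()) {
  stopifnot(inherits(scheme, "apc_grouping"))
  age_idx <- (table$age - scheme$age_start) %/% scheme$age_width
  period_idx <- (table$year - scheme$period_start) %/% scheme$period_width
  bad <- which(age_idx < 0 | age_idx >= scheme$n_age |
                 period_idx < 0 | period_idx >= scheme$n_period)
  if (length(bad) > 0) {
    stop("assign_groups: ", length(bad),
         " record(s) outside the grouping scheme (first offending row ",
         bad[1], ": age=", table$age[bad[1]], ", year=", table$year[bad[1]],
         "); apply filter_records() first")
  }
  out <- table
  out$age_idx <- as.integer(age_idx)
  out$period_idx <- as.integer(period_idx)
  out$cohort_idx <- as.integer(period_idx - age_idx + scheme$n_age - 1L)
  attr(out, "scheme") <- scheme
  out
}

#' Weighted orthogonal polynomial contrasts
#'
#' Builds polynomial contrast vectors over the 0-based group index that are
#' mutually orthogonal under the weighted inner product
#' `<a, b> = sum(w_g a_g b_g)` with `w` normalized to sum 1. Orthogonality
#' to the constant makes every contrast have weighted mean zero, which is
#' what keeps linear and nonlinear coefficients independent when group
#' sizes are unequal. The linear vector is left on the index scale (exactly
#' `index - weighted mean index`, slope 1 per group step, so linear
#' coefficients read as outcome units per group step); nonlinear vectors
#' (orders 2..`max_order`) are scaled to unit weighted root-mean-square
#' norm.
#'
#' Construction is modified Gram-Schmidt on the monomials `1, g, g^2, ...`
#' with a second orthogonalization pass, giving off-diagonal Gram entries
#' at machine precision (well below 1e-10) for the group counts used here.
#'
#' @param group_weights Positive weights per group, typically per-group sums
#'   of survey weights. Any overall rescaling leaves the basis unchanged.
#' @param max_order Highest polynomial order, at most `G - 1`.
#' @param factor Optional label (`"age"`, `"period"`, `"cohort"`) carried in
#'   the result.
#' @return An object of class `apc_contrasts`: `factor`, `n_groups`,
#'   `group_weights` (normalized), `linear` (length-G vector), and
#'   `nonlinear` (named list `nl2`, `nl3`, ... of length-G vectors; empty if
#'   `max_order < 2`).
#' @export
weighted_orthogonal_contrasts <- function(group_weights, max_order = 5L,
                                          factor = NA_character_) {
  G <- length(group_weights)
  if (G < 2) stop("need at least 2 groups")
  if (any(!is.finite(group_weights)) || any(group_weights <= 0)) {
    stop("all group weights must be positive and finite")
  }
  if (max_order > G - 1) {
    stop("max_order (", max_order, ") exceeds G - 1 (", G - 1, ")")
  }
  w <- group_weights / sum(group_weights)
  g <- 0:(G - 1)
  wdot <- function(a, b) sum(w * a * b)

  linear <- g - wdot(g, rep(1, G))
  basis <- list(rep(1, G), linear)
  nonlinear <- list()
  if (max_order >= 2) {
    for (k in 2:max_order) {
      v <- g^k
      for (pass in 1:2) {
        for (b in basis) v <- v - wdot(v, b) / wdot(b, b) * b
      }
      v <- v / sqrt(wdot(v, v))   # unit weighted RMS since sum(w) = 1
      basis[[length(basis) + 1L]] <- v
      nonlinear[[paste0("nl", k)]] <- v
    }
  }
  structure(list(factor = factor, n_groups = G, group_weights = w,
                 linear = linear, nonlinear = nonlinear),
            class = "apc_contrasts")
}

#' Contrast bases for all three APC factors
#'
#' Computes per-group weight totals from a grouped table and builds the
#' weighted orthogonal contrast basis for age, period, and cohort.
#' Polynomial contrasts beyond order 5 are omitted (set to zero) to smooth
#' the estimates; each factor uses `min(5, G - 1)`, i.e. orders 2-5 for age
#' and cohort and 2-3 for the four periods under the default scheme.
#'
#' @param grouped A table from [assign_groups()].
#' @param max_order Truncation order, default 5.
#' @param contrast_weights `"weights"` (per-group sums of survey weights,
#'   default) or `"counts"` (per-group record counts).
#' @return A named list of three `apc_contrasts` (`age`, `period`,
#'   `cohort`).
#' @export
contrast_bases <- function(grouped, max_order = 5L,
                           contrast_weights = c("weights", "counts")) {
  contrast_weights <- match.arg(contrast_weights)
  scheme <- attr(grouped, "scheme")
  if (is.null(scheme)) stop("table must come from assign_groups()")
  w <- if (contrast_weights == "weights") grouped$weight else
    rep(1, nrow(grouped))
  sums <- function(idx, G) {
    s <- vapply(0:(G - 1), function(k) sum(w[idx == k]), numeric(1))
    if (any(s <= 0)) {
      stop("empty group(s) for factor at index ",
           paste(which(s <= 0) - 1L, collapse = ", "),
           "; contrasts need every group occupied")
    }
    s
  }
  list(
    age = weighted_orthogonal_contrasts(sums(grouped$age_idx, scheme$n_age),
                                        min(max_order, scheme$n_age - 1L),
                                        "age"),
    period = weighted_orthogonal_contrasts(
      sums(grouped$period_idx, scheme$n_period),
      min(max_order, scheme$n_period - 1L), "period"),
    cohort = weighted_orthogonal_contrasts(
      sums(grouped$cohort_idx, scheme$n_cohort),
      min(max_order, scheme$n_cohort - 1L), "cohort")
  )
}

# Weighted effect coding for a categorical column: one column per
# non-reference level present, coding 1 on that level and -w_level/w_ref on
# the reference, so each column has weighted mean zero and the intercept
# stays on the weighted grand mean.
weighted_effect_columns <- function(values, weights, levels, reference,
                                    prefix) {
  present <- levels[levels %in% unique(values)]
  if (length(present) < 2) {
    return(matrix(numeric(0), nrow = length(values), ncol = 0))
  }
  ref <- if (reference %in% present) reference else present[length(present)]
  others <- setdiff(present, ref)
  wsum <- vapply(present, function(l) sum(weights[values == l]), numeric(1))
  names(wsum) <- present
  out <- matrix(0, nrow = length(values), ncol = length(others))
  colnames(out) <- paste0(prefix, others)
  is_ref <- values == ref
  for (j in seq_along(others)) {
    out[values == others[j], j] <- 1
    out[is_ref, j] <- -wsum[others[j]] / wsum[ref]
  }
  out
}

#' Build the estimable APC design matrix
#'
#' Assembles the regression design for the reparameterized model: because
#' the centered period index is exactly the sum of the centered age and
#' cohort indices on a Lexis surface, the period linear column is excluded
#' and the two remaining linear columns carry `theta1 = alpha_L + pi_L`
#' (on the age linear contrast) and `theta2 = gamma_L + pi_L` (on the
#' cohort linear contrast). Nonlinear contrasts for all three factors are
#' included, as are weighted-effect-coded day-of-week (reference Sunday)
#' and holiday (reference non-holiday) covariates: 20 columns for the
#' default scheme.
#'
#' @param grouped A table from [assign_groups()].
#' @param bases Contrast bases from [contrast_bases()] built on the same
#'   table (mismatched group counts are an error).
#' @param covariates Character vector among `"day_of_week"`, `"holiday"`;
#'   default both.
#' @param linear_scale `"group"` (slope per group step, default) or
#'   `"year"` (linear columns divided by the group width so slopes read per
#'   calendar year).
#' @return An object of class `apc_design`: model matrix `X` (with column
#'   labels), outcome `y`, weights `w`, plus the `bases`, `scheme`, and
#'   options used.
#' @export
build_design_matrix <- function(grouped, bases = contrast_bases(grouped),
                                covariates = c("day_of_week", "holiday"),
                                linear_scale = c("group", "year")) {
  linear_scale <- match.arg(linear_scale)
  scheme <- attr(grouped, "scheme")
  if (is.null(scheme)) stop("table must come from assign_groups()")
  stopifnot(bases$age$n_groups == scheme$n_age,
            bases$period$n_groups == scheme$n_period,
            bases$cohort$n_groups == scheme$n_cohort)
  n <- nrow(grouped)
  if (n == 0) stop("no records to build a design from")

  lookup <- function(vec, idx) vec[idx + 1L]
  a_div <- if (linear_scale == "year") scheme$age_width else 1
  cols <- list("(Intercept)" = rep(1, n),
               age_L = lookup(bases$age$linear, grouped$age_idx) / a_div,
               cohort_L = lookup(bases$cohort$linear, grouped$cohort_idx) / a_div)
  for (k in names(bases$age$nonlinear)) {
    cols[[paste0("age_", k)]] <- lookup(bases$age$nonlinear[[k]],
                                        grouped$age_idx)
  }
  for (k in names(bases$period$nonlinear)) {
    cols[[paste0("period_", k)]] <- lookup(bases$period$nonlinear[[k]],
                                           grouped$period_idx)
  }
  for (k in names(bases$cohort$nonlinear)) {
    cols[[paste0("cohort_", k)]] <- lookup(bases$cohort$nonlinear[[k]],
                                           grouped$cohort_idx)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if ("day_of_week" %in% covariates) {
    X <- cbind(X, weighted_effect_columns(grouped$day_of_week,
                                          grouped$weight, DAY_LEVELS,
                                          "Sun", "dow_"))
  }
  if ("holiday" %in% covariates) {
    hol <- ifelse(grouped$holiday, "yes", "no")
    X <- cbind(X, weighted_effect_columns(hol, grouped$weight,
                                          c("yes", "no"), "no", "holiday_"))
  }

  qrX <- qr(X * sqrt(grouped$weight))
  if (qrX$rank < ncol(X)) {
    counts <- function(idx, G) vapply(0:(G - 1),
                                      function(k) sum(idx == k), numeric(1))
    empty <- c(
      if (any(counts(grouped$age_idx, scheme$n_age) == 0))
        paste0("age:", paste(which(counts(grouped$age_idx, scheme$n_age) == 0) - 1,
                             collapse = ",")),
      if (any(counts(grouped$period_idx, scheme$n_period) == 0))
        paste0("period:", paste(which(counts(grouped$period_idx, scheme$n_period) == 0) - 1,
                                collapse = ",")),
      if (any(counts(grouped$cohort_idx, scheme$n_cohort) == 0))
        paste0("cohort:", paste(which(counts(grouped$cohort_idx, scheme$n_cohort) == 0) - 1,
                                collapse = ",")))
    stop("design matrix rank deficient (rank ", qrX$rank, " < ", ncol(X),
         " columns)",
         if (length(empty)) paste0("; empty groups: ",
                                   paste(empty, collapse = "; ")) else "")
  }

  structure(list(X = X, y = grouped$minutes_alone, w = grouped$weight,
                 bases = bases, scheme = scheme,
                 covariates = covariates, linear_scale = linear_scale),
            class = "apc_design")
}

#' Export a contrast basis as a data.frame
#'
#' One row per group: label, normalized group weight, linear contrast, and
#' each nonlinear contrast, for audit or plotting.
#'
#' @param basis An `apc_contrasts`.
#' @param labels Optional group labels.
#' @return A data.frame.
#' @export
contrasts_as_data_frame <- function(basis, labels = NULL) {
  df <- data.frame(group = seq_len(basis$n_groups) - 1L,
                   label = labels %||% as.character(seq_len(basis$n_groups) - 1L),
                   weight = basis$group_weights,
                   linear = basis$linear)
  for (k in names(basis$nonlinear)) df[[k]] <- basis$nonlinear[[k]]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
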