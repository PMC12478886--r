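#' Run configuration for the full APC pipeline
#'
#' Bundles every stage option: input, filters, grouping, contrast options,
#' covariates, constraint, strata, and output directory. All defaults
#' reproduce the primary analysis configuration; the weekday/weekend and
#' pre-pandemic sensitivity analyses are pure config changes
#' (`filter = filter_spec(day_subset = ...)`, `filter =
#' filter_spec(year_range = c(2003, 2019))`).
#'
#' @param input Path to a microdata file, or an `apc_microdata` table.
#' @param filter An `apc_filter`, default [filter_spec()].
#' @param scheme An `apc_grouping`, default [grouping_scheme()].
#' @param constraint An `apc_constraint`, default [constraint_spec()].
#' @param strata Gender values fitted as fully separate models (each with
#'   its own contrast weights), default `c("female", "male")`.
#' @param covariates Covariates for the design, default day of week +
#'   holiday.
#' @param contrast_weights `"weights"` or `"counts"`.
#' @param linear_scale `"group"` or `"year"`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param dialect Input delimiter when `input` is a path.
#' @return An object of class `apc_run_config`.
#' @export
run_config <- function(input, filter = filter_spec(),
                       scheme = grouping_scheme(),
                       constraint = constraint_spec(),
                       strata = c("female", "male"),
                       covariates = c("day_of_week", "holiday"),
                       contrast_weights = "weights",
                       linear_scale = "group",
                       out_dir = NULL, dialect = "comma") {
  stopifnot(inherits(filter, "apc_filter"), inherits(scheme, "apc_grouping"),
            inherits(constraint, "apc_constraint"), length(strata) >= 1)
  structure(list(input = input, filter = filter, scheme = scheme,
                 constraint = constraint, strata = strata,
                 covariates = covariates,
                 contrast_weights = contrast_weights,
                 linear_scale = linear_scale, out_dir = out_dir,
                 dialect = dialect),
            class = "apc_run_config")
}

#' Read a run configuration from YAML
#'
#' Flat YAML keys mirror the [run_config()] arguments; nested blocks
#' `filter`, `scheme`, and `constraint` mirror [filter_spec()],
#' [grouping_scheme()], and [constraint_spec()]. Unknown keys are an
#' error, so typos do not pass silently.
#'
#' @param path YAML file path.
#' @param input Optional input override (CLI `--data`).
#' @param out_dir Optional output-directory override.
#' @return An `apc_run_config`.
#' @export
read_run_config <- function(path, input = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("input", "filter", "scheme", "constraint", "strata",
             "covariates", "contrast_weights", "linear_scale", "out_dir",
             "dialect")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "))
  filt <- do.call(filter_spec, y$filter %||% list())
  sch <- do.call(grouping_scheme, y$scheme %||% list())
  con <- do.call(constraint_spec, y$constraint %||% list())
  run_config(input = input %||% y$input, filter = filt, scheme = sch,
             constraint = con, strata = y$strata %||% c("female", "male"),
             covariates = y$covariates %||% c("day_of_week", "holiday"),
             contrast_weights = y$contrast_weights %||% "weights",
             linear_scale = y$linear_scale %||% "group",
             out_dir = out_dir %||% y$out_dir,
             dialect = y$dialect %||% "comma")
}

fit_stratum <- function(table, config) {
  grouped <- assign_groups(table, config$scheme)
  bases <- contrast_bases(grouped, contrast_weights = config$contrast_weights)
  design <- build_design_matrix(grouped, bases,
                                covariates = config$covariates,
                                linear_scale = config$linear_scale)
  fit <- fit_apc_model(design)
  alpha_range <- grid_search_age_bounds(fit, config$constraint)
  region <- bounds_to_ranges(fit$theta1, fit$theta2, alpha_range)
  bands <- net_effect_bands(fit, region)
  list(fit = fit, region = region, bands = bands,
       summaries = lapply(bands, summarize_curve),
       descriptives = list(age = weighted_group_means(table, "age"),
                           year = weighted_group_means(table, "year"),
                           cohort_year = weighted_group_means(table,
                                                              "cohort_year")))
}

#' Run the full bounded-APC analysis pipeline
#'
#' Reads (or accepts) microdata, applies the filter, then per gender
#' stratum: assigns groups, builds the weighted orthogonal contrast bases
#' from that stratum's weights, fits the estimable model by weighted least
#' squares, bounds the linear age effect by grid search under the
#' constraint, propagates bounds along the canonical line, and assembles
#' net total effect curves with identification bands plus weighted
#' descriptive means. With `out_dir` set, writes per-stratum
#' `estimates.json`, `bounded_region.json`, `canonical_line.csv`,
#' `net_effects.csv`, `summaries.json`, `descriptives.csv`, and a run
#' `manifest.json` (config echo, row counts, package version). Everything
#' is deterministic: identical input and config give identical outputs.
#'
#' An empty stratum is skipped with a warning; all other stage errors
#' propagate, prefixed with the stratum.
#'
#' @param config An `apc_run_config`.
#' @return A list of class `apc_report`: per-stratum results
#'   (`fit`, `region`, `bands`, `summaries`, `descriptives`) plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "apc_run_config"))
  table <- if (inherits(config$input, "apc_microdata")) config$input else
    read_microdata(config$input, config$dialect)
  n_read <- nrow(table)
  filtered <- filter_records(table, config$filter)
  message(sprintf("[pipeline] input %d records, %d after filters",
                  n_read, nrow(filtered)))

  results <- list()
  for (stratum in config$strata) {
    sub <- filtered[filtered$gender == stratum, , drop = FALSE]
    sub <- as_apc_microdata(sub)
    if (nrow(sub) == 0) {
      warning("stratum '", stratum, "' is empty; skipped")
      next
    }
    res <- tryCatch(fit_stratum(sub, config), error = function(e) {
      stop("stratum '", stratum, "': ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf(
      "[pipeline] %s: n=%d theta1=%.3f theta2=%.3f alpha=[%.2f, %.2f]",
      stratum, res$fit$n_obs, res$fit$theta1, res$fit$theta2,
      res$region$alpha_range[1], res$region$alpha_range[2]))
    results[[stratum]] <- res
  }
  if (length(results) == 0) stop("no non-empty strata to fit")

  manifest <- list(
    package_version = as.character(utils::packageVersion("apcbound")),
    n_read = n_read, n_after_filter = nrow(filtered),
    strata = lapply(results, function(r) r$fit$n_obs),
    filter = unclass(config$filter),
    constraint = unclass(config$constraint),
    contrast_weights = config$contrast_weights,
    linear_scale = config$linear_scale
  )
  report <- structure(c(results, list(manifest = manifest)),
                      class = "apc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Write a pipeline report bundle to disk
#'
#' @param report An `apc_report` from [run_pipeline()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strata <- setdiff(names(report), "manifest")
  for (s in strata) {
    r <- report[[s]]
    d <- file.path(out_dir, s)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fit <- r$fit
    write_json_file(list(
      beta0 = fit$beta0, theta1 = fit$theta1, theta2 = fit$theta2,
      age_nl = as.list(fit$age_nl), period_nl = as.list(fit$period_nl),
      cohort_nl = as.list(fit$cohort_nl),
      covariate_coefs = as.list(fit$covariate_coefs),
      residual_sd = fit$residual_sd, n_obs = fit$n_obs,
      condition_number = fit$condition_number,
      linear_scale = fit$linear_scale,
      bases = lapply(fit$bases, function(b) list(
        factor = b$factor, group_weights = b$group_weights,
        linear = b$linear, nonlinear = b$nonlinear))),
      file.path(d, "estimates.json"))
    write_json_file(list(
      alpha_range = r$region$alpha_range, pi_range = r$region$pi_range,
      gamma_range = r$region$gamma_range,
      midpoint = as.list(unclass(r$region$midpoint)),
      theta1 = r$region$theta1, theta2 = r$region$theta2),
      file.path(d, "bounded_region.json"))
    utils::write.csv(canonical_line(fit$theta1, fit$theta2),
                     file.path(d, "canonical_line.csv"), row.names = FALSE)
    net <- do.call(rbind, lapply(names(r$bands), function(dim) {
      cbind(dimension = dim, as.data.frame(r$bands[[dim]]))
    }))
    utils::write.csv(net, file.path(d, "net_effects.csv"),
                     row.names = FALSE)
    write_json_file(r$summaries, file.path(d, "summaries.json"))
    desc <- do.call(rbind, lapply(names(r$descriptives), function(dim) {
      cbind(dimension = dim, r$descriptives[[dim]])
    }))
    utils::write.csv(desc, file.path(d, "descriptives.csv"),
                     row.names = FALSE)
  }
  write_json_file(report$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
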