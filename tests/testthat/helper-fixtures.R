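# Small in-code fixtures shared across test files.

# A hand-written microdata data.frame; all rows valid unless edited.
tiny_microdata <- function(n = 8) {
  ages <- c(33, 15, 79, 50, 22, 61, 45, 28)[seq_len(n)]
  years <- c(2013, 2022, 2003, 2010, 2018, 2005, 2021, 2008)[seq_len(n)]
  data.frame(
    age = ages, year = years, cohort_year = years - ages,
    gender = rep(c("female", "male"), length.out = n),
    minutes_alone = seq(150, by = 25, length.out = n),
    weight = rep(1, n),
    day_of_week = rep(c("Tue", "Sat", "Mon", "Sun"), length.out = n),
    holiday = rep(c(FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE
  )
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  df2 <- df
  if (is.logical(df2$holiday)) {
    df2$holiday <- ifelse(df2$holiday, "true", "false")
  }
  utils::write.table(df2, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

# Fast noiseless-ish generator config for structural tests.
quick_config <- function(seed = 7, n = 20000, noise_sd = 60, ...) {
  sim_config(seed = seed, n_records = n, noise_sd = noise_sd, ...)
}

fit_from_table <- function(tab, ...) {
  fit_apc_model(build_design_matrix(assign_groups(tab), ...))
}
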