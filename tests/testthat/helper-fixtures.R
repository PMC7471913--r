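# Shared fixtures: small synthetic designs used across test files.

R_GAS <- 8.314

# The canonical desk-scale design: 6 concentrations, 8-128 uM.
design_grid <- c(8, 16, 32, 64, 96, 128) * 1e-6

design_temps <- c(298.15, 310.15, 320.15)

# Published-style per-temperature association constants and site numbers
# used as generative ground truth (no raw titration data exist to refit).
tab_assoc_k <- c(4073.8, 1862.08, 2691.53)
tab_n_sites <- c(0.89, 0.84, 0.81)
tab_ksv <- c(9225.49, 6891, 15012)

noiseless_series <- function(assoc_k = 4073.8, hill_n = 0.89, f0 = 1000,
                             temperature = 298.15, conc = design_grid) {
  generate_titration(synthetic_spec(
    f0 = f0, assoc_k = assoc_k, hill_n = hill_n, conc_grid = conc,
    temperature = temperature, noise_rel = 0))
}

# Independent OLS oracle: closed-form slope/intercept from sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

write_fixture_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
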