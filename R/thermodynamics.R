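#' Gibbs free energy of binding
#'
#' `dG0 = -R T ln K` with `R = 8.314 J/(mol K)`.  Negative values mean
#' the association is spontaneous at that temperature.
#'
#' @param k Association constant(s), > 0.
#' @param t Absolute temperature(s) in K, > 0.  Vectorized; `k` and `t`
#'   are recycled against each other.
#' @return `dG0` in J/mol.
#' @examples
#' gibbs_free_energy(4073.8, 298.15) / 1000   # -20.60 kJ/mol
#' @export
gibbs_free_energy <- function(k, t) {
  qf_check(is.numeric(k) && all(k > 0), "k must be positive",
           "quenchfit_domain_error")
  qf_check(is.numeric(t) && all(t > 0), "t must be positive (K)",
           "quenchfit_domain_error")
  -.R_GAS * t * log(k)
}

#' van't Hoff regression of association constants on temperature
#'
#' OLS of `ln K` on `1/T`, from `ln K = -dH0/(R T) + dS0/R`: the slope is
#' `-dH0/R` and the intercept `dS0/R`.  Assumes `dH0` and `dS0` are
#' constant over the temperature range (no heat-capacity term).
#'
#' @param temperature Absolute temperatures in K (at least 2 distinct).
#' @param k Association constants (> 0), aligned with `temperature`.
#'   Alternatively `temperature` may be a data frame with columns
#'   `temperature` and `k` (as returned by [vant_hoff_constants()]).
#' @return An object of class `vant_hoff_fit` with fields `delta_h`
#'   (J/mol), `delta_s` (J/(mol K)), `r_squared`, `n_temperatures`.
#' @examples
#' vant_hoff_fit(c(298.15, 310.15, 320.15), c(4073.8, 1862.08, 2691.53))
#' @export
vant_hoff_fit <- function(temperature, k = NULL) {
  if (is.data.frame(temperature)) {
    k <- temperature$k
    temperature <- temperature$temperature
  }
  qf_check(length(temperature) == length(k),
           "temperature and k must have equal length")
  qf_check(all(temperature > 0), "temperatures must be positive (K)",
           "quenchfit_domain_error")
  qf_check(all(k > 0), "association constants must be positive",
           "quenchfit_domain_error")
  if (length(unique(temperature)) < 2) {
    qf_error("van't Hoff fit needs >= 2 distinct temperatures",
             "quenchfit_insufficient_data")
  }
  x <- 1 / temperature
  y <- log(k)
  fit <- stats::lm(y ~ x)
  structure(list(delta_h = -.R_GAS * unname(stats::coef(fit)[2]),
                 delta_s = .R_GAS * unname(stats::coef(fit)[1]),
                 r_squared = r_squared_of(y, stats::fitted(fit)),
                 n_temperatures = length(unique(temperature))),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (%d temperatures): dH0 = %.4g kJ/mol, dS0 = %.4g J/(mol K), R2 = %.4f\n",
              x$n_temperatures, x$delta_h / 1000, x$delta_s, x$r_squared))
  invisible(x)
}

#' Classify the dominant intermolecular force from (dH0, dS0) signs
#'
#' The conventional sign rules for protein--ligand association:
#' `dH0 > 0, dS0 > 0` — hydrophobic association; `dH0 < 0, dS0 < 0` —
#' van der Waals forces or hydrogen bonding; `dH0 < 0, dS0 > 0` —
#' electrostatic interaction.  An enthalpy within `zero_tol` of zero, or
#' any remaining sign pattern (e.g. `dH0 > 0, dS0 <= 0`, or `dS0 == 0`),
#' is `"indeterminate"`.  Every `(dH0, dS0)` pair receives exactly one
#' label.
#'
#' @param delta_h Standard enthalpy change, J/mol.
#' @param delta_s Standard entropy change, J/(mol K).
#' @param zero_tol Half-width of the "enthalpy approximately zero" band,
#'   J/mol (>= 0).
#' @return One of `"hydrophobic"`, `"van_der_waals_or_h_bond"`,
#'   `"electrostatic"`, `"indeterminate"`.
#' @examples
#' classify_forces(-16100, 13.3)   # "electrostatic"
#' @export
classify_forces <- function(delta_h, delta_s, zero_tol = 500) {
  qf_check(zero_tol >= 0, "zero_tol must be non-negative",
           "quenchfit_domain_error")
  if (delta_h > zero_tol && delta_s > 0) "hydrophobic"
  else if (delta_h < -zero_tol && delta_s < 0) "van_der_waals_or_h_bond"
  else if (delta_h < -zero_tol && delta_s > 0) "electrostatic"
  else "indeterminate"
}

#' Full thermodynamic analysis across temperatures
#'
#' Combines per-temperature Gibbs free energies (`-RT ln K`), the van't
#' Hoff regression for `dH0`/`dS0`, the force classification, and
#' spontaneity flags.  `dG0` is reported both directly and via
#' `dH0 - T dS0`; on van't Hoff-consistent constants the two agree
#' exactly, and a discrepancy beyond 5% is flagged (it signals that the
#' constants do not follow a single linear van't Hoff relation).
#'
#' @param temperature Absolute temperatures (K), or a data frame with
#'   columns `temperature` and `k`.
#' @param k Association constants (> 0).
#' @param zero_tol Enthalpy tolerance for [classify_forces()], J/mol.
#' @return An object of class `thermo_result` with fields
#'   `per_temperature` (data frame: `temperature`, `assoc_k`, `delta_g`,
#'   `delta_g_vant_hoff`, `spontaneous`), `delta_h`, `delta_s`,
#'   `force_label`, `r_squared_vant_hoff`, `flags`.
#' @export
thermo_analysis <- function(temperature, k = NULL, zero_tol = 500) {
  if (is.data.frame(temperature)) {
    k <- temperature$k
    temperature <- temperature$temperature
  }
  vh <- vant_hoff_fit(temperature, k)
  dg <- gibbs_free_energy(k, temperature)
  dg_vh <- vh$delta_h - temperature * vh$delta_s
  flags <- character(0)
  rel <- abs(dg - dg_vh) / pmax(abs(dg), 1)
  if (any(rel > 0.05)) {
    flags <- c(flags, sprintf(
      "direct -RT ln K and dH0 - T dS0 disagree by up to %.1f%%: constants deviate from a single van't Hoff line",
      100 * max(rel)))
  }
  structure(list(per_temperature = data.frame(
                   temperature = temperature,
                   assoc_k = k,
                   delta_g = dg,
                   delta_g_vant_hoff = dg_vh,
                   spontaneous = dg < 0),
                 delta_h = vh$delta_h,
                 delta_s = vh$delta_s,
                 force_label = classify_forces(vh$delta_h, vh$delta_s,
                                               zero_tol),
                 zero_tol = zero_tol,
                 r_squared_vant_hoff = vh$r_squared,
                 flags = flags),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Thermodynamics: dH0 = %.4g kJ/mol, dS0 = %.4g J/(mol K) -> %s\n",
              x$delta_h / 1000, x$delta_s, x$force_label))
  pt <- x$per_temperature
  for (i in seq_len(nrow(pt))) {
    cat(sprintf("  T = %.2f K: K = %.4g, dG0 = %.4g kJ/mol%s\n",
                pt$temperature[i], pt$assoc_k[i], pt$delta_g[i] / 1000,
                if (pt$spontaneous[i]) " (spontaneous)" else ""))
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
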