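#' Double-logarithm binding fit
#'
#' OLS of `log10((F0 - F)/F)` on `log10 [Q]`.  The slope is the number of
#' binding sites per protein `n`; the association constant is
#' `K = 10^intercept`.  `K` carries units `mol^-n L^n` — it is a plain
#' `M^-1` only when `n = 1`; the fitted `n` should always be reported
#' alongside.  Points with `F >= F0` have no defined log-transform and
#' are dropped (never clamped), listed in `dropped_points` and flagged.
#'
#' @param series A [titration_series()] with at least 3 usable points
#'   (`[Q] > 0` and `0 < F < F0`).
#' @return An object of class `binding_fit` with fields `temperature`,
#'   `assoc_k`, `n_sites`, `r_squared`, `n_points_used`,
#'   `dropped_points` (concentrations, mol/L), `flags`.
#' @examples
#' s <- generate_titration(synthetic_spec(assoc_k = 4073.8, hill_n = 0.89))
#' double_log_fit(s)
#' @export
double_log_fit <- function(series) {
  d <- .binding_regression(series, log_base = 10)
  structure(list(temperature = series$temperature,
                 assoc_k = 10^d$intercept,
                 n_sites = d$slope,
                 r_squared = d$r_squared,
                 n_points_used = d$n_used,
                 dropped_points = d$dropped,
                 flags = d$flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %.2f K: K = %.4g mol^-n L^n, n = %.4g sites, R2 = %.4f (%d points)\n",
              x$temperature, x$assoc_k, x$n_sites, x$r_squared,
              x$n_points_used))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Hill-plot cooperativity fit
#'
#' OLS of `ln((F0 - F)/F)` on `ln [Q]` — the same regression as
#' [double_log_fit()] in a different log base, so the slope (the Hill
#' coefficient) is identical to `n_sites`.  The dissociation constant is
#' recovered from the intercept `-n ln kD` as `kD = exp(-intercept/n)`,
#' which enforces the general linkage `K = kD^(-n)` (the textbook
#' `K = 1/kD` is its `n = 1` special case).  Cooperativity is labelled by
#' [classify_cooperativity()].
#'
#' @param series A [titration_series()]; preconditions as
#'   [double_log_fit()].  A non-positive slope leaves `kD` undefined and
#'   is a degenerate-fit error.
#' @param coop_tol Tolerance passed to [classify_cooperativity()].
#' @return An object of class `hill_fit` with fields `temperature`,
#'   `hill_n`, `k_d` (mol/L), `q_max` (`NA` for the linearized plot),
#'   `cooperativity`, `r_squared`, `flags`.
#' @export
hill_plot_fit <- function(series, coop_tol = 0.15) {
  d <- .binding_regression(series, log_base = exp(1))
  if (d$slope <= 0) {
    qf_error(sprintf(
      "Hill plot slope %.4g is not positive: kD undefined (fluorescence must decrease with [Q])",
      d$slope), "quenchfit_fit_error")
  }
  structure(list(temperature = series$temperature,
                 hill_n = d$slope,
                 k_d = exp(-d$intercept / d$slope),
                 q_max = NA_real_,
                 cooperativity = classify_cooperativity(d$slope, coop_tol),
                 coop_tol = coop_tol,
                 r_squared = d$r_squared,
                 n_points_used = d$n_used,
                 dropped_points = d$dropped,
                 flags = d$flags),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit at %.2f K: n = %.4g, kD = %.4g mol/L%s -> %s cooperativity\n",
              x$temperature, x$hill_n, x$k_d,
              if (is.finite(x$q_max)) sprintf(", Qmax = %.4g", x$q_max) else "",
              x$cooperativity))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

## Shared log-log regression behind the double-log and Hill plots.
.binding_regression <- function(series, log_base) {
  qf_check(inherits(series, "titration_series"),
           "series must be a titration_series")
  conc <- series$quencher_conc
  f <- series$intensity
  pos <- conc > 0
  usable <- pos & f < series$f0
  dropped <- conc[pos & !usable]
  flags <- character(0)
  if (length(dropped) > 0) {
    flags <- sprintf(
      "dropped %d point(s) with F >= F0 before log transform at T = %g K ([Q] = %s mol/L)",
      length(dropped), series$temperature,
      paste(signif(dropped, 6), collapse = ", "))
  }
  if (sum(usable) < 3) {
    qf_error(sprintf(
      "binding fit needs >= 3 points with 0 < F < F0 and [Q] > 0 (got %d)",
      sum(usable)), "quenchfit_insufficient_data")
  }
  x <- log(conc[usable], base = log_base)
  y <- log((series$f0 - f[usable]) / f[usable], base = log_base)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r_squared_of(y, stats::fitted(fit)),
       n_used = sum(usable),
       dropped = dropped,
       flags = flags)
}

#' Nonlinear Hill saturation fit
#'
#' Levenberg--Marquardt least squares of the quenching fraction against
#' the saturation model `Q = Qmax [Q]^n / (kD^n + [Q]^n)`.  Unlike the
#' linearized plots this variant estimates the saturation value `Qmax`
#' (or holds it at `fix_qmax`) and weights points on the original `Q`
#' scale.  Starting values come from [hill_plot_fit()]; convergence
#' tolerance is `1e-10` on the parameters.
#'
#' @param series A [titration_series()] with at least 4 points when
#'   `Qmax` is free, 3 when fixed.
#' @param fix_qmax Optional fixed `Qmax` in `(0, 1]`.
#' @param coop_tol Tolerance for the cooperativity label.
#' @return A `hill_fit` object with `q_max` populated.
#' @export
hill_saturation_fit <- function(series, fix_qmax = NULL, coop_tol = 0.15) {
  qf_check(inherits(series, "titration_series"),
           "series must be a titration_series")
  use <- series$quencher_conc > 0
  conc <- series$quencher_conc[use]
  q <- quenching_fraction(series$f0, series$intensity[use])
  needed <- if (is.null(fix_qmax)) 4 else 3
  if (length(conc) < needed) {
    qf_error(sprintf("Hill saturation fit needs >= %d points (got %d)",
                     needed, length(conc)), "quenchfit_insufficient_data")
  }
  start <- tryCatch({
    h <- hill_plot_fit(series, coop_tol)
    list(n = h$hill_n, kd = h$k_d)
  }, error = function(e) list(n = 1, kd = stats::median(conc)))
  ctrl <- minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                     maxiter = 500)
  fit <- tryCatch({
    if (is.null(fix_qmax)) {
      minpack.lm::nlsLM(
        q ~ qmax * conc^n / (kd^n + conc^n),
        start = list(qmax = min(max(q) * 1.05, 1), kd = start$kd, n = start$n),
        lower = c(qmax = 1e-12, kd = 1e-15, n = 1e-6),
        upper = c(qmax = 1, kd = Inf, n = Inf),
        control = ctrl)
    } else {
      qf_check(fix_qmax > 0 && fix_qmax <= 1,
               "fix_qmax must lie in (0, 1]", "quenchfit_domain_error")
      qmax <- fix_qmax
      minpack.lm::nlsLM(
        q ~ qmax * conc^n / (kd^n + conc^n),
        start = list(kd = start$kd, n = start$n),
        lower = c(kd = 1e-15, n = 1e-6),
        control = ctrl)
    }
  }, error = function(e) {
    qf_error(paste0("Hill saturation fit failed to converge: ",
                    conditionMessage(e),
                    sprintf(" (start: kd = %.4g, n = %.4g)",
                            start$kd, start$n)),
             "quenchfit_fit_error")
  })
  cf <- stats::coef(fit)
  qmax_hat <- if (is.null(fix_qmax)) unname(cf["qmax"]) else fix_qmax
  n_hat <- unname(cf["n"])
  kd_hat <- unname(cf["kd"])
  structure(list(temperature = series$temperature,
                 hill_n = n_hat,
                 k_d = kd_hat,
                 q_max = qmax_hat,
                 cooperativity = classify_cooperativity(n_hat, coop_tol),
                 coop_tol = coop_tol,
                 r_squared = r_squared_of(q, stats::fitted(fit)),
                 n_points_used = length(conc),
                 dropped_points = numeric(0),
                 flags = character(0)),
            class = "hill_fit")
}

#' Classify binding cooperativity from the Hill coefficient
#'
#' `n > 1` means positively cooperative binding (each bound ligand raises
#' the affinity for the next), `n < 1` negatively cooperative, and
#' `n = 1` independent (non-cooperative) sites.  A tolerance band around
#' 1 absorbs estimation noise: with the default `tol = 0.15`, an
#' estimated `n` of 0.89 is still called non-cooperative.
#'
#' @param n Hill coefficient (> 0).
#' @param tol Half-width of the non-cooperative band around 1 (>= 0).
#' @return `"positive"`, `"negative"` or `"non-cooperative"`.
#' @export
classify_cooperativity <- function(n, tol = 0.15) {
  qf_check(is.numeric(n) && length(n) == 1 && n > 0,
           "n must be a single positive number", "quenchfit_domain_error")
  qf_check(tol >= 0, "tol must be non-negative", "quenchfit_domain_error")
  if (abs(n - 1) <= tol) "non-cooperative"
  else if (n > 1) "positive"
  else "negative"
}
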