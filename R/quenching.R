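#' Quenching fraction
#'
#' `Q = (F0 - F) / F0`, the relative loss of fluorescence caused by the
#' quencher.  `Q` is not clamped: a point with `F > F0` yields a negative
#' value (flagged by [validate_set()] upstream rather than silently
#' altered here).
#'
#' @param f0 Reference intensity without quencher (> 0).
#' @param f Measured intensity (> 0); vectorized.
#' @return Quenching fraction(s), dimensionless, `< 1`.
#' @examples
#' quenching_fraction(1000, 250)   # 0.75
#' @export
quenching_fraction <- function(f0, f) {
  qf_check(is.numeric(f0) && all(f0 > 0),
           "f0 must be positive", "quenchfit_domain_error")
  qf_check(is.numeric(f) && all(f > 0),
           "f must be positive", "quenchfit_domain_error")
  (f0 - f) / f0
}

#' Stern-Volmer fit of a titration series
#'
#' Ordinary least squares of `y = F0/F` against `x = [Q]` with a free
#' intercept.  The slope is the Stern--Volmer constant `Ksv` (L/mol); the
#' bimolecular quenching rate constant is `Kq = Ksv / tau` where `tau` is
#' the unquenched fluorophore lifetime.  The model's theoretical
#' intercept is 1; the intercept is nevertheless estimated freely (fixing
#' it would bias the slope on real data) and a deviation beyond 0.1 is
#' flagged.
#'
#' @param series A [titration_series()] with at least 3 points at
#'   `[Q] > 0`.
#' @param tau Fluorophore lifetime in seconds.  The default `1e-8` s is
#'   the conventional average lifetime of intrinsic biomacromolecule
#'   fluorophores.
#' @return An object of class `quenching_fit` with fields `temperature`,
#'   `ksv`, `intercept`, `r_squared`, `kq`, `tau`, `n_points`, `flags`.
#' @export
stern_volmer_fit <- function(series, tau = 1e-8) {
  qf_check(inherits(series, "titration_series"),
           "series must be a titration_series")
  qf_check(tau > 0, "tau must be positive", "quenchfit_domain_error")
  use <- series$quencher_conc > 0
  x <- series$quencher_conc[use]
  y <- series$f0 / series$intensity[use]
  if (length(x) < 3) {
    qf_error(sprintf("Stern-Volmer fit needs >= 3 points with [Q] > 0 (got %d)",
                     length(x)), "quenchfit_insufficient_data")
  }
  fit <- stats::lm(y ~ x)
  ksv <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  flags <- character(0)
  if (abs(intercept - 1) > 0.1) {
    flags <- c(flags, sprintf(
      "Stern-Volmer intercept %.4g deviates from 1 by more than 0.1 at T = %g K",
      intercept, series$temperature))
  }
  structure(list(temperature = series$temperature,
                 ksv = ksv,
                 intercept = intercept,
                 r_squared = r_squared_of(y, stats::fitted(fit)),
                 kq = ksv / tau,
                 tau = tau,
                 n_points = length(x),
                 flags = flags),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %.2f K: Ksv = %.4g L/mol, intercept = %.4g, R2 = %.4f\n",
              x$temperature, x$ksv, x$intercept, x$r_squared))
  cat(sprintf("  Kq = Ksv/tau = %.4g L/(mol s)  (tau = %g s, %d points)\n",
              x$kq, x$tau, x$n_points))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' `Kq = Ksv / tau`.  Values above the diffusion-controlled ceiling
#' (about `2e10` L/(mol s)) conventionally indicate static quenching;
#' that comparison is made in [classify_mechanism()].
#'
#' @param ksv Stern--Volmer constant, L/mol.
#' @param tau Fluorophore lifetime, s (> 0).
#' @return `kq` in L/(mol s).
#' @examples
#' quenching_rate(6891, 1e-8)  # 6.891e11
#' @export
quenching_rate <- function(ksv, tau) {
  qf_check(is.numeric(tau) && all(tau > 0),
           "tau must be positive", "quenchfit_domain_error")
  ksv / tau
}

#' Classify the quenching mechanism from the temperature trend
#'
#' Dynamic (collisional) quenching grows more efficient with temperature
#' because diffusion speeds up, so `Ksv` increases with `T`; static
#' (ground-state complex) quenching weakens with temperature, so `Ksv`
#' decreases.  The label comes from the sign of the OLS slope of `Ksv`
#' versus `T` across all fits — strict monotonicity is not required, and
#' with three temperatures no significance test is attempted.  Each
#' fit's `Kq` is additionally compared with the diffusion-limited
#' ceiling; that comparison is advisory only (reported as flags) and
#' never overrides the trend label.
#'
#' @param fits A list of [stern_volmer_fit()] results (order irrelevant).
#' @param ceiling Diffusion-limited maximum of `Kq`, L/(mol s).
#' @return An object of class `mechanism_call` with fields `label`
#'   (`"dynamic"`, `"static"` or `"indeterminate"`), `trend_slope`
#'   (L/(mol K)), `exceeds_diffusion_limit` (named logical per
#'   temperature), `ceiling`, `flags`.
#' @export
classify_mechanism <- function(fits, ceiling = 2.0e10) {
  if (inherits(fits, "quenching_fit")) fits <- list(fits)
  qf_check(is.list(fits) && length(fits) >= 1 &&
             all(vapply(fits, inherits, logical(1), "quenching_fit")),
           "fits must be a list of quenching_fit objects")
  tt <- vapply(fits, `[[`, numeric(1), "temperature")
  ksv <- vapply(fits, `[[`, numeric(1), "ksv")
  kq <- vapply(fits, `[[`, numeric(1), "kq")
  ord <- order(tt)
  tt <- tt[ord]; ksv <- ksv[ord]; kq <- kq[ord]
  exceeds <- stats::setNames(kq > ceiling, format(tt))
  flags <- character(0)
  for (i in which(exceeds)) {
    flags <- c(flags, sprintf(
      "Kq = %.4g L/(mol s) at T = %g K exceeds the diffusion-limited ceiling %.3g (advisory: suggests static quenching)",
      kq[i], tt[i], ceiling))
  }
  if (length(unique(tt)) < 2) {
    label <- "indeterminate"
    slope <- NA_real_
  } else {
    slope <- unname(stats::coef(stats::lm(ksv ~ tt))[2])
    label <- if (slope > 0) "dynamic" else if (slope < 0) "static"
             else "indeterminate"
    if (any(diff(ksv) < 0) && slope > 0) {
      flags <- c(flags,
                 "Ksv is not monotone in temperature; mechanism call rests on the overall trend slope")
    }
  }
  structure(list(label = label, trend_slope = slope,
                 exceeds_diffusion_limit = exceeds,
                 ceiling = ceiling, flags = flags),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (Ksv-vs-T trend slope = %s L/(mol K))\n",
              x$label,
              if (is.na(x$trend_slope)) "NA" else sprintf("%.4g", x$trend_slope)))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
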