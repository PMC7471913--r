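#' Specify a synthetic titration experiment
#'
#' Parameters of the generative binding model
#' `F = F0 / (1 + K [Q]^n)`, optionally corrupted by multiplicative
#' Gaussian measurement noise.  This single family is simultaneously the
#' Stern--Volmer model (`n = 1`, `K = Ksv`), the double-log binding model
#' (`log10((F0-F)/F) = log10 K + n log10 [Q]` holds exactly), and the Hill
#' saturation model with `Qmax = 1` and `kD = K^(-1/n)` — the three
#' linearizations used downstream are mutually consistent only under this
#' family, which makes it the natural ground-truth oracle.
#'
#' @param f0 True zero-quencher intensity (arbitrary units, > 0).
#' @param assoc_k True association constant `K` (units `mol^-n L^n`,
#'   >= 0).
#' @param hill_n True binding-site/Hill coefficient `n` (> 0).
#' @param conc_grid Quencher concentrations in mol/L.  Defaults to the
#'   desk-scale design used throughout: 8, 16, 32, 64, 96, 128 micromolar.
#' @param temperature Absolute temperature in K.
#' @param noise_rel Relative standard deviation of the multiplicative
#'   Gaussian noise on `F` (0 = noiseless).
#' @param seed Integer seed; the generator is deterministic for a fixed
#'   seed and leaves the caller's RNG stream untouched.
#' @param noisy_f0 If `TRUE`, `f0` is also perturbed by one draw of the
#'   same noise; by default `f0` is published noise-free so that the
#'   quenching fraction's ground truth stays exact.
#' @param label Optional sample label passed through to the series.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_titration()]
#' @export
synthetic_spec <- function(f0 = 1000,
                           assoc_k = 4073.8,
                           hill_n = 0.89,
                           conc_grid = c(8, 16, 32, 64, 96, 128) * 1e-6,
                           temperature = 298.15,
                           noise_rel = 0,
                           seed = NULL,
                           noisy_f0 = FALSE,
                           label = NULL) {
  qf_check(f0 > 0, "f0 must be positive")
  qf_check(assoc_k >= 0, "assoc_k must be non-negative")
  qf_check(hill_n > 0, "hill_n must be positive")
  qf_check(noise_rel >= 0, "noise_rel must be non-negative")
  qf_check(all(conc_grid >= 0), "conc_grid must be non-negative")
  qf_check(temperature > 0, "temperature must be positive (K)")
  structure(list(f0 = f0, assoc_k = assoc_k, hill_n = hill_n,
                 conc_grid = sort(conc_grid), temperature = temperature,
                 noise_rel = noise_rel, seed = seed, noisy_f0 = noisy_f0,
                 label = label),
            class = "synthetic_spec")
}

#' Generate a synthetic titration series
#'
#' Evaluates the noiseless model `F = F0 / (1 + K [Q]^n)` on the
#' concentration grid, then applies multiplicative noise
#' `F * (1 + eps)`, `eps ~ N(0, noise_rel)`, redrawing any point that
#' would become non-positive.  With `noise_rel = 0` the output satisfies
#' the double-log relation exactly at every point, so a fit on it must
#' recover the generating parameters to numerical precision.
#'
#' @param spec A [synthetic_spec()].
#' @return A [titration_series()] with `f0 = spec$f0` (noise-free unless
#'   `noisy_f0`).
#' @examples
#' spec <- synthetic_spec(assoc_k = 9225.49, hill_n = 1, noise_rel = 0.01,
#'                        seed = 7)
#' stern_volmer_fit(generate_titration(spec))
#' @export
generate_titration <- function(spec) {
  qf_check(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  conc <- spec$conc_grid[spec$conc_grid > 0]
  f_true <- spec$f0 / (1 + spec$assoc_k * conc^spec$hill_n)
  with_preserved_seed(spec$seed, {
    f <- f_true
    f0 <- spec$f0
    if (spec$noise_rel > 0) {
      f <- f_true * (1 + stats::rnorm(length(f_true), 0, spec$noise_rel))
      while (any(f <= 0)) {
        bad <- f <= 0
        f[bad] <- f_true[bad] *
          (1 + stats::rnorm(sum(bad), 0, spec$noise_rel))
      }
      if (isTRUE(spec$noisy_f0)) {
        repeat {
          f0 <- spec$f0 * (1 + stats::rnorm(1, 0, spec$noise_rel))
          if (f0 > 0) break
        }
      }
    }
    titration_series(spec$temperature, conc, f, f0 = f0,
                     label = spec$label)
  })
}

#' Specify van't Hoff-consistent thermodynamics
#'
#' @param delta_h True standard enthalpy change (J/mol).
#' @param delta_s True standard entropy change (J/(mol K)).
#' @param temperatures At least two distinct absolute temperatures (K).
#' @return An object of class `vant_hoff_spec`.
#' @export
vant_hoff_spec <- function(delta_h, delta_s,
                           temperatures = c(298.15, 310.15, 320.15)) {
  qf_check(length(unique(temperatures)) >= 2,
           "at least two distinct temperatures required")
  qf_check(all(temperatures > 0), "temperatures must be positive (K)",
           "quenchfit_domain_error")
  structure(list(delta_h = delta_h, delta_s = delta_s,
                 temperatures = sort(temperatures)),
            class = "vant_hoff_spec")
}

#' Association constants implied by a van't Hoff specification
#'
#' Evaluates `K(T) = exp(-dH0/(R T) + dS0/R)` with
#' `R = 8.314 J/(mol K)`.  Feeding the result back into
#' [vant_hoff_fit()] recovers `dH0` and `dS0` to machine precision, since
#' `ln K` is exactly linear in `1/T`.
#'
#' @param vspec A [vant_hoff_spec()].
#' @return A data frame with columns `temperature` (K) and `k`.
#' @export
vant_hoff_constants <- function(vspec) {
  qf_check(inherits(vspec, "vant_hoff_spec"), "vspec must be a vant_hoff_spec")
  tt <- vspec$temperatures
  k <- exp(-vspec$delta_h / (.R_GAS * tt) + vspec$delta_s / .R_GAS)
  data.frame(temperature = tt, k = k)
}

#' Generate a full multi-temperature synthetic titration set
#'
#' Convenience wrapper: one [generate_titration()] series per temperature
#' with association constants tied together by [vant_hoff_constants()],
#' so the set is a consistent end-to-end ground truth for the whole
#' pipeline (binding fits, mechanism trend, and thermodynamics).
#'
#' @param vspec A [vant_hoff_spec()] fixing `K(T)`.
#' @param hill_n Common binding-site coefficient.
#' @param f0 Zero-quencher intensity shared by all series.
#' @param conc_grid Concentration grid in mol/L.
#' @param noise_rel Relative noise SD.
#' @param seed Integer seed; per-series seeds are derived from it.
#' @return A [titration_set()].
#' @export
generate_titration_set <- function(vspec, hill_n = 1, f0 = 1000,
                                   conc_grid = c(8, 16, 32, 64, 96, 128) * 1e-6,
                                   noise_rel = 0, seed = NULL) {
  ks <- vant_hoff_constants(vspec)
  series <- lapply(seq_len(nrow(ks)), function(i) {
    generate_titration(synthetic_spec(
      f0 = f0, assoc_k = ks$k[i], hill_n = hill_n, conc_grid = conc_grid,
      temperature = ks$temperature[i], noise_rel = noise_rel,
      seed = if (is.null(seed)) NULL else (seed + i - 1L) %% .Machine$integer.max))
  })
  titration_set(series)
}
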