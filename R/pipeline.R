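#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis chain in one
#' place.  Defaults: fluorophore lifetime `tau = 1e-8` s, diffusion
#' ceiling `2e10` L/(mol s), cooperativity tolerance 0.15, near-zero
#' enthalpy tolerance 500 J/mol, van't Hoff fed from the binding-analysis
#' association constants.
#'
#' @param tau Fluorophore lifetime, s (> 0).
#' @param kq_ceiling Diffusion-limited maximum of `Kq`, L/(mol s).
#' @param coop_tol Half-width of the non-cooperative band around
#'   `n = 1`.
#' @param zero_tol Enthalpy tolerance for force classification, J/mol.
#' @param vant_hoff_source Which per-temperature constants feed the van't
#'   Hoff regression: `"binding"` (double-log association constants, the
#'   default) or `"stern_volmer"` (quenching constants).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tau = 1e-8, kq_ceiling = 2.0e10,
                            coop_tol = 0.15, zero_tol = 500,
                            vant_hoff_source = c("binding", "stern_volmer")) {
  qf_check(tau > 0, "tau must be positive", "quenchfit_domain_error")
  qf_check(kq_ceiling >= 0 && coop_tol >= 0 && zero_tol >= 0,
           "tolerances must be non-negative", "quenchfit_domain_error")
  structure(list(tau = tau, kq_ceiling = kq_ceiling, coop_tol = coop_tol,
                 zero_tol = zero_tol,
                 vant_hoff_source = match.arg(vant_hoff_source)),
            class = "pipeline_config")
}

#' Run the full quenching / binding / thermodynamics pipeline
#'
#' Per temperature: Stern--Volmer fit and double-log/Hill binding fits.
#' Across temperatures: mechanism classification from the `Ksv` trend and
#' (when at least two temperatures are present) Gibbs energies, van't
#' Hoff `dH0`/`dS0` and the force label.  Advisory inconsistencies —
#' an intercept away from 1, `Kq` above the diffusion ceiling, a
#' non-monotone `Ksv` sequence — never abort the pipeline; they are
#' accumulated in `flags`, each exactly once.  The result is fully
#' deterministic for a fixed input and configuration.
#'
#' @param ts A [titration_set()].
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_result` with elements
#'   `quenching` (list of [stern_volmer_fit()] results plus the
#'   `mechanism` call), `binding` (list of [double_log_fit()] results),
#'   `cooperativity` (list of [hill_plot_fit()] results),
#'   `thermodynamics` ([thermo_analysis()] result, or `NULL` when fewer
#'   than two temperatures), `flags`, `config`.
#' @examples
#' ts <- generate_titration_set(vant_hoff_spec(-16100, 13.3))
#' run_pipeline(ts)
#' @export
run_pipeline <- function(ts, cfg = pipeline_config()) {
  qf_check(inherits(ts, "titration_set"), "ts must be a titration_set")
  qf_check(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  flags <- validate_set(ts)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      qf_error(paste0("[", name, "] ", conditionMessage(e)),
               "quenchfit_pipeline_error")
    })
  }

  sv <- stage("quenching", lapply(ts$series, stern_volmer_fit, tau = cfg$tau))
  mech <- stage("quenching", classify_mechanism(sv, ceiling = cfg$kq_ceiling))
  binding <- stage("binding", lapply(ts$series, double_log_fit))
  hill <- stage("cooperativity",
                lapply(ts$series, hill_plot_fit, coop_tol = cfg$coop_tol))

  thermo <- NULL
  if (length(ts$series) >= 2) {
    ks <- if (cfg$vant_hoff_source == "binding") {
      vapply(binding, `[[`, numeric(1), "assoc_k")
    } else {
      vapply(sv, `[[`, numeric(1), "ksv")
    }
    tt <- vapply(ts$series, `[[`, numeric(1), "temperature")
    thermo <- stage("thermodynamics",
                    thermo_analysis(tt, ks, zero_tol = cfg$zero_tol))
  } else {
    flags <- c(flags, "van't Hoff skipped: fewer than 2 temperatures")
  }

  for (obj in c(sv, list(mech), binding, hill,
                if (!is.null(thermo)) list(thermo))) {
    flags <- c(flags, obj$flags)
  }
  structure(list(quenching = list(fits = sv, mechanism = mech),
                 binding = binding,
                 cooperativity = hill,
                 thermodynamics = thermo,
                 flags = unique(flags),
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== Quenching ==\n")
  for (f in x$quenching$fits) print(f)
  print(x$quenching$mechanism)
  cat("== Binding ==\n")
  for (f in x$binding) print(f)
  cat("== Cooperativity ==\n")
  for (f in x$cooperativity) print(f)
  cat("== Thermodynamics ==\n")
  if (is.null(x$thermodynamics)) cat("  skipped\n") else print(x$thermodynamics)
  if (length(x$flags) > 0) {
    cat("== Flags ==\n")
    for (f in x$flags) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Relative cell viability from absorbances
#'
#' `100 * (Abs_sample - Abs_blank) / (Abs_control - Abs_blank)`, the
#' standard MTT-assay readout.  Values above 100% or below 0% are
#' returned as-is (flag upstream, never clamp).  This utility is
#' independent of the titration pipeline.
#'
#' @param abs_sample Absorbance of treated cells.
#' @param abs_control Absorbance of untreated (vehicle) cells.
#' @param abs_blank Absorbance of the cell-free blank.
#' @return Relative viability in percent; vectorized over `abs_sample`.
#' @examples
#' relative_viability(0.65, 0.85, 0.05)   # 75
#' @export
relative_viability <- function(abs_sample, abs_control, abs_blank) {
  qf_check(all(abs_control != abs_blank),
           "abs_control must differ from abs_blank",
           "quenchfit_domain_error")
  100 * (abs_sample - abs_blank) / (abs_control - abs_blank)
}
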