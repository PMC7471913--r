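.REPORT_SCHEMA_VERSION <- "1.0"

#' Serialize pipeline results to a JSON report
#'
#' Writes a structured JSON document with sections `quenching`,
#' `binding`, `cooperativity`, `thermodynamics` and `flags`, plus a
#' `schema_version` field.  All numeric values are in SI units (mol/L,
#' L/mol, J/mol, K, seconds); a skipped thermodynamics stage is written
#' as `null` with its flag retained.
#'
#' @param results A [run_pipeline()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  qf_check(inherits(results, "pipeline_result"),
           "results must come from run_pipeline()")
  doc <- report_document(results)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) {
    qf_error(paste0("cannot write report to '", path, "': ",
                    conditionMessage(e)), "quenchfit_io_error")
  })
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return The report as nested lists/data frames.
#' @export
read_report <- function(path) {
  qf_check(file.exists(path), paste0("file not found: ", path),
           "quenchfit_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

## Assemble the plain-list report structure behind write_report().
report_document <- function(results) {
  sv <- results$quenching$fits
  mech <- results$quenching$mechanism
  quenching <- list(
    per_temperature = lapply(sv, function(f) list(
      temperature_K = f$temperature, ksv = f$ksv, intercept = f$intercept,
      r_squared = f$r_squared, kq = f$kq, tau = f$tau,
      n_points = f$n_points)),
    mechanism = mech$label,
    trend_slope = if (is.na(mech$trend_slope)) NULL else mech$trend_slope,
    kq_ceiling = mech$ceiling,
    exceeds_diffusion_limit = as.list(unname(mech$exceeds_diffusion_limit)))
  binding <- lapply(results$binding, function(f) list(
    temperature_K = f$temperature, assoc_k = f$assoc_k,
    n_sites = f$n_sites, r_squared = f$r_squared,
    n_points_used = f$n_points_used,
    dropped_points = as.list(f$dropped_points)))
  cooperativity <- lapply(results$cooperativity, function(f) list(
    temperature_K = f$temperature, hill_n = f$hill_n, k_d = f$k_d,
    label = f$cooperativity, tol = f$coop_tol))
  thermo <- results$thermodynamics
  thermodynamics <- if (is.null(thermo)) NULL else list(
    per_temperature = lapply(seq_len(nrow(thermo$per_temperature)),
      function(i) {
        pt <- thermo$per_temperature[i, ]
        list(temperature_K = pt$temperature, assoc_k = pt$assoc_k,
             delta_g = pt$delta_g, delta_g_vant_hoff = pt$delta_g_vant_hoff,
             spontaneous = pt$spontaneous)
      }),
    delta_h = thermo$delta_h,
    delta_s = thermo$delta_s,
    force_label = thermo$force_label,
    r_squared_vant_hoff = thermo$r_squared_vant_hoff,
    source_constant = results$config$vant_hoff_source)
  list(schema_version = .REPORT_SCHEMA_VERSION,
       quenching = quenching,
       binding = binding,
       cooperativity = cooperativity,
       thermodynamics = thermodynamics,
       flags = as.list(results$flags))
}
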