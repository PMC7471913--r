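#' Construct a single-temperature titration series
#'
#' A `titration_series` holds one temperature's fluorescence quenching
#' titration: an ordered quencher concentration grid, the measured
#' fluorescence intensities, and the reference intensity `f0` measured
#' without quencher.  Concentrations are always stored in mol/L; unit
#' conversion happens once, at file-reading time ([read_titration_csv()]).
#'
#' @param temperature Absolute temperature in K (scalar, > 0).
#' @param quencher_conc Quencher (nanoparticle) concentrations in mol/L;
#'   non-negative, no duplicates.  Points are stored sorted by
#'   concentration.
#' @param intensity Fluorescence intensities (arbitrary units, > 0),
#'   aligned with `quencher_conc`.
#' @param f0 Reference intensity at zero quencher (> 0).
#' @param protein_conc Optional protein concentration in mol/L.
#' @param label Optional free-text sample identifier.
#' @return An object of class `titration_series`.
#' @examples
#' s <- titration_series(298.15, c(8, 16, 32, 64, 96, 128) * 1e-6,
#'                       c(930, 870, 770, 630, 540, 470), f0 = 1000)
#' s
#' @export
titration_series <- function(temperature, quencher_conc, intensity, f0,
                             protein_conc = NULL, label = NULL) {
  qf_check(is.numeric(temperature) && length(temperature) == 1 &&
             is.finite(temperature) && temperature > 0,
           "temperature must be a single positive number (K)")
  qf_check(is.numeric(quencher_conc) && all(is.finite(quencher_conc)) &&
             all(quencher_conc >= 0),
           "quencher_conc must be non-negative and finite (mol/L)")
  qf_check(length(quencher_conc) == length(intensity),
           "quencher_conc and intensity must have equal length")
  qf_check(is.numeric(intensity) && all(is.finite(intensity)) &&
             all(intensity > 0),
           "all intensities must be positive and finite")
  qf_check(is.numeric(f0) && length(f0) == 1 && is.finite(f0) && f0 > 0,
           "f0 must be a single positive number")
  qf_check(anyDuplicated(quencher_conc) == 0,
           "quencher_conc must be strictly increasing after sorting (no duplicates)")
  ord <- order(quencher_conc)
  structure(
    list(temperature = as.numeric(temperature),
         quencher_conc = as.numeric(quencher_conc[ord]),
         intensity = as.numeric(intensity[ord]),
         f0 = as.numeric(f0),
         protein_conc = protein_conc,
         label = label),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s: T = %.2f K, F0 = %g, %d points, [Q] %g-%g mol/L\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$temperature, x$f0, length(x$quencher_conc),
              min(x$quencher_conc), max(x$quencher_conc)))
  invisible(x)
}

#' Construct a multi-temperature titration set
#'
#' @param series A list of [titration_series()] objects at pairwise
#'   distinct temperatures (at least one).
#' @param metadata Optional free-text instrument/excitation notes.
#' @return An object of class `titration_set`.
#' @export
titration_set <- function(series, metadata = NULL) {
  if (inherits(series, "titration_series")) series <- list(series)
  qf_check(is.list(series) && length(series) >= 1 &&
             all(vapply(series, inherits, logical(1), "titration_series")),
           "series must be a non-empty list of titration_series objects")
  temps <- vapply(series, `[[`, numeric(1), "temperature")
  qf_check(anyDuplicated(temps) == 0,
           "all series temperatures must be distinct")
  series <- series[order(temps)]
  structure(list(series = series, metadata = metadata),
            class = "titration_set")
}

#' @export
print.titration_set <- function(x, ...) {
  cat(sprintf("Titration set: %d temperature(s)\n", length(x$series)))
  for (s in x$series) print(s)
  invisible(x)
}

.conc_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Read a titration CSV file
#'
#' The file must carry columns `temperature_K`, `quencher_conc` and
#' `intensity`, with an optional `f0` column; rows may appear in any
#' order.  Rows are grouped by temperature into one series each.  A row
#' with `quencher_conc == 0` is consumed as that temperature's `f0`; an
#' explicit `f0` column overrides it, and the two disagreeing by more than
#' 0.1% (relative) is an error.
#'
#' @param path Path to a CSV file.
#' @param conc_unit Unit of the `quencher_conc` column: one of `"M"`,
#'   `"mM"`, `"uM"`, `"nM"`.  Concentrations are converted to mol/L on
#'   input.
#' @return A [titration_set()].
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' write.csv(data.frame(temperature_K = 298.15,
#'                      quencher_conc = c(0, 8, 16, 32, 64, 128),
#'                      intensity = c(1000, 930, 870, 770, 630, 470)),
#'           csv, row.names = FALSE)
#' read_titration_csv(csv, conc_unit = "uM")
#' @export
read_titration_csv <- function(path, conc_unit = c("M", "mM", "uM", "nM")) {
  conc_unit <- match.arg(conc_unit)
  qf_check(file.exists(path), paste0("file not found: ", path),
           "quenchfit_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("temperature_K", "quencher_conc", "intensity")) {
    if (!col %in% names(df)) {
      qf_error(paste0("missing column: ", col), "quenchfit_format_error")
    }
  }
  bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
  if (length(bad) > 0) {
    qf_error(paste0("non-positive intensity at row ", bad[1],
                    " of ", path), "quenchfit_validation_error")
  }
  df$quencher_conc <- df$quencher_conc * .conc_factors[[conc_unit]]
  series <- lapply(split(df, df$temperature_K), function(block) {
    zero <- block$quencher_conc == 0
    f0_col <- if ("f0" %in% names(block)) block$f0[is.finite(block$f0)] else numeric(0)
    f0_row <- if (any(zero)) block$intensity[zero][1] else NULL
    f0 <- NULL
    if (length(f0_col) > 0) {
      qf_check(length(unique(f0_col)) == 1,
               "f0 column must be constant within a temperature block")
      f0 <- f0_col[1]
      if (!is.null(f0_row) && abs(f0 - f0_row) > 1e-3 * abs(f0_row)) {
        qf_error(sprintf(
          "f0 column (%g) disagrees with zero-concentration intensity (%g) at %g K",
          f0, f0_row, block$temperature_K[1]), "quenchfit_validation_error")
      }
    } else if (!is.null(f0_row)) {
      f0 <- f0_row
    }
    if (is.null(f0)) {
      qf_error(sprintf(
        "no f0 for temperature %g K: add a zero-concentration row or an f0 column",
        block$temperature_K[1]), "quenchfit_validation_error")
    }
    keep <- !zero
    titration_series(block$temperature_K[1],
                     block$quencher_conc[keep],
                     block$intensity[keep],
                     f0 = f0)
  })
  titration_set(unname(series))
}

#' Write a titration set to CSV
#'
#' Inverse of [read_titration_csv()]: emits `temperature_K`,
#' `quencher_conc` (in the requested unit) and `intensity` columns, with
#' one zero-concentration row per series carrying `f0`.
#'
#' @param ts A [titration_set()] or single [titration_series()].
#' @param path Output file path.
#' @param conc_unit Unit for the written `quencher_conc` column.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(ts, path, conc_unit = c("M", "mM", "uM", "nM")) {
  conc_unit <- match.arg(conc_unit)
  if (inherits(ts, "titration_series")) ts <- titration_set(list(ts))
  rows <- do.call(rbind, lapply(ts$series, function(s) {
    data.frame(temperature_K = s$temperature,
               quencher_conc = c(0, s$quencher_conc) / .conc_factors[[conc_unit]],
               intensity = c(s$f0, s$intensity))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a titration set, returning warnings
#'
#' Non-fatal data-quality checks: points whose intensity is at or above
#' `f0` at nonzero quencher concentration (unusable in the logarithmic
#' transforms), series with fewer than 3 points, and sets with fewer than
#' 2 temperatures (no van't Hoff analysis possible).  Problems are
#' returned as a character vector of warnings, never raised.
#'
#' @param ts A [titration_set()].
#' @return Character vector of warning messages (empty if clean).
#' @export
validate_set <- function(ts) {
  qf_check(inherits(ts, "titration_set"), "ts must be a titration_set")
  warnings <- character(0)
  for (s in ts$series) {
    high <- which(s$intensity >= s$f0 & s$quencher_conc > 0)
    for (i in high) {
      warnings <- c(warnings, sprintf(
        "T = %g K: intensity %g >= F0 = %g at [Q] = %g mol/L; point unusable in log transforms",
        s$temperature, s$intensity[i], s$f0, s$quencher_conc[i]))
    }
    if (length(s$quencher_conc) < 3) {
      warnings <- c(warnings, sprintf(
        "T = %g K: fewer than 3 titration points (%d)",
        s$temperature, length(s$quencher_conc)))
    }
  }
  if (length(ts$series) < 2) {
    warnings <- c(warnings,
                  "fewer than 2 temperatures: van't Hoff analysis unavailable")
  }
  warnings
}
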