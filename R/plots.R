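#' Diagnostic plots for a pipeline result
#'
#' Base-graphics versions of the four classical plots: Stern--Volmer
#' (`F0/F` vs `[Q]`), double-log binding, Hill, and van't Hoff
#' (`ln K` vs `1/T`), each with its fitted line.
#'
#' @param ts The [titration_set()] that was analysed.
#' @param results The matching [run_pipeline()] result.
#' @param which Subset of `c("stern_volmer", "double_log", "hill",
#'   "vant_hoff")`.
#' @return `NULL`, invisibly; called for the plots.
#' @export
plot_pipeline <- function(ts, results,
                          which = c("stern_volmer", "double_log",
                                    "hill", "vant_hoff")) {
  which <- match.arg(which, several.ok = TRUE)
  if ("stern_volmer" %in% which) plot_stern_volmer(ts, results$quenching$fits)
  if ("double_log" %in% which) plot_double_log(ts, results$binding)
  if ("hill" %in% which) plot_hill(ts, results$cooperativity)
  if ("vant_hoff" %in% which && !is.null(results$thermodynamics)) {
    plot_vant_hoff(results$thermodynamics)
  }
  invisible(NULL)
}

.series_palette <- function(n) grDevices::hcl.colors(max(n, 2), "Dark 2")[seq_len(n)]

plot_stern_volmer <- function(ts, fits) {
  cols <- .series_palette(length(ts$series))
  xs <- lapply(ts$series, `[[`, "quencher_conc")
  ys <- mapply(function(s) s$f0 / s$intensity, ts$series, SIMPLIFY = FALSE)
  plot(NA, xlim = range(unlist(xs)), ylim = range(unlist(ys), 1),
       xlab = "[Q] (mol/L)", ylab = expression(F[0] / F),
       main = "Stern-Volmer plot")
  for (i in seq_along(ts$series)) {
    graphics::points(xs[[i]], ys[[i]], col = cols[i], pch = 16)
    graphics::abline(fits[[i]]$intercept, fits[[i]]$ksv, col = cols[i])
  }
  .temp_legend(ts, cols)
}

plot_double_log <- function(ts, fits) {
  cols <- .series_palette(length(ts$series))
  pts <- lapply(ts$series, function(s) {
    ok <- s$quencher_conc > 0 & s$intensity < s$f0
    list(x = log10(s$quencher_conc[ok]),
         y = log10((s$f0 - s$intensity[ok]) / s$intensity[ok]))
  })
  plot(NA, xlim = range(unlist(lapply(pts, `[[`, "x"))),
       ylim = range(unlist(lapply(pts, `[[`, "y"))),
       xlab = expression(log[10] * "[Q]"),
       ylab = expression(log[10] * ((F[0] - F) / F)),
       main = "Double-log binding plot")
  for (i in seq_along(ts$series)) {
    graphics::points(pts[[i]]$x, pts[[i]]$y, col = cols[i], pch = 16)
    graphics::abline(log10(fits[[i]]$assoc_k), fits[[i]]$n_sites,
                     col = cols[i])
  }
  .temp_legend(ts, cols)
}

plot_hill <- function(ts, fits) {
  cols <- .series_palette(length(ts$series))
  pts <- lapply(ts$series, function(s) {
    ok <- s$quencher_conc > 0 & s$intensity < s$f0
    list(x = log(s$quencher_conc[ok]),
         y = log((s$f0 - s$intensity[ok]) / s$intensity[ok]))
  })
  plot(NA, xlim = range(unlist(lapply(pts, `[[`, "x"))),
       ylim = range(unlist(lapply(pts, `[[`, "y"))),
       xlab = "ln [Q]", ylab = expression(ln((F[0] - F) / F)),
       main = "Hill plot")
  for (i in seq_along(ts$series)) {
    graphics::points(pts[[i]]$x, pts[[i]]$y, col = cols[i], pch = 16)
    graphics::abline(-fits[[i]]$hill_n * log(fits[[i]]$k_d),
                     fits[[i]]$hill_n, col = cols[i])
  }
  .temp_legend(ts, cols)
}

plot_vant_hoff <- function(thermo) {
  pt <- thermo$per_temperature
  x <- 1 / pt$temperature
  y <- log(pt$assoc_k)
  plot(x, y, pch = 16, xlab = "1/T (1/K)", ylab = "ln K",
       main = "van't Hoff plot")
  graphics::abline(thermo$delta_s / .R_GAS, -thermo$delta_h / .R_GAS)
}

.temp_legend <- function(ts, cols) {
  graphics::legend("topleft", bty = "n", col = cols, pch = 16,
                   legend = sprintf("%.2f K",
                                    vapply(ts$series, `[[`, numeric(1),
                                           "temperature")))
}
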