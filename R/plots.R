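#' Plot buildup curves
#'
#' Transfer efficiency versus mixing time for each destination spin
#' (ggplot2, one line per spin), mirroring the usual presentation of
#' simulated buildups.
#'
#' @param curve A `buildup_curve`, or a named list of them (one panel
#'   facet per element).
#' @return A ggplot object.
#' @export
plot_buildup <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_buildup() requires the 'ggplot2' package")
  curves <- if (inherits(curve, "buildup_curve")) list(curve = curve) else curve
  tab <- do.call(rbind, lapply(names(curves), function(nm) {
    cu <- curves[[nm]]
    do.call(rbind, lapply(colnames(cu$efficiency), function(d)
      data.frame(scheme = nm, tau_ms = cu$times * 1e3, spin = d,
                 efficiency = cu$efficiency[, d])))
  }))
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[["tau_ms"]],
                                          y = .data[["efficiency"]],
                                          colour = .data[["spin"]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mixing time (ms)", y = "transfer efficiency") +
    ggplot2::theme_minimal()
  if (length(curves) > 1L)
    gg <- gg + ggplot2::facet_wrap(~scheme)
  gg
}

#' Plot a scan result
#'
#' Optimal transfer efficiency versus the scanned variable (MAS frequency,
#' static field, B1 scale or offset difference).
#'
#' @param scan A `scan_result`.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan() requires the 'ggplot2' package")
  tab <- as.data.frame(scan)
  xcol <- names(tab)[1]
  ycol <- if ("eff_opt" %in% names(tab)) "eff_opt" else "eff"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = paste0(attr(scan, "variable"), " (",
                             attr(scan, "units"), ")"),
                  y = "optimal transfer efficiency") +
    ggplot2::theme_minimal()
}
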