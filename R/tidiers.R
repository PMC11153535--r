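#' Tidiers and plot methods
#'
#' broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods for the
#' package's result types: waveforms, A-lines, scans, flush fields and
#' comparisons.
#'
#' @param x,object A package result object.
#' @param ... Unused.
#' @name ivoct-tidiers
NULL

#' @rdname ivoct-tidiers
#' @method tidy ivoct_scan
#' @export
tidy.ivoct_scan <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname ivoct-tidiers
#' @method glance ivoct_scan
#' @export
glance.ivoct_scan <- function(x, ...) {
  g <- scan_gamma(x,
    f1 = attr(x, "protocol")$f1 %||% 0.7,
    f2 = attr(x, "protocol")$f2 %||% 0.3)
  dplyr::mutate(g, cil_mm = cil(x), n_frames = nrow(x),
    cif_fraction = mean(x$cif))
}

#' @rdname ivoct-tidiers
#' @method tidy ivoct_comparison
#' @export
tidy.ivoct_comparison <- function(x, ...) x$summaries

#' @rdname ivoct-tidiers
#' @method glance ivoct_comparison
#' @export
glance.ivoct_comparison <- function(x, ...) {
  tibble(
    dosage_reduction_pct = x$dosage_reduction_pct,
    quality_reduction_pct = x$quality_reduction_pct,
    gamma_continuous = x$summaries$gamma[1],
    gamma_intermittent = x$summaries$gamma[2],
    cil_continuous_mm = x$summaries$cil_mm[1],
    cil_intermittent_mm = x$summaries$cil_mm[2]
  )
}

#' @rdname ivoct-tidiers
#' @method tidy ivoct_flush
#' @export
tidy.ivoct_flush <- function(x, ...) {
  nt <- length(x$times)
  tidyr::expand_grid(
    time = x$times,
    z = x$grid$z_c_mm,
    r = x$grid$r_c_mm
  ) |>
    dplyr::mutate(w_e = as.vector(x$w)) |>
    dplyr::mutate(haematocrit = haematocrit_from_mass_fraction(
      pmin(pmax(.data$w_e, 0), 1), x$rho_e, x$saline_density))
}

#' @rdname ivoct-tidiers
#' @method autoplot ivoct_waveform
#' @export
autoplot.ivoct_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$flow)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "flow rate (mL/s)",
      title = attr(object, "kind"))
}

#' @rdname ivoct-tidiers
#' @method autoplot ivoct_aline
#' @export
autoplot.ivoct_aline <- function(object, ...) {
  df <- tidyr::pivot_longer(object[, c("r", "M", "G")], -"r")
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "r (mm)", y = NULL)
}

#' @rdname ivoct-tidiers
#' @method autoplot ivoct_scan
#' @export
autoplot.ivoct_scan <- function(object, ...) {
  thr <- attr(object, "protocol")$cif_threshold %||% 0.75
  ggplot2::ggplot(object, ggplot2::aes(.data$lens_z, .data$m_w,
      colour = .data$cif)) +
    ggplot2::geom_point(shape = 17) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
      `FALSE` = "firebrick"), name = "CIF") +
    ggplot2::labs(x = "lens position z (mm)", y = expression(M[w])) +
    ggplot2::ylim(0, 1)
}

#' @rdname ivoct-tidiers
#' @method autoplot ivoct_comparison
#' @export
autoplot.ivoct_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(object$scans, tidy), .id = "scheme")
  thr <- attr(object$scans[[1]], "protocol")$cif_threshold %||% 0.75
  ggplot2::ggplot(df, ggplot2::aes(.data$lens_z, .data$m_w,
      colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "lens position z (mm)", y = expression(M[w])) +
    ggplot2::ylim(0, 1)
}
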