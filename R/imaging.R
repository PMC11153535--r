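#' Render a cross-sectional OCT image from one A-line
#'
#' Rotates the radial grayscale profile about the catheter axis onto a
#' square raster covering 10 x 10 mm centred on the axis: each pixel takes
#' the `G` value of the nearest radial sample at its distance from the
#' centre (nearest-sample lookup for bit-exact reproducibility). Pixels
#' beyond 5 mm, and inside the OCT catheter, are black.
#'
#' @param aline An [propagate()] result.
#' @param size Image side (pixels).
#' @param extent_mm Physical half-extent (mm).
#' @param interpolate Use linear interpolation instead of nearest-sample.
#' @return An integer matrix of class `ivoct_image` (values 0..255).
#' @export
render_cross_section <- function(aline, size = 512, extent_mm = 5,
                                 interpolate = FALSE) {
  if (size < 2) {
    abort("domain error: size must be at least 2", class = "ivoct_domain_error")
  }
  px <- (seq_len(size) - (size + 1) / 2) * (2 * extent_mm / size)
  rad <- sqrt(outer(px^2, px^2, `+`))
  g <- if (interpolate) {
    approx(aline$r, aline$G, xout = rad, rule = 2)$y
  } else {
    idx <- findInterval(rad, aline$r + c(diff(aline$r) / 2, Inf))
    aline$G[pmin(idx + 1L, length(aline$r))]
  }
  g <- matrix(as.integer(round(g)), size, size)
  g[rad < min(aline$r)] <- 0L # inside the OCT catheter
  g[rad > extent_mm] <- 0L
  structure(g, class = "ivoct_image")
}

#' Stack A-lines into a longitudinal image
#'
#' One column per frame (ordered by lens position along +z), mirrored about
#' the axis row, giving the axial cut through the pulled-back 3D image
#' stack.
#'
#' @param alines A list of [propagate()] results on a common radial grid.
#' @param z Optional lens positions (mm) used to order the columns.
#' @return An integer matrix of class `ivoct_image` with `2 * n_radial - 1`
#'   rows and one column per frame.
#' @export
stack_longitudinal <- function(alines, z = NULL) {
  if (!length(alines)) {
    abort("input error: need at least one frame", class = "ivoct_domain_error")
  }
  r0 <- alines[[1]]$r
  same <- vapply(alines, function(a) {
    length(a$r) == length(r0) && max(abs(a$r - r0)) < 1e-12
  }, logical(1))
  if (!all(same)) {
    abort("input error: frames must share one radial grid",
      class = "ivoct_domain_error")
  }
  if (!is.null(z)) alines <- alines[order(z)]
  cols <- vapply(alines, function(a) c(rev(a$G), a$G[-1]), numeric(2 * length(r0) - 1))
  structure(matrix(as.integer(cols), nrow = 2 * length(r0) - 1),
    class = "ivoct_image")
}

#' Write / read an 8-bit grayscale image
#'
#' PNG or TIFF, selected from the file extension or the `format` argument;
#' round-trips bit-exactly.
#'
#' @param image An `ivoct_image` (integer matrix, 0..255).
#' @param path Output path.
#' @param format `"png"`, `"tiff"`, or `NULL` to infer from the extension.
#' @return `path` invisibly (write); an `ivoct_image` (read).
#' @export
write_image <- function(image, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  m <- unclass(image) / 255
  storage.mode(m) <- "double"
  switch(format,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    abort(sprintf("format error: unsupported image format '%s'", format),
      class = "ivoct_domain_error")
  )
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  m <- switch(format,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("format error: unsupported image format '%s'", format),
      class = "ivoct_domain_error")
  )
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
    class = "ivoct_image")
}

#' @export
print.ivoct_image <- function(x, ...) {
  cat(sprintf("<ivoct_image %d x %d, grayscale 0..255>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @method autoplot ivoct_image
#' @export
autoplot.ivoct_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    col = seq_len(ncol(object)), row = seq_len(nrow(object))
  )
  df$value <- as.vector(unclass(object)) # column-major: row varies fastest
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
      limits = c(0, 255), name = "G") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
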