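#' 2D image container
#'
#' A 2D CT slice (or attenuation map) stored as a numeric matrix with pixel
#' spacing and a unit tag. Row 1 is the top image row and the image center
#' lies at the scanner isocenter. The unit tag is `"HU"` for Hounsfield
#' units, `"1/cm"` for linear attenuation, or an arbitrary label for other
#' gridded quantities (e.g. activity); every operation in the package
#' propagates it.
#'
#' @param values numeric matrix (finite values only).
#' @param spacing pixel spacing in mm.
#' @param unit unit tag, default `"HU"`.
#' @return An `image2d` object.
#' @export
image2d <- function(values, spacing = 1.5, unit = "HU") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("image2d: values must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("image2d: spacing must be a positive scalar (mm)")
  structure(list(values = values, spacing = spacing, unit = unit),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %dx%d, %.3g mm/px, unit=%s, range [%.4g, %.4g]>\n",
              nrow(x$values), ncol(x$values), x$spacing, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$values)

stop_if_unit <- function(img, expected, what) {
  if (!inherits(img, "image2d")) stop(what, ": expected an image2d")
  if (!identical(img$unit, expected))
    stop(sprintf("%s: expected unit \"%s\" but got \"%s\"%s", what, expected,
                 img$unit,
                 if (expected == "1/cm" && img$unit == "HU")
                   "; convert with hu_to_mu() first" else ""))
  invisible(img)
}

same_grid <- function(a, b, what) {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, ": images are on different grids (",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), ")")
  invisible(TRUE)
}

#' Equi-angular fan-beam geometry
#'
#' Describes the acquisition geometry: `n_views` source positions equally
#' spaced over 360 degrees and an equi-angular detector of `n_bins` bins
#' centered so the isocenter ray falls midway between the two middle bins.
#' The per-bin fan increment is chosen so the detector covers the
#' reconstruction field of view with a two-bin margin on each side.
#'
#' @param n_views number of projection angles over 360 degrees.
#' @param n_bins number of detector bins.
#' @param sad source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm); recorded for completeness.
#' @param fov diameter of the reconstruction field of view (mm).
#' @return A `fan_geometry` object.
#' @export
fan_geometry <- function(n_views = 1000L, n_bins = 920L, sad = 600,
                         sdd = 1100, fov = 500) {
  n_views <- as.integer(n_views); n_bins <- as.integer(n_bins)
  if (n_views < 2L || n_bins < 2L)
    stop("fan_geometry: n_views and n_bins must both be >= 2")
  if (fov >= 2 * sad) stop("fan_geometry: fov must be smaller than 2*sad")
  gamma_max <- asin((fov / 2) / sad)
  dgamma <- 2 * gamma_max / (n_bins - 4L) # ~2 overscan bins per side
  structure(list(n_views = n_views, n_bins = n_bins, sad = sad, sdd = sdd,
                 fov = fov, dgamma = dgamma,
                 gammas = (seq_len(n_bins) - 0.5 - n_bins / 2) * dgamma,
                 betas = 2 * pi * (seq_len(n_views) - 1L) / n_views),
            class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf("<fan_geometry %d views x %d bins, SAD %g mm, FOV %g mm>\n",
              x$n_views, x$n_bins, x$sad, x$fov))
  invisible(x)
}

#' Sinogram container
#'
#' Fan-beam projection data on an `n_views` x `n_bins` grid. `kind` is
#' `"line_integral"` for -log(I/I0) data (the default currency of the
#' pipeline) or `"intensity"` for relative photon counts.
#'
#' @param values numeric `n_views` x `n_bins` matrix.
#' @param geom the [fan_geometry()] the data were sampled on.
#' @param kind `"line_integral"` or `"intensity"`.
#' @return A `sinogram` object.
#' @export
sinogram <- function(values, geom, kind = "line_integral") {
  values <- as.matrix(values)
  if (!inherits(geom, "fan_geometry")) stop("sinogram: geom must be a fan_geometry")
  if (nrow(values) != geom$n_views || ncol(values) != geom$n_bins)
    stop(sprintf("sinogram: values are %dx%d but geometry is %d views x %d bins",
                 nrow(values), ncol(values), geom$n_views, geom$n_bins))
  kind <- match.arg(kind, c("line_integral", "intensity"))
  if (kind == "line_integral" && min(values) < -1e-9)
    warning("sinogram: negative line integrals beyond float tolerance")
  structure(list(values = values, geom = geom, kind = kind), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d views x %d bins, kind=%s, range [%.4g, %.4g]>\n",
              x$geom$n_views, x$geom$n_bins, x$kind,
              min(x$values), max(x$values)))
  invisible(x)
}

same_geometry <- function(sino, geom, what) {
  g <- sino$geom
  if (g$n_views != geom$n_views || g$n_bins != geom$n_bins ||
      g$sad != geom$sad || abs(g$dgamma - geom$dgamma) > 1e-12)
    stop(what, ": sinogram does not match the supplied geometry")
  invisible(TRUE)
}
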