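#' Monochromatic fan-beam forward projection
#'
#' Computes line integrals of a linear-attenuation image along every
#' source-to-bin ray of the equi-angular fan-beam geometry, using
#' interpolating (Joseph-style) ray tracing: one bilinear sample per
#' row/column crossing along the dominant ray axis. The operator is linear
#' in the image.
#'
#' @param mu_image an [image2d()] with unit `"1/cm"`.
#' @param geom a [fan_geometry()].
#' @return A [sinogram()] of kind `"line_integral"`.
#' @export
forward_project_mono <- function(mu_image, geom) {
  stop_if_unit(mu_image, "1/cm", "forward_project_mono")
  vals <- cpp_fan_forward(mu_image$values, mu_image$spacing,
                          geom$n_views, geom$n_bins, geom$sad, geom$dgamma)
  sinogram(vals, geom, "line_integral")
}

#' Dense ray-march reference projector
#'
#' A deliberately simple, slow reference implementation of the fan-beam
#' line integral: each ray is sampled at a fixed small step (default
#' 0.25 mm) with bilinear interpolation and the samples are summed. It
#' shares no code with [forward_project_mono()] and exists to validate it.
#'
#' @inheritParams forward_project_mono
#' @param step sampling step along the ray in mm.
#' @return A [sinogram()] of kind `"line_integral"`.
#' @export
forward_project_ref <- function(mu_image, geom, step = 0.25) {
  stop_if_unit(mu_image, "1/cm", "forward_project_ref")
  img <- mu_image$values
  H <- nrow(img); W <- ncol(img); s <- mu_image$spacing
  reach <- sqrt(sum((c(H, W) * s / 2)^2)) + 2 * s
  tvals <- seq(geom$sad - reach, geom$sad + reach, by = step)
  out <- matrix(0, geom$n_views, geom$n_bins)
  for (v in seq_len(geom$n_views)) {
    beta <- geom$betas[v]
    sx <- geom$sad * cos(beta); sy <- geom$sad * sin(beta)
    phi <- beta + pi + geom$gammas
    px <- sx + outer(cos(phi), tvals)
    py <- sy + outer(sin(phi), tvals)
    cc <- px / s + (W - 1) / 2 + 1
    rr <- (H - 1) / 2 - py / s + 1
    j0 <- floor(cc); i0 <- floor(rr)
    fj <- cc - j0; fi <- rr - i0
    acc <- matrix(0, geom$n_bins, length(tvals))
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      w <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      idx <- ii[ok] + (jj[ok] - 1) * H
      a <- acc[ok]
      acc[ok] <- a + w[ok] * img[idx]
    }
    out[v, ] <- rowSums(acc) * step * 0.1
  }
  sinogram(out, geom, "line_integral")
}

#' Polychromatic fan-beam forward projection
#'
#' Simulates a polychromatic acquisition: each material density map is
#' projected with the monochromatic projector to obtain per-ray area
#' densities (g/cm^2), then Beer-Lambert attenuation is summed over the
#' spectrum, `I/I0 = sum_E w(E) exp(-sum_m (mu/rho)_m(E) t_m)`, and
#' converted back to a line integral `-log(I/I0)`. With a single-energy
#' spectrum this reduces exactly to the monochromatic projection at that
#' energy. Rays whose transmitted fraction falls below `floor` are clamped
#' (photon starvation); the affected ray count is attached as attribute
#' `"n_starved"`.
#'
#' @param material_maps named list of density matrices (g/cm^3 per pixel),
#'   one per material label present in `table`; all on the same grid.
#' @param spectrum a [spectrum_120kvp()] style object.
#' @param table a [material_table()].
#' @param geom a [fan_geometry()].
#' @param spacing pixel spacing of the maps in mm.
#' @param floor transmitted-fraction clamp, default 1e-12.
#' @return A [sinogram()] of kind `"line_integral"`.
#' @export
forward_project_poly <- function(material_maps, spectrum, table, geom,
                                 spacing = 1.5, floor = 1e-12) {
  if (length(material_maps) == 0)
    return(sinogram(matrix(0, geom$n_views, geom$n_bins), geom, "line_integral"))
  unknown <- setdiff(names(material_maps), names(table$materials))
  if (length(unknown))
    stop("forward_project_poly: unknown material(s): ", paste(unknown, collapse = ", "))
  paths <- lapply(material_maps, function(m)
    cpp_fan_forward(as.matrix(m), spacing, geom$n_views, geom$n_bins,
                    geom$sad, geom$dgamma))
  frac <- matrix(0, geom$n_views, geom$n_bins)
  for (k in seq_along(spectrum$energies)) {
    E <- spectrum$energies[k]
    expo <- matrix(0, geom$n_views, geom$n_bins)
    for (m in names(paths)) {
      mor <- attenuation_lookup(table, m, E) / table$materials[[m]]$density
      expo <- expo + mor * paths[[m]]
    }
    frac <- frac + spectrum$weights[k] * exp(-expo)
  }
  n_starved <- sum(frac < floor)
  frac <- pmax(frac, floor)
  out <- sinogram(-log(frac), geom, "line_integral")
  attr(out, "n_starved") <- n_starved
  out
}

#' Poisson counting noise on a sinogram
#'
#' Converts line integrals to expected photon counts `N0 exp(-p)`, draws
#' Poisson counts, and converts back with `-log(max(count, 1)/N0)`. The
#' caller's RNG state is preserved; the draw is fully determined by `seed`.
#'
#' @param sino a line-integral [sinogram()].
#' @param n0 incident photons per bin (> 0).
#' @param seed integer seed.
#' @return A noisy [sinogram()].
#' @export
add_poisson_noise <- function(sino, n0, seed = 1L) {
  if (!is.numeric(n0) || n0 <= 0) stop("add_poisson_noise: n0 must be > 0")
  if (sino$kind != "line_integral") stop("add_poisson_noise: need line integrals")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lambda <- n0 * exp(-sino$values)
  counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  sinogram(-log(pmax(counts, 1) / n0), sino$geom, "line_integral")
}

# equi-angular ramp filter kernel (discretized), optionally Hann-apodized,
# returned as its DFT of length nfft
fan_filter_fft <- function(n_bins, dgamma, nfft, filter = c("hann", "ramp")) {
  filter <- match.arg(filter)
  g <- numeric(nfft)
  g[1] <- 1 / (8 * dgamma^2)
  k <- seq_len(n_bins - 1)
  vals <- ifelse(k %% 2 == 1, -0.5 / (pi * sin(k * dgamma))^2, 0)
  g[1 + k] <- vals
  g[nfft + 1 - k] <- vals
  G <- stats::fft(g)
  if (filter == "hann") {
    fidx <- pmin(0:(nfft - 1), nfft - (0:(nfft - 1)))
    G <- G * 0.5 * (1 + cos(pi * fidx / (nfft / 2)))
  }
  G
}

#' Filtered backprojection (equi-angular fan beam)
#'
#' Standard full-scan equi-angular FBP: cosine pre-weighting of each
#' projection, row-wise convolution with the equi-angular ramp kernel
#' (Hann-apodized by default, pure ramp selectable), then
#' inverse-square-weighted backprojection. A linear operator.
#'
#' @param sino a line-integral [sinogram()].
#' @param grid_size output grid in pixels (scalar or c(H, W)).
#' @param spacing output pixel spacing in mm.
#' @param filter `"hann"` (default) or `"ramp"`.
#' @return An [image2d()] with unit `"1/cm"`.
#' @export
fbp <- function(sino, grid_size = 256L, spacing = 1.5,
                filter = c("hann", "ramp")) {
  if (!inherits(sino, "sinogram")) stop("fbp: expected a sinogram")
  if (sino$kind != "line_integral") stop("fbp: need line-integral data")
  filter <- match.arg(filter)
  geom <- sino$geom
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  n <- geom$n_bins
  nfft <- 2^ceiling(log2(2 * n))
  G <- fan_filter_fft(n, geom$dgamma, nfft, filter)
  sad_cm <- geom$sad / 10
  w <- sad_cm * cos(geom$gammas)
  pw <- sweep(sino$values, 2, w, `*`)
  padded <- matrix(0, geom$n_views, nfft)
  padded[, seq_len(n)] <- pw
  Q <- t(stats::mvfft(t(padded)))
  q <- Re(t(stats::mvfft(t(Q * rep(1, geom$n_views) %o% G), inverse = TRUE))) / nfft
  q <- q[, seq_len(n), drop = FALSE] * geom$dgamma
  img <- cpp_fan_backproject(q, spacing, grid_size[1], grid_size[2],
                             geom$sad, geom$dgamma)
  image2d(img, spacing = spacing, unit = "1/cm")
}

#' Convert HU to linear attenuation and back
#'
#' Below 100 HU the standard water scaling is used,
#' `mu = mu_water(E) (1 + HU/1000)`, floored at zero; above 100 HU the
#' slope steepens linearly toward the tabulated bone attenuation at
#' 1500 HU (and continues with the same slope beyond), reflecting the
#' higher effective atomic number of mineralized tissue and metal.
#' `mu_to_hu()` inverts the mapping exactly (the sub-100 branch is the
#' exact algebraic inverse); attenuations of zero map to -1000 HU.
#'
#' @param img an [image2d()] in HU (for `hu_to_mu`) or 1/cm (for `mu_to_hu`).
#' @param energy reference energy in keV.
#' @param table a [material_table()].
#' @return The converted [image2d()].
#' @export
hu_to_mu <- function(img, energy = 70, table = material_table()) {
  stop_if_unit(img, "HU", "hu_to_mu")
  p <- hu_mu_params(table, energy)
  hu <- img$values
  mu <- ifelse(hu <= 100, pmax(p$mu_w * (1 + hu / 1000), 0),
               p$mu100 + (hu - 100) * p$slope)
  image2d(mu, spacing = img$spacing, unit = "1/cm")
}

#' @rdname hu_to_mu
#' @export
mu_to_hu <- function(img, energy = 70, table = material_table()) {
  stop_if_unit(img, "1/cm", "mu_to_hu")
  p <- hu_mu_params(table, energy)
  mu <- img$values
  hu <- ifelse(mu <= p$mu100, pmax(1000 * (mu / p$mu_w - 1), -1000),
               100 + (mu - p$mu100) / p$slope)
  image2d(hu, spacing = img$spacing, unit = "HU")
}

hu_mu_params <- function(table, energy) {
  mu_w <- attenuation_lookup(table, "soft_tissue", energy)
  mu_b <- attenuation_lookup(table, "bone", energy)
  mu100 <- mu_w * 1.1
  list(mu_w = mu_w, mu100 = mu100, slope = (mu_b - mu100) / (1500 - 100))
}
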