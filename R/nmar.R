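#' Segment metal from a CT image
#'
#' Thresholds the image at `threshold` HU and removes connected components
#' smaller than `min_pixels` (8-connectivity).
#'
#' @param img an [image2d()] in HU.
#' @param threshold metal threshold in HU (default 2500).
#' @param min_pixels smallest component kept (default 3).
#' @return A logical `metal_mask` matrix with attribute
#'   `source_threshold`. Raises a `no_metal_found` error when the mask is
#'   empty.
#' @export
segment_metal <- function(img, threshold = 2500, min_pixels = 3L) {
  stop_if_unit(img, "HU", "segment_metal")
  mask <- img$values > threshold
  if (any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_pixels)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask))
    stop(structure(class = c("no_metal_found", "error", "condition"),
                   list(message = sprintf(
                     "segment_metal: no metal above %g HU (image max %.0f HU)",
                     threshold, max(img$values)), call = sys.call(-1))))
  attr(mask, "source_threshold") <- threshold
  mask
}

# 8-connected component labelling (two-pass union-find on a binary matrix)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1 && lab[i - 1, j] > 0) nb <- c(nb, lab[i - 1, j])
    if (j > 1) {
      if (lab[i, j - 1] > 0) nb <- c(nb, lab[i, j - 1])
      if (i > 1 && lab[i - 1, j - 1] > 0) nb <- c(nb, lab[i - 1, j - 1])
      if (i < H && lab[i + 1, j - 1] > 0) nb <- c(nb, lab[i + 1, j - 1])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else {
      roots <- unique(vapply(nb, find, 1L))
      r <- min(roots)
      lab[i, j] <- r
      for (x in roots) parent[x] <- r
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 1L)
  relabel <- match(roots, sort(unique(roots)))
  idx <- lab > 0
  lab[idx] <- relabel[lab[idx]]
  lab
}

#' Metal trace in projection space
#'
#' Forward-projects the metal mask and marks every sinogram bin whose line
#' integral through the mask exceeds a small positive threshold, then
#' dilates the trace along the detector axis by `dilation_bins`.
#'
#' @param mask logical metal mask.
#' @param geom a [fan_geometry()].
#' @param spacing pixel spacing in mm.
#' @param dilation_bins dilation radius along bins (default 1).
#' @param threshold positive threshold on the mask line integral (in cm of
#'   unit-attenuation material).
#' @return Logical `n_views` x `n_bins` trace matrix.
#' @export
metal_trace <- function(mask, geom, spacing = 1.5, dilation_bins = 1L,
                        threshold = 1e-3) {
  if (!any(mask)) stop("metal_trace: empty metal mask")
  tr <- metal_trace_raw(mask, geom, spacing, dilation_bins, threshold)
  tr
}

metal_trace_raw <- function(mask, geom, spacing, dilation_bins = 1L,
                            threshold = 1e-3) {
  proj <- cpp_fan_forward(mask * 1.0, spacing, geom$n_views, geom$n_bins,
                          geom$sad, geom$dgamma)
  tr <- proj > threshold
  if (dilation_bins > 0L && any(tr)) {
    d <- tr
    for (k in seq_len(dilation_bins)) {
      d[, -1] <- d[, -1] | tr[, -ncol(tr)]
      d[, -ncol(d)] <- d[, -ncol(d)] | tr[, -1]
      tr <- d
    }
  }
  tr
}

#' Linear interpolation across the metal trace
#'
#' Within each view (sinogram row), values on trace bins are replaced by
#' 1-D linear interpolation between the nearest untraced bins on either
#' side; a trace reaching a row edge is filled with the nearest untraced
#' value. Untraced bins are untouched, bit for bit. A fully traced row is
#' replaced by a copy of the nearest row with untraced bins (with a
#' warning).
#'
#' @param sino a [sinogram()].
#' @param trace logical trace matrix of the same shape.
#' @return The interpolated [sinogram()].
#' @export
li_interpolate <- function(sino, trace) {
  v <- sino$values
  if (!identical(dim(trace), dim(v)))
    stop("li_interpolate: trace and sinogram shapes differ")
  full_rows <- which(rowSums(!trace) == 0L)
  ok_rows <- which(rowSums(!trace) > 0L)
  if (length(full_rows)) {
    if (!length(ok_rows)) stop("li_interpolate: every row is fully traced")
    warning(sprintf("li_interpolate: %d fully traced row(s) replaced by nearest untraced row",
                    length(full_rows)))
  }
  out <- v
  for (r in ok_rows) {
    tr <- trace[r, ]
    if (!any(tr)) next
    keep <- which(!tr)
    out[r, tr] <- approx(keep, v[r, keep], xout = which(tr), rule = 2)$y
  }
  for (r in full_rows) {
    src <- ok_rows[which.min(abs(ok_rows - r))]
    out[r, ] <- out[src, ]
  }
  sinogram(out, sino$geom, sino$kind)
}

#' Build the NMAR prior image
#'
#' Classifies an HU image into air (-1000), soft tissue (0) and bone
#' (original HU preserved above the bone threshold), optionally after a
#' small Gaussian smoothing.
#'
#' @param img an [image2d()] in HU (typically the LI-corrected image).
#' @param air_threshold HU below which a pixel is air (default -500).
#' @param bone_threshold HU above which the original value is kept
#'   (default 150).
#' @param smooth_sigma Gaussian smoothing in pixels before classification;
#'   0 (default) disables it.
#' @return The prior [image2d()] in HU.
#' @export
build_prior <- function(img, air_threshold = -500, bone_threshold = 150,
                        smooth_sigma = 0) {
  stop_if_unit(img, "HU", "build_prior")
  hu <- img$values
  if (smooth_sigma > 0) hu <- gauss_smooth(hu, smooth_sigma)
  out <- hu
  out[hu < air_threshold] <- -1000
  out[hu >= air_threshold & hu < bone_threshold] <- 0
  image2d(out, spacing = img$spacing, unit = "HU")
}

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_apply <- function(x) {
    x <- rbind(matrix(x[1, ], r, ncol(x), byrow = TRUE), x,
               matrix(x[nrow(x), ], r, ncol(x), byrow = TRUE))
    apply(x, 2, function(col) stats::filter(col, k)[(r + 1):(length(col) - r)])
  }
  t(pad_apply(t(pad_apply(m))))
}

#' Normalization-interpolation core of NMAR
#'
#' Divides the measured sinogram by the prior sinogram, linearly
#' interpolates the normalized data across the metal trace, and
#' re-multiplies by the prior. The normalization is offset-stabilized:
#' `norm = (s + delta) / (max(prior, 0) + delta)`, so rays that miss the
#' body (both sinograms near zero) normalize to 1 instead of an arbitrary
#' ratio; without the offset, a trace segment ending at the body boundary
#' interpolates between a tissue ratio near 1 and a meaningless air ratio,
#' and the error is re-amplified by the large prior values mid-trace.
#' With `delta = 0` the division falls back to a bare `eps` floor. For a
#' perfect prior (prior equal to the true data, measured data exact off
#' the trace) the corrected trace reproduces the true data exactly in
#' either mode. Exposed separately so that property can be exercised
#' directly. Untraced bins are returned bit-identical.
#'
#' @param sino measured line-integral [sinogram()].
#' @param prior_sino prior-image [sinogram()] on the same geometry.
#' @param trace logical metal trace.
#' @param delta normalization offset (line-integral units; default 1,
#'   about 5 cm of water).
#' @param eps division floor used when `delta = 0`.
#' @return Corrected [sinogram()].
#' @export
nmar_sinogram_correct <- function(sino, prior_sino, trace, delta = 1,
                                  eps = 1e-6) {
  sv <- sino$values
  if (delta > 0) {
    pv <- pmax(prior_sino$values, 0) + delta
    norm <- sinogram((sv + delta) / pv, sino$geom, sino$kind)
    interp <- li_interpolate(norm, trace)
    out <- interp$values * pv - delta
  } else {
    pv <- pmax(prior_sino$values, eps)
    norm <- sinogram(sv / pv, sino$geom, sino$kind)
    interp <- li_interpolate(norm, trace)
    out <- interp$values * pv
  }
  out[!trace] <- sv[!trace]
  sinogram(pmax(out, 0), sino$geom, sino$kind)
}

#' Normalized metal artefact reduction
#'
#' The full NMAR pipeline on an HU image: segment the metal; forward
#' project; identify the metal trace; pre-correct with plain linear
#' interpolation (LI-MAR) and build the tissue-class prior from the
#' LI-corrected image (or the raw input); normalize the measured sinogram
#' by the prior sinogram, interpolate across the trace, denormalize;
#' reconstruct; and reinsert the original metal pixels. With `passes > 1`
#' the prior is then rebuilt from the corrected image and the original
#' sinogram is re-corrected (iterative prior refinement: the first-pass
#' image classifies much more reliably around bone than the LI image).
#' Deterministic.
#'
#' @param img metal-affected [image2d()] in HU.
#' @param geom a [fan_geometry()].
#' @param table a [material_table()].
#' @param energy reference energy (keV) for HU/attenuation conversion.
#' @param measured_sino optional measured [sinogram()] of the affected
#'   acquisition. When available (e.g. from a [simulate_case()]), it is
#'   used directly, as a scanner's projection-domain NMAR would; otherwise
#'   the affected image is forward projected, which adds a second
#'   reconstruction blur to the output.
#' @param metal_threshold metal segmentation threshold (HU).
#' @param dilation_bins trace dilation (bins).
#' @param prior_source `"li"` (default) builds the prior from the
#'   LI-corrected image, `"raw"` from the input image.
#' @param prior_smooth_sigma optional prior smoothing (pixels).
#' @param delta,eps normalization offset and floor (see
#'   [nmar_sinogram_correct()]).
#' @param filter FBP apodization.
#' @param hu_clip clinical HU range the corrected reconstruction is
#'   clipped to; NULL disables.
#' @param passes number of prior-refinement passes (default 2).
#' @return List with `corrected` ([image2d()]) and `artifacts` (list:
#'   `mask`, `trace`, `prior` from the final pass, `li_image`).
#' @export
nmar_correct <- function(img, geom, table = material_table(), energy = 70,
                         measured_sino = NULL,
                         metal_threshold = 2500, dilation_bins = 1L,
                         prior_source = c("li", "raw"),
                         prior_smooth_sigma = 0, delta = 1, eps = 1e-6,
                         filter = "hann", hu_clip = c(-1024, 3071),
                         passes = 2L) {
  prior_source <- match.arg(prior_source)
  stop_if_unit(img, "HU", "nmar_correct")
  if (passes < 1L) stop("nmar_correct: passes must be >= 1")
  gs <- dim(img$values); sp <- img$spacing
  mask <- segment_metal(img, metal_threshold)
  sino <- if (is.null(measured_sino))
    forward_project_mono(hu_to_mu(img, energy, table), geom)
  else { same_geometry(measured_sino, geom, "nmar_correct"); measured_sino }
  trace <- metal_trace(mask, geom, spacing = sp, dilation_bins = dilation_bins)
  li_sino <- li_interpolate(sino, trace)
  li_img <- mu_to_hu(fbp(li_sino, gs, sp, filter), energy, table)
  prior_src_img <- if (prior_source == "li") li_img else img
  corrected <- NULL; prior <- NULL
  for (p in seq_len(passes)) {
    prior <- build_prior(prior_src_img, smooth_sigma = prior_smooth_sigma)
    prior_sino <- forward_project_mono(hu_to_mu(prior, energy, table), geom)
    corr_sino <- nmar_sinogram_correct(sino, prior_sino, trace, delta, eps)
    corrected <- mu_to_hu(fbp(corr_sino, gs, sp, filter), energy, table)
    if (!is.null(hu_clip))
      corrected$values <- pmin(pmax(corrected$values, hu_clip[1]), hu_clip[2])
    corrected$values[mask] <- img$values[mask]
    prior_src_img <- corrected
  }
  list(corrected = corrected,
       artifacts = list(mask = mask, trace = trace, prior = prior,
                        li_image = li_img))
}
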