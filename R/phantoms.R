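#' Phantom specification
#'
#' An ordered list of geometric primitives painted onto an air background
#' (-1000 HU) in painter's order: later primitives overwrite earlier ones.
#' Primitives are defined in physical mm coordinates relative to the
#' isocenter (x to the right, y upward) and must lie entirely inside the
#' grid. Body (non-air) primitives are constrained to -200..1500 HU.
#'
#' @param primitives list of primitives; each is a list with fields
#'   `geometry` ("ellipse", "rectangle" or "polygon"), `hu`, and geometry
#'   parameters: ellipse `center`, `semiaxes` (mm), `rotation` (deg);
#'   rectangle `center`, `size` (full widths, mm), `rotation`; polygon
#'   `vertices` (n x 2 matrix, mm).
#' @param grid_size image size in pixels (scalar or c(H, W)); default 256.
#' @param spacing pixel spacing in mm.
#' @param seed integer seed driving the texture field of
#'   [make_body_phantom()].
#' @param texture_amp amplitude (HU) of the smooth random texture added to
#'   soft tissue; 0 disables it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(primitives = list(), grid_size = 256L, spacing = 1.5,
                         seed = 1L, texture_amp = 20) {
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  grid_size <- as.integer(grid_size)
  half <- grid_size * spacing / 2 # c(H, W) -> y, x half-extents
  for (k in seq_along(primitives)) {
    p <- primitives[[k]]
    r <- switch(p$geometry,
      ellipse = max(p$semiaxes),
      rectangle = sqrt(sum((p$size / 2)^2)),
      polygon = 0,
      stop("phantom_spec: unknown geometry \"", p$geometry, "\" in primitive ", k))
    xy <- if (p$geometry == "polygon") p$vertices else
      matrix(p$center, ncol = 2)
    if (any(abs(xy[, 1]) + r > half[2]) || any(abs(xy[, 2]) + r > half[1]))
      stop(sprintf("phantom_spec: primitive %d (%s) extends outside the grid",
                   k, p$geometry))
    if (!is.null(p$hu) && (p$hu < -200 || p$hu > 1500))
      stop(sprintf("phantom_spec: primitive %d HU %g outside [-200, 1500]",
                   k, p$hu))
  }
  structure(list(grid_size = grid_size, spacing = spacing,
                 primitives = primitives, seed = as.integer(seed),
                 texture_amp = texture_amp),
            class = "phantom_spec")
}

# physical coordinate grids (mm): X to the right, Y upward, isocenter center
coord_grids <- function(H, W, spacing) {
  x <- (seq_len(W) - 1 - (W - 1) / 2) * spacing
  y <- ((H - 1) / 2 - (seq_len(H) - 1)) * spacing
  list(X = matrix(x, H, W, byrow = TRUE), Y = matrix(y, H, W))
}

prim_mask <- function(p, H, W, spacing) {
  g <- coord_grids(H, W, spacing)
  rot <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  }
  switch(p$geometry,
    ellipse = {
      th <- (if (is.null(p$rotation)) 0 else p$rotation) * pi / 180
      dx <- g$X - p$center[1]; dy <- g$Y - p$center[2]
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      (u / p$semiaxes[1])^2 + (v / p$semiaxes[2])^2 <= 1
    },
    rectangle = {
      th <- (if (is.null(p$rotation)) 0 else p$rotation) * pi / 180
      dx <- g$X - p$center[1]; dy <- g$Y - p$center[2]
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      abs(u) <= p$size[1] / 2 & abs(v) <= p$size[2] / 2
    },
    polygon = {
      inside <- pracma::inpolygon(as.vector(g$X), as.vector(g$Y),
                                  p$vertices[, 1], p$vertices[, 2])
      matrix(inside, H, W)
    },
    stop("unknown primitive geometry: ", p$geometry))
}

#' Render a body phantom
#'
#' Paints the spec's primitives over a -1000 HU air background in order,
#' then adds a seeded smooth texture field (a handful of broad Gaussian
#' blobs) to soft-tissue pixels so projections are not piecewise constant.
#' Rendering is a pure function of the spec: repeated calls are
#' bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return An [image2d()] in HU.
#' @export
make_body_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$grid_size[1]; W <- spec$grid_size[2]
  img <- matrix(-1000, H, W)
  for (p in spec$primitives) img[prim_mask(p, H, W, spec$spacing)] <- p$hu
  if (spec$texture_amp > 0 && length(spec$primitives)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    g <- coord_grids(H, W, spec$spacing)
    ext <- min(H, W) * spec$spacing
    field <- matrix(0, H, W)
    for (k in 1:6) {
      cx <- runif(1, -ext / 4, ext / 4); cy <- runif(1, -ext / 4, ext / 4)
      sg <- runif(1, ext / 20, ext / 8)
      amp <- runif(1, -spec$texture_amp, spec$texture_amp)
      field <- field + amp * exp(-((g$X - cx)^2 + (g$Y - cy)^2) / (2 * sg^2))
    }
    soft <- img > -500 & img < 150
    img[soft] <- pmin(pmax(img[soft] + field[soft], -200), 1500)
  }
  image2d(img, spacing = spec$spacing, unit = "HU")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Parametric body templates
#'
#' Three stylized anatomical regions (thorax, head, pelvis) built from
#' ellipses: soft-tissue body outline, low-density lung surrogates, bone
#' ovals (spine, skull, pelvis) and organ-like soft structures. Sizes scale
#' with the grid extent so the same template renders sensibly at 64 to 400
#' pixels.
#'
#' @param template one of "thorax", "head", "pelvis".
#' @inheritParams phantom_spec
#' @return A [phantom_spec()].
#' @export
body_phantom_spec <- function(template = c("thorax", "head", "pelvis"),
                              grid_size = 256L, spacing = 1.5, seed = 1L,
                              texture_amp = 20) {
  template <- match.arg(template)
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  u <- min(grid_size) * spacing / 384 # templates authored for a 384 mm extent
  el <- function(cx, cy, a, b, hu, rot = 0)
    list(geometry = "ellipse", center = c(cx, cy) * u, semiaxes = c(a, b) * u,
         rotation = rot, hu = hu)
  prims <- switch(template,
    thorax = list(
      el(0, 0, 160, 110, 35),
      el(-70, 10, 52, 62, -190, 8),
      el(70, 10, 52, 62, -190, -8),
      el(20, 0, 38, 33, 45),
      el(0, -78, 16, 16, 700),
      el(0, -78, 5, 5, 60),
      el(0, 96, 15, 8, 500)),
    head = list(
      el(0, 0, 80, 100, 1200),
      el(0, 0, 69, 89, 45),
      el(0, 52, 12, 10, -190),
      el(0, -60, 14, 9, 300),
      el(-25, 20, 10, 14, 25),
      el(25, 20, 10, 14, 25)),
    pelvis = list(
      el(0, 0, 170, 110, 30),
      el(-80, 10, 28, 48, 600, -25),
      el(80, 10, 28, 48, 600, 25),
      el(-70, -42, 21, 21, 800),
      el(70, -42, 21, 21, 800),
      el(0, -25, 30, 24, 15),
      el(0, 55, 19, 17, 500)))
  phantom_spec(prims, grid_size = grid_size, spacing = spacing, seed = seed,
               texture_amp = texture_amp)
}

# local-frame primitive sets for the 8 stylized implants (mm at scale 1)
metal_shape_defs <- function() {
  el <- function(cx, cy, a, b) list(geometry = "ellipse", center = c(cx, cy),
                                    semiaxes = c(a, b))
  rc <- function(cx, cy, w, h) list(geometry = "rectangle", center = c(cx, cy),
                                    size = c(w, h))
  list(
    `1` = list(name = "dental_filling_a", prims = list(el(0, 0, 5, 4))),
    `2` = list(name = "dental_filling_b", prims = list(el(-5, 0, 3.4, 3.4),
                                                       el(5, 0, 3.4, 3.4))),
    `3` = list(name = "spine_screw_a", prims = list(rc(0, 0, 7, 28))),
    `4` = list(name = "spine_screw_b", prims = list(rc(-6, 0, 6, 24),
                                                    rc(6, 0, 6, 24))),
    `5` = list(name = "hip_prosthesis_a", prims = list(el(0, 10, 12, 12),
                                                       rc(0, -14, 8, 32))),
    `6` = list(name = "hip_prosthesis_b", prims = list(el(0, 0, 14, 10))),
    `7` = list(name = "shoulder_prosthesis_a", prims = list(el(0, 8, 10, 10),
                                                            rc(0, -12, 6, 26))),
    `8` = list(name = "shoulder_prosthesis_b", prims = list(rc(0, 0, 24, 9),
                                                            rc(8, -12, 8, 20))))
}

#' Build a metal implant shape
#'
#' Rasterizes one of eight stylized implant geometries (dental fillings,
#' spine fixation screws, hip and shoulder prostheses, two variants each)
#' into a binary mask on the target grid, after rotating and scaling the
#' local geometry and translating it to the anchor pixel. The same
#' arguments always yield the same mask.
#'
#' @param shape_id integer 1..8.
#' @param material_label one of "iron", "gold", "titanium", "copper".
#' @param anchor insertion point as (row, col) pixel indices.
#' @param grid_size target grid in pixels (scalar or c(H, W)).
#' @param spacing pixel spacing in mm.
#' @param rotation rotation in degrees.
#' @param scale isotropic scale factor.
#' @param table [material_table()] used to validate the material.
#' @return A `metal_shape` object with fields `mask` (logical matrix),
#'   `shape_id`, `material_label`, `anchor`, `rotation`, `scale`.
#' @export
make_metal_shape <- function(shape_id, material_label, anchor,
                             grid_size = 256L, spacing = 1.5,
                             rotation = 0, scale = 1,
                             table = material_table()) {
  defs <- metal_shape_defs()
  if (!as.character(shape_id) %in% names(defs))
    stop("make_metal_shape: shape_id must be one of ", paste(names(defs), collapse = ", "))
  metals <- c("iron", "gold", "titanium", "copper")
  if (!material_label %in% metals || is.null(table$materials[[material_label]]))
    stop("make_metal_shape: material must be one of ", paste(metals, collapse = ", "))
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  H <- grid_size[1]; W <- grid_size[2]
  if (anchor[1] < 1 || anchor[1] > H || anchor[2] < 1 || anchor[2] > W)
    stop("make_metal_shape: anchor (row, col) outside the grid")
  ax <- (anchor[2] - 1 - (W - 1) / 2) * spacing
  ay <- ((H - 1) / 2 - (anchor[1] - 1)) * spacing
  a <- rotation * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  mask <- matrix(FALSE, H, W)
  def <- defs[[as.character(shape_id)]]
  for (p in def$prims) {
    ctr <- as.vector(R %*% (p$center * scale)) + c(ax, ay)
    q <- p
    q$center <- ctr
    q$rotation <- rotation
    if (p$geometry == "ellipse") q$semiaxes <- p$semiaxes * scale
    if (p$geometry == "rectangle") q$size <- p$size * scale
    mask <- mask | prim_mask(q, H, W, spacing)
  }
  if (sum(mask) < 4)
    stop("make_metal_shape: mask area below 4 pixels; increase scale or grid resolution")
  structure(list(shape_id = as.integer(shape_id), name = def$name,
                 material_label = material_label,
                 mask = mask, anchor = anchor, rotation = rotation,
                 scale = scale, spacing = spacing),
            class = "metal_shape")
}

#' Insert a metal implant into a CT image
#'
#' Sets the pixels under the shape mask to the implant material's HU value
#' at the reference energy (HU = 1000 (mu/mu_water - 1), clipped at the
#' extended-scale ceiling); all other pixels are untouched.
#'
#' @param image an [image2d()] in HU.
#' @param shape a [make_metal_shape()] result on the same grid.
#' @param table a [material_table()].
#' @param energy reference energy in keV.
#' @param ceiling HU clip for very dense metals.
#' @return The modified [image2d()].
#' @export
insert_metal <- function(image, shape, table = material_table(), energy = 70,
                         ceiling = 30000) {
  stop_if_unit(image, "HU", "insert_metal")
  if (!identical(dim(image$values), dim(shape$mask)))
    stop("insert_metal: image and shape mask are on different grids")
  hu <- material_hu(table, shape$material_label, energy, ceiling)
  out <- image
  out$values[shape$mask] <- hu
  out
}

# per-template default insertion anchors (fraction of grid) for each shape
anchor_hint <- function(template, shape_id, grid_size) {
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  frac <- switch(template,
    head = list(`1` = c(0.78, 0.5), `2` = c(0.78, 0.5), `3` = c(0.62, 0.5),
                `4` = c(0.62, 0.5), `5` = c(0.5, 0.38), `6` = c(0.5, 0.62),
                `7` = c(0.45, 0.40), `8` = c(0.45, 0.60)),
    thorax = list(`1` = c(0.30, 0.5), `2` = c(0.30, 0.5), `3` = c(0.70, 0.5),
                  `4` = c(0.70, 0.5), `5` = c(0.5, 0.30), `6` = c(0.5, 0.70),
                  `7` = c(0.35, 0.30), `8` = c(0.35, 0.70)),
    pelvis = list(`1` = c(0.40, 0.5), `2` = c(0.40, 0.5), `3` = c(0.65, 0.5),
                  `4` = c(0.65, 0.5), `5` = c(0.60, 0.30), `6` = c(0.60, 0.70),
                  `7` = c(0.45, 0.32), `8` = c(0.45, 0.68)))
  round(frac[[as.character(shape_id)]] * grid_size)
}
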