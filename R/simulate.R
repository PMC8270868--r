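#' Weighted-threshold material segmentation
#'
#' Decomposes an HU image into fractional material weights for air, soft
#' tissue, bone and metal using hard class thresholds (-900, 150 and
#' 2500 HU) softened by linear transition ramps of +/- 50 HU, so weights
#' are in 0..1 and sum to one at every pixel. Per-class density grids are
#' derived by scaling the class's nominal density with the pixel HU:
#' soft tissue scales as water (1 + HU/1000 g/cm^3), bone scales linearly
#' so 1500 HU maps to its nominal 1.92 g/cm^3, air and metal use their
#' nominal densities (the metal HU is ceiling-clipped and carries no
#' density information).
#'
#' @param img an [image2d()] in HU.
#' @param table a [material_table()].
#' @param metal_label which metal the metal class maps to.
#' @param bands named thresholds/half-band width (HU), overridable.
#' @return List with `weights` (named list of weight matrices) and
#'   `density` (named list of density matrices, g/cm^3, already multiplied
#'   by the weights; names air/soft_tissue/bone plus the metal label).
#' @export
segment_materials <- function(img, table = material_table(),
                              metal_label = "iron",
                              bands = c(air = -900, bone = 150,
                                        metal = 2500, half = 50)) {
  stop_if_unit(img, "HU", "segment_materials")
  hu <- img$values
  h <- bands[["half"]]
  up <- function(b) pmin(pmax((hu - (b - h)) / (2 * h), 0), 1)
  w_air <- 1 - up(bands[["air"]])
  w_soft <- up(bands[["air"]]) * (1 - up(bands[["bone"]]))
  w_bone <- up(bands[["bone"]]) * (1 - up(bands[["metal"]]))
  w_metal <- up(bands[["metal"]])
  d_soft <- pmin(pmax(1 + hu / 1000, 0), 2.0)
  d_bone <- pmin(pmax(table$materials$bone$density * (hu + 1000) / 2500, 0.2), 3.2)
  dens <- list(
    air = w_air * table$materials$air$density,
    soft_tissue = w_soft * d_soft,
    bone = w_bone * d_bone)
  dens[[metal_label]] <- w_metal * table$materials[[metal_label]]$density
  list(weights = list(air = w_air, soft_tissue = w_soft, bone = w_bone,
                      metal = w_metal),
       density = dens, metal_label = metal_label)
}

#' Water beam-hardening calibration
#'
#' Maps each polychromatic line integral to its monochromatic equivalent at
#' the reference energy by inverting the (monotone) polychromatic water
#' attenuation curve: the measured value is interpreted as the attenuation
#' of a water slab, whose thickness is then multiplied by mu_water(E0).
#' This is the standard scanner "water correction": pure water paths become
#' exact, while bone and metal paths keep their beam-hardening residual.
#'
#' @param sino polychromatic line-integral [sinogram()].
#' @param spectrum,table the spectrum and material table used to acquire it.
#' @param energy reference energy (keV).
#' @return Calibrated [sinogram()].
#' @export
water_precorrect <- function(sino, spectrum, table, energy = 70) {
  morw <- sapply(spectrum$energies, function(E) attenuation_lookup(table, "soft_tissue", E))
  tgrid <- seq(0, 120, by = 0.02) # water-equivalent thickness, cm
  pgrid <- -log(colSums(spectrum$weights * exp(-outer(morw, tgrid))))
  t_of_p <- approx(pgrid, tgrid, xout = pmin(pmax(sino$values, 0), max(pgrid)),
                   rule = 2)$y
  mono <- attenuation_lookup(table, "soft_tissue", energy) *
    matrix(t_of_p, nrow(sino$values), ncol(sino$values))
  sinogram(mono, sino$geom, "line_integral")
}

#' Simulate one metal-artefact case
#'
#' The full artefact simulation for one (body, implant) pair: the implant
#' is inserted into the metal-free image; the reference image is the FBP of
#' the *monochromatic* projection of the inserted image (so it carries the
#' same sampling blur as the affected image); the metal-affected image is
#' the FBP of the *polychromatic* projection of the weighted-threshold
#' material decomposition, optionally Poisson-noised and (by default)
#' water-calibrated. Deterministic for a fixed seed.
#'
#' @param metal_free an [image2d()] in HU.
#' @param shape a [make_metal_shape()] on the same grid.
#' @param geom a [fan_geometry()].
#' @param spectrum,table spectrum and material table.
#' @param seed integer seed (used only when `noise_n0` is set).
#' @param noise_n0 incident photons per bin for Poisson noise; NULL (default)
#'   disables noise.
#' @param energy reference energy in keV.
#' @param filter FBP apodization.
#' @param water_calibration apply [water_precorrect()] to the affected
#'   sinogram (default TRUE).
#' @param hu_clip clinical HU display range both reconstructions are
#'   clipped to (default -1024..3071, the 12-bit scanner scale, so that
#'   dense-metal overshoot halos behave as they do in clinical data);
#'   NULL disables.
#' @param case_id,realization,template provenance strings stored on the case.
#' @return A `simulation_case`: metal_free, metal_inserted_ref,
#'   metal_affected (all [image2d()] HU), affected_sinogram, ref_sinogram,
#'   metal_mask, and provenance fields.
#' @export
simulate_case <- function(metal_free, shape, geom, spectrum,
                          table = material_table(), seed = 1L,
                          noise_n0 = NULL, energy = 70,
                          filter = "hann", water_calibration = TRUE,
                          hu_clip = c(-1024, 3071),
                          case_id = NA_character_, realization = NA_integer_,
                          template = NA_character_) {
  stop_if_unit(metal_free, "HU", "simulate_case")
  gs <- dim(metal_free$values); sp <- metal_free$spacing
  clip <- function(im) {
    if (!is.null(hu_clip))
      im$values <- pmin(pmax(im$values, hu_clip[1]), hu_clip[2])
    im
  }
  inserted <- insert_metal(metal_free, shape, table, energy)
  ref_sino <- forward_project_mono(hu_to_mu(inserted, energy, table), geom)
  ref <- clip(mu_to_hu(fbp(ref_sino, gs, sp, filter), energy, table))
  seg <- segment_materials(inserted, table, metal_label = shape$material_label)
  aff_sino <- forward_project_poly(seg$density, spectrum, table, geom,
                                   spacing = sp)
  if (!is.null(noise_n0))
    aff_sino <- add_poisson_noise(aff_sino, noise_n0, seed)
  cal_sino <- if (water_calibration)
    water_precorrect(aff_sino, spectrum, table, energy) else aff_sino
  affected <- clip(mu_to_hu(fbp(cal_sino, gs, sp, filter), energy, table))
  structure(list(case_id = case_id, shape_id = shape$shape_id,
                 material_label = shape$material_label,
                 realization = realization, template = template,
                 seed = as.integer(seed),
                 metal_free = metal_free, metal_inserted = inserted,
                 metal_inserted_ref = ref, metal_affected = affected,
                 affected_sinogram = cal_sino, ref_sinogram = ref_sino,
                 metal_mask = shape$mask),
            class = "simulation_case")
}

#' @export
print.simulation_case <- function(x, ...) {
  cat(sprintf("<simulation_case %s: shape %d, %s, realization %s>\n",
              x$case_id, x$shape_id, x$material_label, x$realization))
  invisible(x)
}

#' Dataset manifest: case bookkeeping and train/eval split
#'
#' Enumerates the full factorial corpus (realizations x shapes x materials),
#' assigns per-case seeds and anatomical templates (cycled across
#' realizations), and splits cases into train/eval sets. The evaluation
#' split is stratified: each (shape, material) pair contributes
#' `floor(n_eval/n_strata)` cases, with the remainder distributed over a
#' seeded sample of strata, so per-stratum eval counts differ by at most
#' one. With the default configuration (25 realizations, 8 shapes, 4
#' materials, eval fraction 140/800) this reproduces the 800-case corpus
#' with its 660/140 split.
#'
#' @param n_realizations realizations per (shape, material) pair.
#' @param shape_ids integer vector of implant shapes.
#' @param materials character vector of implant materials, crossed with
#'   every shape (the full-factorial augmentation design).
#' @param material_by_shape alternatively, a named character vector
#'   mapping each shape id to one material (e.g. the clinical pairing:
#'   dental fillings gold, screws and shoulder prostheses iron, hip
#'   prostheses copper), giving realizations x shapes cases; overrides
#'   `materials`.
#' @param eval_fraction fraction of cases held out for evaluation.
#' @param templates anatomical templates cycled across realizations.
#' @param global_seed integer seed controlling case seeds and the split.
#' @return A `dataset_manifest` with `cases` (data.frame), `split`
#'   (train/eval case-id vectors) and `counts`.
#' @export
build_manifest <- function(n_realizations = 25L, shape_ids = 1:8,
                           materials = c("iron", "gold", "titanium", "copper"),
                           material_by_shape = NULL,
                           eval_fraction = 140 / 800,
                           templates = c("thorax", "head", "pelvis"),
                           global_seed = 1L) {
  stopifnot(n_realizations >= 1L, length(shape_ids) >= 1L, length(materials) >= 1L)
  if (is.null(material_by_shape)) {
    grid <- expand.grid(realization = seq_len(n_realizations),
                        shape_id = as.integer(shape_ids),
                        material_label = materials,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(realization = seq_len(n_realizations),
                        shape_id = as.integer(shape_ids),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$material_label <- unname(material_by_shape[as.character(grid$shape_id)])
    if (anyNA(grid$material_label))
      stop("build_manifest: material_by_shape must name every shape id")
  }
  grid$template <- templates[((grid$realization - 1L + grid$shape_id) %%
                                length(templates)) + 1L]
  grid$case_id <- sprintf("s%d_%s_r%02d", grid$shape_id,
                          substr(grid$material_label, 1, 2), grid$realization)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(global_seed))
  grid$seed <- sample.int(2^31 - 1, nrow(grid))
  n_eval <- round(eval_fraction * nrow(grid))
  strata <- split(seq_len(nrow(grid)),
                  paste(grid$shape_id, grid$material_label))
  base <- n_eval %/% length(strata)
  extra <- n_eval - base * length(strata)
  extra_strata <- if (extra > 0) sample(names(strata), extra) else character(0)
  eval_idx <- unlist(lapply(names(strata), function(s) {
    k <- min(base + (s %in% extra_strata), length(strata[[s]]))
    strata[[s]][sample.int(length(strata[[s]]), k)]
  }))
  train_idx <- setdiff(seq_len(nrow(grid)), eval_idx)
  split <- list(train = grid$case_id[train_idx], eval = grid$case_id[eval_idx])
  structure(list(cases = grid, split = split,
                 counts = c(n_realizations = n_realizations,
                            n_shapes = length(shape_ids),
                            n_materials = length(materials)),
                 global_seed = as.integer(global_seed)),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d cases (%d train / %d eval), seed %d>\n",
              nrow(x$cases), length(x$split$train), length(x$split$eval),
              x$global_seed))
  invisible(x)
}

#' Build (and optionally materialize) the simulation corpus
#'
#' Realizes every case of a manifest: renders the body phantom for the
#' case's template, jitters the implant anchor/rotation/scale with the
#' case seed (anchor +/- 15 px at 256-px scale, rotation +/- 20 deg, scale
#' 0.8-1.2), and runs [simulate_case()]. With `materialize = FALSE` only
#' the manifest bookkeeping is returned. With `out_dir` set, images and
#' sinograms are written as NIfTI plus a JSON manifest.
#'
#' @param manifest a [build_manifest()] result (or NULL to build one from
#'   the remaining arguments' defaults).
#' @param geom,spectrum,table acquisition model.
#' @param grid_size,spacing phantom grid (pixels, mm).
#' @param metal_scale base implant scale; the default scales the implants
#'   by the same factor as the body templates (grid extent / 384 mm), so
#'   the implant-to-anatomy ratio stays clinical at any resolution.
#' @param noise_n0 optional Poisson noise level, passed to [simulate_case()].
#' @param materialize simulate the images (TRUE) or bookkeeping only.
#' @param out_dir optional output directory for NIfTI/JSON files.
#' @param texture_amp soft-tissue texture amplitude for the body phantoms.
#' @param ... further arguments passed to [build_manifest()] when no
#'   manifest is supplied.
#' @inheritParams build_manifest
#' @return The manifest, with `cases_data` (list of `simulation_case`)
#'   attached when materialized, and `out_dir` when written.
#' @export
build_dataset <- function(manifest = NULL, geom = fan_geometry(),
                          spectrum = spectrum_120kvp(),
                          table = material_table(),
                          grid_size = 256L, spacing = 1.5,
                          metal_scale = NULL, noise_n0 = NULL,
                          materialize = TRUE, out_dir = NULL,
                          texture_amp = 20, global_seed = 1L, ...) {
  if (is.null(manifest)) manifest <- build_manifest(global_seed = global_seed, ...)
  if (!materialize) return(manifest)
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  if (is.null(metal_scale)) metal_scale <- min(grid_size) * spacing / 384
  cases <- vector("list", nrow(manifest$cases))
  names(cases) <- manifest$cases$case_id
  for (k in seq_len(nrow(manifest$cases))) {
    row <- manifest$cases[k, ]
    cs <- case_from_row(row, geom, spectrum, table, grid_size, spacing,
                        metal_scale, noise_n0, texture_amp)
    cases[[k]] <- cs
    if (!is.null(out_dir)) write_case(cs, out_dir)
  }
  manifest$cases_data <- cases
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    manifest$out_dir <- out_dir
  }
  manifest
}

# realize one manifest row (shared by build_dataset and tests)
case_from_row <- function(row, geom, spectrum, table, grid_size, spacing,
                          metal_scale, noise_n0, texture_amp = 20) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(row$seed)
  spec <- body_phantom_spec(row$template, grid_size, spacing,
                            seed = row$seed, texture_amp = texture_amp)
  body <- make_body_phantom(spec)
  jit <- round(runif(2, -15, 15) * min(grid_size) / 256)
  anchor <- anchor_hint(row$template, row$shape_id, grid_size) + jit
  anchor <- pmin(pmax(anchor, round(0.15 * grid_size)), round(0.85 * grid_size))
  rot <- runif(1, -20, 20)
  scl <- metal_scale * runif(1, 0.8, 1.2)
  shape <- NULL
  for (k in 1:4) { # coarse grids: grow the implant until it rasterizes
    shape <- tryCatch(
      make_metal_shape(row$shape_id, row$material_label, anchor,
                       grid_size, spacing, rotation = rot, scale = scl,
                       table = table),
      error = function(e) NULL)
    if (!is.null(shape)) break
    scl <- scl * 1.4
  }
  if (is.null(shape))
    stop("case_from_row: implant shape ", row$shape_id,
         " cannot be rasterized on this grid")
  simulate_case(body, shape, geom, spectrum, table, seed = row$seed,
                noise_n0 = noise_n0, case_id = row$case_id,
                realization = row$realization, template = row$template)
}
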