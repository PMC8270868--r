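#' Desk-scale study conditions
#'
#' The fixed conditions used by the package's worked examples, test suite
#' and acceptance script: a 128 x 128 grid at 2 mm spacing (256 mm field
#' of view), a 192-view x 160-bin fan-beam geometry, the 120 kVp
#' spectrum, Poisson noise at 2e4 incident photons per bin (low-dose, so
#' photon starvation through metal is realistic), and the clinical
#' implant-material pairing: dental fillings in gold (amalgam surrogate),
#' spine screws and shoulder prostheses in iron (steel), hip prostheses
#' in copper (cobalt-chrome surrogate). These emulate the severe-artefact
#' regime the correction methods target; the full-factorial
#' shape x material crossing remains available through
#' [build_manifest()].
#'
#' @param grid_size,spacing,n_views,n_bins,fov,noise_n0 overrides.
#' @return A list of named conditions (`geom`, `spectrum`, `table`,
#'   `grid_size`, `spacing`, `noise_n0`, `material_by_shape`).
#' @export
desk_conditions <- function(grid_size = 128L, spacing = 2.0,
                            n_views = 192L, n_bins = 160L, fov = 260,
                            noise_n0 = 2e4) {
  list(geom = fan_geometry(n_views, n_bins, fov = fov),
       spectrum = spectrum_120kvp(),
       table = material_table(),
       grid_size = as.integer(grid_size), spacing = spacing,
       noise_n0 = noise_n0,
       material_by_shape = c(`1` = "gold", `2` = "gold",
                             `3` = "iron", `4` = "iron",
                             `5` = "copper", `6` = "copper",
                             `7` = "iron", `8` = "iron"))
}

#' Materialize a desk-scale fixture suite
#'
#' Builds `n_realizations x 8 shapes` simulation cases under
#' [desk_conditions()], suppressing the expected negative-line-integral
#' warnings from the Poisson noise model.
#'
#' @param n_realizations realizations per shape.
#' @param global_seed corpus seed.
#' @param conditions a [desk_conditions()] list.
#' @param eval_fraction held-out fraction for the train/eval split.
#' @param shape_ids implant shapes to include.
#' @return A materialized `dataset_manifest` (see [build_dataset()]).
#' @export
desk_suite <- function(n_realizations = 2L, global_seed = 20L,
                       conditions = desk_conditions(),
                       eval_fraction = 140 / 800, shape_ids = 1:8) {
  man <- build_manifest(n_realizations = n_realizations,
                        shape_ids = shape_ids,
                        material_by_shape = conditions$material_by_shape,
                        eval_fraction = eval_fraction,
                        global_seed = global_seed)
  suppressWarnings(
    build_dataset(man, geom = conditions$geom, spectrum = conditions$spectrum,
                  table = conditions$table, grid_size = conditions$grid_size,
                  spacing = conditions$spacing,
                  noise_n0 = conditions$noise_n0))
}

#' Clinical-cohort fixture suite
#'
#' Sixteen severe-artefact cases mirroring the composition of a clinical
#' MAR cohort: dental fillings dominate (gold, three realizations of each
#' of the two dental shapes), followed by hip (copper) and shoulder
#' (iron) prostheses. Spine screws are excluded, as in the clinical
#' cohorts such methods are evaluated on; their mild artefacts sit below
#' the error floor of prior-based correction (see the methods vignette).
#'
#' @inheritParams desk_suite
#' @return A materialized `dataset_manifest` with 16 cases.
#' @export
clinical_suite <- function(global_seed = 20L, conditions = desk_conditions()) {
  plan <- data.frame(
    shape_id = c(1L, 1L, 1L, 2L, 2L, 2L, 5L, 5L, 5L, 6L, 6L, 6L, 7L, 7L, 8L, 8L),
    realization = c(1:3, 1:3, 1:3, 1:3, 1:2, 1:2))
  plan$material_label <- unname(conditions$material_by_shape[as.character(plan$shape_id)])
  templates <- c("thorax", "head", "pelvis")
  plan$template <- templates[(plan$realization - 1L + plan$shape_id) %% 3L + 1L]
  plan$case_id <- sprintf("s%d_%s_r%02d", plan$shape_id,
                          substr(plan$material_label, 1, 2), plan$realization)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(global_seed))
  plan$seed <- sample.int(2^31 - 1, nrow(plan))
  man <- structure(list(cases = plan,
                        split = list(train = character(0), eval = plan$case_id),
                        counts = c(n_realizations = 3L, n_shapes = 6L,
                                   n_materials = 3L),
                        global_seed = as.integer(global_seed)),
                   class = "dataset_manifest")
  suppressWarnings(
    build_dataset(man, geom = conditions$geom, spectrum = conditions$spectrum,
                  table = conditions$table, grid_size = conditions$grid_size,
                  spacing = conditions$spacing,
                  noise_n0 = conditions$noise_n0))
}
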