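# Material segmentation, case simulation and dataset bookkeeping.

test_that("weighted-threshold segmentation is hard outside the ramps and
           linear inside them, with weights summing to one", {
  tab <- fx_table()
  img <- image2d(matrix(c(-1000, 3000, 150, 0, 125, 175, 2525), 1), 2, "HU")
  seg <- segment_materials(img, tab)
  w <- seg$weights
  expect_equal(w$air[1, 1], 1)
  expect_equal(w$metal[1, 2], 1)
  # band midpoint at the soft/bone threshold -> 0.5 / 0.5
  expect_equal(w$soft_tissue[1, 3], 0.5, tolerance = 1e-12)
  expect_equal(w$bone[1, 3], 0.5, tolerance = 1e-12)
  expect_equal(w$soft_tissue[1, 4], 1)
  # quarter points of the +/-50 band
  expect_equal(w$soft_tissue[1, 5], 0.75, tolerance = 1e-12)
  expect_equal(w$bone[1, 6], 0.75, tolerance = 1e-12)
  expect_equal(w$metal[1, 7], 0.75, tolerance = 1e-12)
  tot <- w$air + w$soft_tissue + w$bone + w$metal
  expect_lt(max(abs(tot - 1)), 1e-12)
})

test_that("the no-metal null residual of the simulation pipeline is small", {
  cond <- desk_conditions(noise_n0 = NULL)
  body <- make_body_phantom(body_phantom_spec("thorax", cond$grid_size,
                                              cond$spacing, seed = 7))
  seg <- segment_materials(body, cond$table)
  aff <- forward_project_poly(seg$density, cond$spectrum, cond$table,
                              cond$geom, spacing = cond$spacing)
  cal <- water_precorrect(aff, cond$spectrum, cond$table)
  null_aff <- mu_to_hu(fbp(cal, cond$grid_size, cond$spacing), table = cond$table)
  ref <- mu_to_hu(fbp(forward_project_mono(hu_to_mu(body, table = cond$table),
                                           cond$geom),
                      cond$grid_size, cond$spacing), table = cond$table)
  # bone beam-hardening is the only residual after water calibration;
  # measured 10.2 HU at the fixture resolution, an order of magnitude below
  # the smallest metal-case residual
  expect_lt(rmse(ref, null_aff), 12)
})

test_that("metal insertion produces a strictly larger residual than the null
           and identical grids/masks for ref and affected", {
  cond <- fx_conditions()
  suite <- fx_clinical_suite()
  cs <- suite$cases_data[[1]]
  expect_identical(dim(cs$metal_inserted_ref$values),
                   dim(cs$metal_affected$values))
  expect_identical(dim(cs$metal_mask), dim(cs$metal_affected$values))
  expect_gt(sum(cs$metal_mask), 0)
})

test_that("simulate_case is bit-identical for a fixed seed", {
  cond <- desk_conditions()
  tab <- cond$table
  body <- make_body_phantom(body_phantom_spec("pelvis", 64L, 4, seed = 5))
  shape <- make_metal_shape(6, "copper", c(38, 45), 64L, 4, scale = 1.4,
                            table = tab)
  geom <- fan_geometry(96, 80, fov = 260)
  a <- suppressWarnings(simulate_case(body, shape, geom, cond$spectrum, tab,
                                      seed = 42, noise_n0 = 2e4))
  b <- suppressWarnings(simulate_case(body, shape, geom, cond$spectrum, tab,
                                      seed = 42, noise_n0 = 2e4))
  expect_identical(a$metal_affected$values, b$metal_affected$values)
  expect_identical(a$metal_inserted_ref$values, b$metal_inserted_ref$values)
  expect_identical(a$affected_sinogram$values, b$affected_sinogram$values)
})

test_that("manifest counts multiply out and the paper configuration splits 660/140", {
  m <- build_manifest(n_realizations = 2, shape_ids = 1:2,
                      materials = c("iron", "gold"), global_seed = 1)
  expect_equal(nrow(m$cases), 8)
  mp <- build_manifest() # 25 x 8 x 4
  expect_equal(nrow(mp$cases), 800)
  expect_equal(length(mp$split$train), 660)
  expect_equal(length(mp$split$eval), 140)
  expect_length(intersect(mp$split$train, mp$split$eval), 0)
  expect_setequal(c(mp$split$train, mp$split$eval), mp$cases$case_id)
})

test_that("the evaluation split is stratified within one case per stratum", {
  mp <- build_manifest(global_seed = 3)
  ev <- mp$cases[mp$cases$case_id %in% mp$split$eval, ]
  counts <- table(paste(ev$shape_id, ev$material_label))
  expect_equal(length(counts), 32)
  expect_true(all(abs(as.numeric(counts) - 140 / 32) <= 1))
})

test_that("manifests rebuild identically from the same global seed", {
  a <- build_manifest(n_realizations = 4, global_seed = 99)
  b <- build_manifest(n_realizations = 4, global_seed = 99)
  expect_identical(a$cases, b$cases)
  expect_identical(a$split, b$split)
  c2 <- build_manifest(n_realizations = 4, global_seed = 100)
  expect_false(identical(a$split$eval, c2$split$eval))
})

test_that("manifest JSON round-trips through write/read", {
  m <- build_manifest(n_realizations = 2, shape_ids = 1:3,
                      materials = "iron", global_seed = 7)
  path <- tempfile(fileext = ".json")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(m2$cases$case_id, m$cases$case_id)
  expect_equal(m2$split$eval, m$split$eval)
  expect_equal(m2$global_seed, m$global_seed)
})

test_that("a materialized mini-dataset writes NIfTI cases that read back", {
  cond <- desk_conditions(grid_size = 64L, spacing = 4, n_views = 96L,
                          n_bins = 80L, noise_n0 = NULL)
  man <- build_manifest(n_realizations = 1, shape_ids = 5L,
                        materials = "copper", global_seed = 2)
  out <- file.path(tempdir(), "mini_ds")
  ds <- build_dataset(man, geom = cond$geom, spectrum = cond$spectrum,
                      table = cond$table, grid_size = 64L, spacing = 4,
                      out_dir = out)
  base <- file.path(out, ds$cases$case_id[1])
  expect_true(file.exists(paste0(base, "_affected.nii.gz")))
  back <- read_image2d(paste0(base, "_affected.nii.gz"))
  expect_equal(back$values, ds$cases_data[[1]]$metal_affected$values,
               tolerance = 1e-6)
  expect_equal(back$spacing, 4)
  expect_true(file.exists(file.path(out, "manifest.json")))
  unlink(out, recursive = TRUE)
})

test_that("phantom specs round-trip through YAML", {
  spec <- body_phantom_spec("pelvis", 96L, 2.5, seed = 12, texture_amp = 15)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  expect_identical(make_body_phantom(spec)$values,
                   make_body_phantom(spec2)$values)
})
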