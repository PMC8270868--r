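# Shared fixtures, built once per test run and cached. The clinical suite
# and the desk training corpus are expensive; every file that needs them
# goes through these accessors.
.fx <- new.env(parent = emptyenv())

fx_conditions <- function() {
  if (is.null(.fx$cond)) .fx$cond <- desk_conditions()
  .fx$cond
}

fx_table <- function() fx_conditions()$table

# 16-case severe-artefact suite (dental/hip/shoulder cohort)
fx_clinical_suite <- function() {
  if (is.null(.fx$clinical)) .fx$clinical <- clinical_suite(global_seed = 20L)
  .fx$clinical
}

# NMAR corrections for the clinical suite, keyed by case id
fx_clinical_nmar <- function() {
  if (is.null(.fx$clinical_nmar)) {
    cond <- fx_conditions()
    suite <- fx_clinical_suite()
    .fx$clinical_nmar <- lapply(suite$cases_data, function(cs)
      suppressWarnings(nmar_correct(cs$metal_affected, cond$geom, cond$table,
                                    measured_sino = cs$affected_sinogram))$corrected)
    names(.fx$clinical_nmar) <- names(suite$cases_data)
  }
  .fx$clinical_nmar
}

# 200-case desk corpus (25 realizations x 8 shapes, clinical pairing)
fx_desk_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- desk_suite(25L, global_seed = 20L)
  .fx$corpus
}

fx_corpus_nmar <- function() {
  if (is.null(.fx$corpus_nmar)) {
    cond <- fx_conditions()
    corpus <- fx_desk_corpus()
    .fx$corpus_nmar <- lapply(corpus$cases_data, function(cs)
      suppressWarnings(nmar_correct(cs$metal_affected, cond$geom, cond$table,
                                    measured_sino = cs$affected_sinogram))$corrected)
    names(.fx$corpus_nmar) <- names(corpus$cases_data)
  }
  .fx$corpus_nmar
}

# image-domain model trained on the desk corpus (per training seed)
fx_dli_model <- function(seed) {
  key <- paste0("dli_", seed)
  if (is.null(.fx[[key]])) {
    corpus <- fx_desk_corpus()
    cfg <- model_config("image", preset = "desk")
    pairs <- training_pairs(corpus$cases_data[corpus$split$train], cfg,
                            nmar_images = fx_corpus_nmar())
    tc <- train_config("practical", epochs = 10L, steps_per_epoch = 30L,
                       batch_size = 4L, patch_size = 64L, seed = seed)
    .fx[[key]] <- train_model(build_model(cfg, seed = seed), pairs, tc)
  }
  .fx[[key]]
}

# per-case eval RMSE (metal excluded) for a named image list or corrector
case_rmse <- function(cs, img) rmse(cs$metal_inserted_ref, img, !cs$metal_mask)

# a small smooth attenuation image for projector checks
fx_smooth_mu <- function(seed, n = 64, spacing = 3) {
  set.seed(seed)
  x <- (seq_len(n) - 1 - (n - 1) / 2) * spacing
  X <- matrix(x, n, n, byrow = TRUE); Y <- t(X)
  f <- matrix(0.02, n, n)
  for (k in 1:5) {
    cx <- runif(1, -60, 60); cy <- runif(1, -60, 60)
    sg <- runif(1, 12, 35); amp <- runif(1, 0.02, 0.2)
    f <- f + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
  }
  image2d(f, spacing = spacing, unit = "1/cm")
}
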