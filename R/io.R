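#' Read and write images as NIfTI
#'
#' Images travel as 2D NIfTI volumes with the pixel spacing in the header;
#' the unit tag is not part of NIfTI and must be supplied on read.
#'
#' @param img an [image2d()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit unit tag to attach on read.
#' @return `read_image2d` returns an [image2d()].
#' @export
write_image2d <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  n <- RNifti::asNifti(img$values)
  RNifti::pixdim(n) <- c(img$spacing, img$spacing)
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' @rdname write_image2d
#' @export
read_image2d <- function(path, unit = "HU") {
  n <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(n)[1]
  image2d(as.matrix(n[, ]), spacing = sp, unit = unit)
}

#' Phantom specs as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  prims <- lapply(spec$primitives, function(p) {
    p$center <- as.numeric(p$center)
    if (!is.null(p$semiaxes)) p$semiaxes <- as.numeric(p$semiaxes)
    if (!is.null(p$size)) p$size <- as.numeric(p$size)
    if (!is.null(p$vertices)) p$vertices <- lapply(seq_len(nrow(p$vertices)),
                                                   function(i) as.numeric(p$vertices[i, ]))
    p
  })
  yaml::write_yaml(list(grid_size = as.integer(spec$grid_size),
                        spacing = spec$spacing, seed = spec$seed,
                        texture_amp = spec$texture_amp,
                        primitives = prims), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  prims <- lapply(y$primitives, function(p) {
    if (!is.null(p$vertices))
      p$vertices <- do.call(rbind, lapply(p$vertices, as.numeric))
    p
  })
  phantom_spec(prims, grid_size = y$grid_size, spacing = y$spacing,
               seed = y$seed, texture_amp = y$texture_amp)
}

write_case <- function(cs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, cs$case_id)
  write_image2d(cs$metal_free, paste0(base, "_free.nii.gz"))
  write_image2d(cs$metal_inserted, paste0(base, "_inserted.nii.gz"))
  write_image2d(cs$metal_inserted_ref, paste0(base, "_ref.nii.gz"))
  write_image2d(cs$metal_affected, paste0(base, "_affected.nii.gz"))
  write_image2d(image2d(cs$affected_sinogram$values, 1, "line_integral"),
                paste0(base, "_sino.nii.gz"))
  write_image2d(image2d(cs$metal_mask * 1.0, cs$metal_free$spacing, "mask"),
                paste0(base, "_mask.nii.gz"))
  invisible(base)
}

#' Write a dataset manifest as JSON
#'
#' Records case descriptors, per-case seeds, the train/eval split and the
#' global seed, sufficient to rebuild the identical corpus.
#'
#' @param manifest a [build_manifest()] result.
#' @param path output JSON path.
#' @return `read_manifest` returns the `dataset_manifest` (bookkeeping
#'   only; case data are not stored in the JSON).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(cases = manifest$cases, split = manifest$split,
                            counts = as.list(manifest$counts),
                            global_seed = manifest$global_seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cases = j$cases,
                 split = list(train = j$split$train, eval = j$split$eval),
                 counts = unlist(j$counts), global_seed = j$global_seed),
            class = "dataset_manifest")
}
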