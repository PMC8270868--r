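#' Load the material attenuation table
#'
#' Reads a CSV of mass attenuation coefficients sampled on an ascending keV
#' energy grid, one row per (material, energy), with columns `material`,
#' `density_g_cm3`, `energy_keV`, `mu_over_rho_cm2_g` and `kedge_keV`
#' (NA when the material has no absorption edge inside the tabulated range).
#' The packaged default (`inst/extdata/materials_xcom_approx.csv`) is an
#' approximate re-tabulation of standard photon cross-section values for the
#' seven materials the simulator needs (air, soft tissue, bone, iron, gold,
#' titanium, copper) on a 20-point 20-150 keV grid; gold's K-edge at
#' 80.7 keV is declared so interpolation never crosses it.
#'
#' @param path CSV file; default is the packaged table.
#' @return A `material_table` object: list of per-material entries
#'   (`density`, `energy`, `mu_over_rho`, `kedge`) plus the common
#'   `energy_grid`.
#' @export
material_table <- function(path = system.file("extdata",
                                              "materials_xcom_approx.csv",
                                              package = "marct")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("material", "density_g_cm3", "energy_keV", "mu_over_rho_cm2_g")
  if (!all(need %in% names(tab))) stop("material_table: missing columns")
  mats <- split(tab, tab$material)
  required <- c("air", "soft_tissue", "bone", "iron", "gold", "titanium", "copper")
  missing <- setdiff(required, names(mats))
  if (length(missing))
    stop("material_table: required materials absent: ", paste(missing, collapse = ", "))
  out <- lapply(mats, function(s) {
    s <- s[order(s$energy_keV), ]
    if (any(s$mu_over_rho_cm2_g <= 0))
      stop("material_table: non-positive attenuation for ", s$material[1])
    list(density = s$density_g_cm3[1],
         energy = s$energy_keV,
         mu_over_rho = s$mu_over_rho_cm2_g,
         kedge = if (all(is.na(s$kedge_keV))) numeric(0) else s$kedge_keV[1])
  })
  structure(list(materials = out,
                 energy_grid = sort(unique(tab$energy_keV))),
            class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table: %s; %d energies %g-%g keV>\n",
              paste(names(x$materials), collapse = ", "),
              length(x$energy_grid), min(x$energy_grid), max(x$energy_grid)))
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' Looks up the mass attenuation coefficient by log-log interpolation on the
#' tabulated energy grid and multiplies by the nominal density. Declared
#' absorption edges delimit interpolation segments: an energy between the
#' grid points that bracket a K-edge is resolved on the side of the edge it
#' falls on, so the interpolation never smooths across the discontinuity.
#'
#' @param table a [material_table()].
#' @param material material label.
#' @param energy photon energy in keV (vectorized); must lie within the
#'   tabulated range.
#' @return Linear attenuation in 1/cm.
#' @export
attenuation_lookup <- function(table, material, energy) {
  m <- table$materials[[material]]
  if (is.null(m))
    stop("attenuation_lookup: unknown material \"", material, "\"; known: ",
         paste(names(table$materials), collapse = ", "))
  rng <- range(m$energy)
  if (any(energy < rng[1] - 1e-9) || any(energy > rng[2] + 1e-9))
    stop(sprintf("attenuation_lookup: energy outside tabulated range [%g, %g] keV",
                 rng[1], rng[2]))
  energy <- pmin(pmax(energy, rng[1]), rng[2])
  breaks <- c(rng[1] - 1e-9, m$kedge, rng[2] + 1e-9)
  out <- numeric(length(energy))
  for (s in seq_len(length(breaks) - 1L)) {
    in_seg_q <- energy > breaks[s] & energy <= breaks[s + 1L]
    if (!any(in_seg_q)) next
    in_seg_t <- m$energy > breaks[s] & m$energy <= breaks[s + 1L]
    le <- log(m$energy[in_seg_t]); lv <- log(m$mu_over_rho[in_seg_t])
    out[in_seg_q] <- exp(approx(le, lv, xout = log(energy[in_seg_q]), rule = 2)$y)
  }
  # energies exactly at the lower range bound fall outside all (open, closed]
  # segments; fix them up explicitly
  at_lo <- energy <= rng[1]
  if (any(at_lo)) out[at_lo] <- m$mu_over_rho[1]
  m$density * out
}

#' Polychromatic X-ray spectrum
#'
#' A discretized bremsstrahlung-like spectrum for a tube potential of `kvp`
#' kilovolts: photon fluence follows the Kramers form (kvp - E) multiplied
#' by a closed-form inherent-filtration factor exp(-(E0/E)^3) with
#' E0 = 30 keV, which suppresses the soft end of the beam the way a few mm
#' of aluminium would. Weights are normalized to sum to one. Any other
#' spectrum can be supplied as a `spectrum` object or two-column CSV
#' (energy_keV, weight).
#'
#' @param kvp tube potential in kV (default 120).
#' @param n_bins number of energy bins between `e_min` and `kvp`.
#' @param e_min lowest sampled energy (keV).
#' @return A `spectrum` object with fields `energies` (keV, ascending),
#'   `weights` (sum to 1) and `kvp`.
#' @export
spectrum_120kvp <- function(kvp = 120, n_bins = 20L, e_min = 20) {
  if (n_bins < 1L) stop("spectrum_120kvp: need at least one bin")
  e <- seq(e_min, kvp - 1, length.out = n_bins)
  w <- (kvp - e) * exp(-(30 / e)^3)
  spectrum_from(e, w, kvp)
}

#' @rdname spectrum_120kvp
#' @param energies,weights explicit sample energies (keV) and nonnegative
#'   weights for a user-supplied spectrum.
#' @export
spectrum_from <- function(energies, weights, kvp = max(energies)) {
  if (length(energies) < 1L) stop("spectrum: at least one energy required")
  if (is.unsorted(energies, strictly = TRUE)) stop("spectrum: energies must be ascending")
  if (any(weights < 0)) stop("spectrum: negative weights")
  if (max(energies) > kvp + 1e-9) stop("spectrum: energies must not exceed kvp")
  w <- weights / sum(weights)
  structure(list(energies = energies, weights = w, kvp = kvp), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %g kVp, %d bins %g-%g keV, mean %.1f keV>\n",
              x$kvp, length(x$energies), min(x$energies), max(x$energies),
              sum(x$energies * x$weights)))
  invisible(x)
}

#' Hounsfield value of a material at a reference energy
#'
#' HU = 1000 * (mu - mu_water) / mu_water with water approximated by the
#' soft-tissue entry of the table, clipped at `ceiling` (extended HU scale so
#' gold remains representable).
#'
#' @inheritParams attenuation_lookup
#' @param energy reference energy in keV (default 70, the conventional
#'   effective energy of a 120 kVp beam).
#' @param ceiling upper HU clip (default 30000).
#' @return HU value (scalar).
#' @export
material_hu <- function(table, material, energy = 70, ceiling = 30000) {
  mu <- attenuation_lookup(table, material, energy)
  mu_w <- attenuation_lookup(table, "soft_tissue", energy)
  min(1000 * (mu / mu_w - 1), ceiling)
}
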