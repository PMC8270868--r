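# Phantom rendering, implant shapes and attenuation table.

test_that("an empty spec renders uniform air and rendering is deterministic", {
  spec <- phantom_spec(list(), grid_size = 32L, spacing = 2)
  img <- make_body_phantom(spec)
  expect_true(all(img$values == -1000))
  spec2 <- body_phantom_spec("thorax", 64L, 3, seed = 9)
  a <- make_body_phantom(spec2)
  b <- make_body_phantom(spec2)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= -1000 & a$values <= 1500))
})

test_that("rendered ellipse area matches an independent point-in-ellipse scan", {
  spec <- phantom_spec(list(list(geometry = "ellipse", center = c(0, 0),
                                 semiaxes = c(60, 40), rotation = 0, hu = 0)),
                       grid_size = 256L, spacing = 1.5, texture_amp = 0)
  img <- make_body_phantom(spec)
  n_body <- sum(img$values > -500)
  # independent scan over pixel centers in physical coordinates
  n_oracle <- 0L
  for (i in 1:256) for (j in 1:256) {
    x <- (j - 1 - 127.5) * 1.5; y <- (127.5 - (i - 1)) * 1.5
    if ((x / 60)^2 + (y / 40)^2 <= 1) n_oracle <- n_oracle + 1L
  }
  expect_equal(n_body, n_oracle)
})

test_that("primitives outside the grid are rejected with the primitive named", {
  expect_error(phantom_spec(list(list(geometry = "ellipse", center = c(180, 0),
                                      semiaxes = c(30, 30), hu = 0)),
                            grid_size = 128L, spacing = 1.5),
               "primitive 1")
})

test_that("metal shape masks scale quadratically and are deterministic", {
  tab <- fx_table()
  s1 <- make_metal_shape(1, "titanium", c(128, 128), 256L, 1.5, scale = 1, table = tab)
  s2 <- make_metal_shape(1, "titanium", c(128, 128), 256L, 1.5, scale = 2, table = tab)
  ratio <- sum(s2$mask) / sum(s1$mask)
  expect_lt(abs(ratio - 4), 0.15 * 4)
  s1b <- make_metal_shape(1, "titanium", c(128, 128), 256L, 1.5, scale = 1, table = tab)
  expect_identical(s1$mask, s1b$mask)
})

test_that("invalid shape ids, materials and anchors are rejected", {
  tab <- fx_table()
  expect_error(make_metal_shape(9, "iron", c(10, 10), 64L, 2, table = tab), "shape_id")
  expect_error(make_metal_shape(1, "bone", c(10, 10), 64L, 2, table = tab), "material")
  expect_error(make_metal_shape(1, "iron", c(500, 10), 64L, 2, table = tab), "anchor")
})

test_that("every shape and template renders a usable mask at desk scale", {
  tab <- fx_table()
  for (sid in 1:8) {
    s <- make_metal_shape(sid, "iron", c(64, 64), 128L, 2, scale = 0.8, table = tab)
    expect_gte(sum(s$mask), 4)
  }
  for (tmpl in c("thorax", "head", "pelvis"))
    expect_s3_class(make_body_phantom(body_phantom_spec(tmpl, 128L, 2)), "image2d")
})

test_that("insert_metal writes the HU-definition value under the mask only", {
  tab <- fx_table()
  body <- make_body_phantom(body_phantom_spec("thorax", 128L, 2, seed = 3))
  shape <- make_metal_shape(3, "titanium", c(64, 64), 128L, 2, table = tab)
  out <- insert_metal(body, shape, tab, energy = 70)
  # independent evaluation of HU = 1000 (mu/mu_water - 1)
  mu_ti <- attenuation_lookup(tab, "titanium", 70)
  mu_w <- attenuation_lookup(tab, "soft_tissue", 70)
  hu_expect <- min(1000 * (mu_ti / mu_w - 1), 30000)
  expect_true(all(out$values[shape$mask] == hu_expect))
  expect_identical(out$values[!shape$mask], body$values[!shape$mask])
})

test_that("attenuation lookups hit tabulated grid points exactly", {
  tab <- fx_table()
  m <- tab$materials$iron
  for (k in c(1, 5, length(m$energy)))
    expect_equal(attenuation_lookup(tab, "iron", m$energy[k]),
                 m$density * m$mu_over_rho[k], tolerance = 1e-12)
  expect_error(attenuation_lookup(tab, "iron", 5), "range")
  expect_error(attenuation_lookup(tab, "adamantium", 70), "unknown")
})

test_that("mid-segment lookups agree with an independent log-log interpolation", {
  tab <- fx_table()
  m <- tab$materials$copper
  e1 <- m$energy[3]; e2 <- m$energy[4]; emid <- sqrt(e1 * e2)
  lv <- exp(log(m$mu_over_rho[3]) +
              (log(emid) - log(e1)) / (log(e2) - log(e1)) *
              (log(m$mu_over_rho[4]) - log(m$mu_over_rho[3])))
  expect_equal(attenuation_lookup(tab, "copper", emid), m$density * lv,
               tolerance = 1e-10)
  got <- attenuation_lookup(tab, "copper", emid)
  expect_true(got < m$density * m$mu_over_rho[3] &&
                got > m$density * m$mu_over_rho[4])
})

test_that("tabulated values decrease with energy except across gold's K-edge", {
  tab <- fx_table()
  for (lbl in names(tab$materials)) {
    m <- tab$materials[[lbl]]
    if (!length(m$kedge)) {
      expect_true(all(diff(m$mu_over_rho) < 0), label = lbl)
    } else {
      lo <- m$energy < m$kedge; hi <- m$energy > m$kedge
      expect_true(all(diff(m$mu_over_rho[lo]) < 0))
      expect_true(all(diff(m$mu_over_rho[hi]) < 0))
      # the jump across the edge goes up
      expect_gt(m$mu_over_rho[hi][1], tail(m$mu_over_rho[lo], 1))
    }
  }
  expect_equal(tab$materials$gold$kedge, 80.7, tolerance = 0.1)
  # interpolation never crosses the edge: values just below/above differ a lot
  below <- attenuation_lookup(tab, "gold", 80.69)
  above <- attenuation_lookup(tab, "gold", 80.71)
  expect_gt(above / below, 2)
})

test_that("the 120 kVp spectrum is a normalized plausible bremsstrahlung shape", {
  sp <- spectrum_120kvp()
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
  expect_lte(max(sp$energies), 120)
  mean_e <- sum(sp$energies * sp$weights)
  expect_gt(mean_e, 50); expect_lt(mean_e, 80)
  expect_error(spectrum_from(c(30, 20), c(1, 1)), "ascending")
  expect_error(spectrum_from(c(20, 130), c(1, 1), kvp = 120), "exceed")
})
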