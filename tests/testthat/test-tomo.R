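# Fan-beam projection, polychromatic attenuation, noise and FBP.

test_that("projection of nothing is nothing and the projector is linear", {
  geom <- fan_geometry(n_views = 24, n_bins = 32, fov = 200)
  z <- image2d(matrix(0, 32, 32), 4, "1/cm")
  expect_true(all(forward_project_mono(z, geom)$values == 0))
  img <- fx_smooth_mu(3, 32, 4)
  a <- forward_project_mono(img, geom)$values
  img3 <- image2d(3 * img$values, 4, "1/cm")
  expect_lt(max(abs(forward_project_mono(img3, geom)$values - 3 * a)), 1e-10)
  expect_error(forward_project_mono(image2d(matrix(0, 8, 8), 4, "HU"), geom),
               "convert")
})

test_that("central rays through a uniform disc match the analytic chord", {
  # r = 50 mm, mu = 0.2 /cm -> central line integral 2 * 5 cm * 0.2 = 2.0
  n <- 128; s <- 2
  x <- (seq_len(n) - 1 - (n - 1) / 2) * s
  X <- matrix(x, n, n, byrow = TRUE); Y <- t(X)
  disc <- image2d(ifelse(X^2 + Y^2 <= 50^2, 0.2, 0), s, "1/cm")
  geom <- fan_geometry(n_views = 60, n_bins = 129, fov = 280)
  sino <- forward_project_mono(disc, geom)$values
  central <- sino[, 65] # odd bin count: middle bin is the isocenter ray
  expect_lt(abs(mean(central) - 2.0), 0.02)
  expect_lt(sd(central), 0.02) # rotational symmetry
})

test_that("polychromatic projection reduces to mono for one energy and obeys
           the closed-form two-energy sublinearity", {
  tab <- fx_table()
  geom <- fan_geometry(n_views = 16, n_bins = 24, fov = 200)
  n <- 24; s <- 8
  dens <- matrix(0, n, n); dens[10:14, 10:14] <- 1
  mono70 <- spectrum_from(70, 1)
  p_poly <- forward_project_poly(list(soft_tissue = dens), mono70, tab, geom,
                                 spacing = s)$values
  mu70 <- attenuation_lookup(tab, "soft_tissue", 70)
  p_mono <- forward_project_mono(image2d(dens * mu70, s, "1/cm"), geom)$values
  expect_lt(max(abs(p_poly - p_mono)), 1e-10)
  # empty maps
  expect_true(all(forward_project_poly(list(), mono70, tab, geom)$values == 0))
  # closed form: w = (.5,.5), mu = (.2,.1) per unit length
  p1 <- -log(0.5 * exp(-0.2) + 0.5 * exp(-0.1))
  p2 <- -log(0.5 * exp(-0.4) + 0.5 * exp(-0.2))
  expect_equal(p1, 0.14875, tolerance = 1e-4)
  expect_equal(p2, 0.29501, tolerance = 1e-4)
  expect_lt(p2, 2 * p1) # beam hardening is sublinear in path length
})

test_that("poisson noise is seeded, vanishes at huge flux, and has the right mean", {
  geom <- fan_geometry(n_views = 8, n_bins = 16, fov = 200)
  sino <- sinogram(matrix(1, 8, 16), geom)
  n1 <- add_poisson_noise(sino, 1e12, seed = 4)
  expect_lt(max(abs(n1$values - sino$values)), 1e-3)
  a <- add_poisson_noise(sino, 1e4, seed = 9)
  b <- add_poisson_noise(sino, 1e4, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(add_poisson_noise(sino, -5), "n0")
  # empirical mean of counts for p = 1, N0 = 1e4 over 10k draws vs 1e4/e
  big <- sinogram(matrix(1, 100, 100), fan_geometry(100, 100, fov = 200))
  noisy <- add_poisson_noise(big, 1e4, seed = 11)
  counts <- 1e4 * exp(-noisy$values)
  expect_lt(abs(mean(counts) - 1e4 * exp(-1)) / (1e4 * exp(-1)), 0.01)
})

test_that("fbp is linear and zero in, zero out", {
  geom <- fan_geometry(n_views = 48, n_bins = 64, fov = 200)
  z <- sinogram(matrix(0, 48, 64), geom)
  expect_true(all(fbp(z, 32L, 4)$values == 0))
  img <- fx_smooth_mu(8, 32, 4)
  s1 <- forward_project_mono(img, geom)
  r1 <- fbp(s1, 32L, 4)$values
  r2 <- fbp(sinogram(2 * s1$values, geom), 32L, 4)$values
  expect_lt(max(abs(r2 - 2 * r1)), 1e-8)
})

test_that("project-then-reconstruct recovers a uniform disc to a few percent", {
  n <- 128; s <- 2
  x <- (seq_len(n) - 1 - (n - 1) / 2) * s
  X <- matrix(x, n, n, byrow = TRUE); Y <- t(X)
  disc <- image2d(ifelse(X^2 + Y^2 <= 50^2, 0.02 * 10, 0), s, "1/cm")
  geom <- fan_geometry(n_views = 360, n_bins = 367, fov = 280)
  rec <- fbp(forward_project_mono(disc, geom), n, s)
  inner <- X^2 + Y^2 <= (0.8 * 50)^2
  expect_lt(abs(mean(rec$values[inner]) - 0.2) / 0.2, 0.05)
})

test_that("HU/attenuation conversion fixes water and air and round-trips", {
  tab <- fx_table()
  img <- image2d(matrix(c(-1000, 0, 50, 100), 2), 2, "HU")
  mu <- hu_to_mu(img, 70, tab)
  muw <- attenuation_lookup(tab, "soft_tissue", 70)
  expect_equal(mu$values[1, 1], 0)
  expect_equal(mu$values[1, 2], muw * 1.05, tolerance = 1e-12)
  expect_equal(mu$values[2, 1], muw, tolerance = 1e-12)
  set.seed(2)
  hu <- matrix(runif(64, -1000, 100), 8)
  rt <- mu_to_hu(hu_to_mu(image2d(hu, 2, "HU"), 70, tab), 70, tab)
  expect_lt(max(abs(rt$values - hu)), 1e-9)
  # above the soft-tissue branch the map is continuous and invertible too
  hu2 <- matrix(runif(64, 100, 3000), 8)
  rt2 <- mu_to_hu(hu_to_mu(image2d(hu2, 2, "HU"), 70, tab), 70, tab)
  expect_lt(max(abs(rt2$values - hu2)), 1e-6)
})

test_that("geometry constructor validates its arguments", {
  expect_error(fan_geometry(n_views = 1), ">= 2")
  expect_error(fan_geometry(fov = 1300, sad = 600), "fov")
  g <- fan_geometry(100, 64, fov = 250)
  expect_equal(length(g$gammas), 64)
  # centered detector: middle two bins straddle zero symmetrically
  expect_equal(g$gammas[32], -g$gammas[33], tolerance = 1e-14)
})
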