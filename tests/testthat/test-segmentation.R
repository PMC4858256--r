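test_that("a step edge is assigned to its first bright sample", {
  vol <- array(0, dim = c(16, 16, 80))
  vol[, , 40:80] <- 1
  ly <- segment_layers(vol)
  expect_true(all(ly$z_ilm == 40))
})

test_that("segmentation is equivariant under a global depth shift", {
  base <- array(0, dim = c(12, 12, 90))
  base[, , 30:90] <- 1
  base[, , 60:64] <- 2.2
  shift <- array(0, dim = c(12, 12, 90))
  shift[, , 37:90] <- 1
  shift[, , 67:71] <- 2.2
  a <- segment_layers(base)
  b <- segment_layers(shift)
  expect_true(all(b$z_ilm - a$z_ilm == 7))
  expect_true(all(b$z_alc - a$z_alc == 7))
})

test_that("a tilted noisy ILM plane is recovered within one depth sample", {
  nx <- 96; ny <- 96
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  zi <- 20 + 8 * (xg - 1) / (nx - 1) + 5 * (yg - 1) / (ny - 1)
  spec <- scene_spec(nx = nx, ny = ny, nz = 96, z_ilm = zi, z_alc = zi + 32,
                     noise_sd = 0.1, seed = 9)  # noise 10% of the step height
  st <- structural_volume(generate_volume(spec)$volume)
  ly <- segment_layers(st)
  expect_gte(mean(abs(ly$z_ilm - ceiling(zi)) <= 1), 0.99)
})

test_that("manual overrides are returned verbatim", {
  vol <- array(0, dim = c(10, 10, 40))
  vol[, , 15:40] <- 1
  ov <- matrix(17.25, 10, 10)
  ly <- segment_layers(vol, override = list(z_ilm = ov))
  expect_identical(ly$z_ilm, ov)
  expect_true(ly$override$z_ilm)
  # sparse control points on a plane reproduce the plane
  pts <- expand.grid(x = c(1, 5, 10), y = c(1, 5, 10))
  pts$z <- 5 + 0.5 * pts$x + 0.25 * pts$y
  surf <- surface_from_points(pts, 10, 10)
  grid <- expand.grid(x = 1:10, y = 1:10)
  expect_equal(as.vector(surf), 5 + 0.5 * grid$x + 0.25 * grid$y,
               tolerance = 1e-6)
})

test_that("segmentation fails loudly when too many A-scans lack a boundary", {
  flat <- array(1, dim = c(12, 12, 40))  # featureless: no gradient anywhere
  expect_error(segment_layers(flat), "failed on")
})

test_that("disc margin from Bruch's membrane termini matches the analytic circle", {
  # disc radius chosen so the margin is a 30 px circle
  spec <- scene_spec(nx = 96, ny = 96, nz = 96, z_ilm = 20, z_alc = 52,
                     disc_radius_mm = 30 / 96 * 2.4, noise_sd = 0.05, seed = 14)
  st <- structural_volume(generate_volume(spec)$volume)
  ly <- delineate_disc_margin(st, segment_layers(st), extent_mm = 2.4)
  expect_lt(abs(ly$area_onh_px - pi * 30^2) / (pi * 30^2), 0.05)
  expect_equal(ly$area_onh_px, sum(ly$disc_mask))
  expect_equal(ly$area_onh_mm2, ly$area_onh_px * (2.4 / 96)^2)
})

test_that("a scene without a Bruch's membrane gap is signalled as disc-free", {
  # continuous band everywhere: no termini to fit
  vol <- array(0, dim = c(48, 48, 64))
  vol[, , 16:64] <- 1
  vol[, , 40:44] <- 2.2
  ly <- segment_layers(vol)
  expect_error(delineate_disc_margin(vol, ly), "Bruch's membrane")
})

test_that("manual polygon contours rasterize like the independent oracle", {
  vol <- array(0, dim = c(24, 24, 40))
  vol[, , 12:40] <- 1
  ly <- segment_layers(vol)
  poly <- data.frame(x = c(5.5, 18.5, 18.5, 5.5), y = c(5.5, 5.5, 18.5, 18.5))
  ly <- delineate_disc_margin(vol, ly, contour = poly)
  expect_equal(ly$area_onh_px, polygon_area_oracle(poly, 24, 24))
})

test_that("the pre-laminar mask counts voxels by the half-open depth rule", {
  mk_layers <- function(zi, za, disc, nz) {
    structure(list(z_ilm = zi, z_alc = za, disc_mask = disc, nz = nz),
              class = "onh_layer_model")
  }
  # constant surfaces 10 and 20 over a 50 px disc -> 50 * 10 voxels
  disc <- matrix(FALSE, 10, 10); disc[1:5, 1:10] <- TRUE
  ly <- mk_layers(matrix(10, 10, 10), matrix(20, 10, 10), disc, 32)
  expect_equal(sum(prelc_mask(ly)), 50 * 10)
  # empty slab where the surfaces touch
  zi <- matrix(10, 10, 10); za <- matrix(20, 10, 10)
  zi[3, 3] <- za[3, 3] <- 15
  ly2 <- mk_layers(zi, za, matrix(TRUE, 10, 10), 32)
  expect_equal(sum(prelc_mask(ly2)[3, 3, ]), 0)
  # random integer surfaces against a brute-force triple loop and the
  # closed-form count sum(z_alc - z_ilm)
  set.seed(41)
  zi <- matrix(sample(3:10, 64, TRUE), 8, 8)
  za <- zi + matrix(sample(0:8, 64, TRUE), 8, 8)
  disc <- matrix(runif(64) < 0.6, 8, 8)
  ly3 <- mk_layers(zi, za, disc, 24)
  m <- prelc_mask(ly3)
  cnt <- 0L
  for (x in 1:8) for (y in 1:8) for (z in 1:24) {
    if (disc[x, y] && z >= zi[x, y] && z < za[x, y]) cnt <- cnt + 1L
  }
  expect_equal(sum(m), cnt)
  expect_equal(sum(m), sum((za - zi)[disc]))
})
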