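mk_scaled_flow <- function(arr) {
  structure(list(flow = arr, scaled = TRUE, scale_factor = 1,
                 mode = "max", all_zero = all(arr == 0)),
            class = "onh_flow")
}

test_that("the en-face MIP takes the slab maximum and flags empty slabs", {
  d <- c(6, 6, 8)
  # single-slice slab: projection equals that slice
  set.seed(51)
  f <- array(runif(prod(d), 0, 255), dim = d)
  m1 <- array(FALSE, dim = d); m1[, , 4] <- TRUE
  expect_equal(mip_enface(mk_scaled_flow(f), m1)$mip, f[, , 4])
  # single impulse inside the slab
  f2 <- array(0, dim = d)
  f2[3, 5, 6] <- 42
  m2 <- array(TRUE, dim = d)
  ef <- mip_enface(mk_scaled_flow(f2), m2)
  expect_equal(ef$mip[3, 5], 42)
  expect_equal(sum(ef$mip), 42)
  # random slab vs loop oracle, plus MIP dominance and empty-slab flag
  set.seed(52)
  m3 <- array(runif(prod(d)) < 0.5, dim = d)
  ef3 <- mip_enface(mk_scaled_flow(f), m3)
  expect_equal(ef3$mip, mip_loop_oracle(f, m3))
  for (z in seq_len(d[3])) {
    sel <- m3[, , z]
    expect_true(all(ef3$mip[sel] >= f[, , z][sel]))
  }
  expect_identical(ef3$empty_slab, apply(m3, c(1, 2), function(v) !any(v)))
  expect_error(mip_enface(mk_scaled_flow(f), m3[, , 1:4]), "dimensions")
})

test_that("vesselness vanishes on flat fields and ignores constant offsets", {
  expect_true(all(vesselness(matrix(3.7, 32, 32)) == 0))
  set.seed(53)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(vesselness(img), vesselness(img + 50), tolerance = 1e-10)
})

test_that("the scale attaining the maximum response tracks the ridge width", {
  nx <- 64
  xg <- matrix(seq_len(nx), nx, nx)
  for (w in c(2, 3)) {
    ridge <- 200 * exp(-(xg - 32.5)^2 / (2 * w^2))
    # one fixed c keeps the per-scale maxima comparable
    resp <- vapply(1:5, function(s) {
      max(vesselness(ridge, scales = s, c = 30))
    }, numeric(1))
    expect_lte(abs(which.max(resp) - w), 1)
    V <- vesselness(ridge, scales = 1:4)
    expect_gt(mean(V[32:33, ]), mean(V[c(8, 56), ]))
  }
})

test_that("vesselness commutes with axis-aligned 90-degree rotation", {
  rot90 <- function(m) t(m[nrow(m):1, ])
  set.seed(54)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  expect_equal(vesselness(rot90(img)), rot90(vesselness(img)),
               tolerance = 1e-10)
})

test_that("binarization follows the documented threshold rules", {
  expect_equal(sum(binarize_vessels(matrix(0, 8, 8), method = "fixed")), 0)
  # bimodal map under otsu selects the upper mode, matching the
  # exhaustive-search oracle
  set.seed(55)
  V <- matrix(sample(c(0.1, 0.9), 400, TRUE, prob = c(0.6, 0.4)), 20, 20)
  mk <- binarize_vessels(V, method = "otsu")
  expect_equal(mk, V == 0.9, ignore_attr = TRUE)
  expect_equal(attr(mk, "threshold"), otsu_oracle(as.vector(V)),
               tolerance = 0.05)
  # strict fixed threshold at zero keeps exactly the positive pixels
  V2 <- matrix(c(0, 0.3, 0, 0.8), 2, 2)
  expect_equal(binarize_vessels(V2, method = "fixed", t = 0), V2 > 0,
               ignore_attr = TRUE)
  # degenerate map falls back to fixed with a warning
  expect_warning(binarize_vessels(matrix(0.4, 8, 8), method = "otsu"),
                 "degenerate")
  expect_error(binarize_vessels(matrix(2, 4, 4), method = "fixed"), "0, 1")
})

test_that("hysteresis masks nest between the strong and weak thresholds", {
  set.seed(56)
  V <- matrix(runif(900), 30, 30)
  h <- binarize_vessels(V, method = "hysteresis")
  o <- binarize_vessels(V, method = "otsu")
  thr <- attr(o, "threshold")
  expect_true(all(h[o]))                   # grown mask contains all seeds
  expect_true(all(V[unname(h)] > thr / 2)) # and stays above the weak level
})

test_that("detected vessels overlap ground truth with Dice >= 0.7", {
  spec <- small_scene(n_vessels = 8, delta = 0.8, seed = 61,
                      nx = 96, ny = 96, nz = 96, radius_px = 2)
  sim <- generate_volume(spec)
  flow <- scale_to_dynamic_range(compute_flow(sim$volume))
  st <- structural_volume(sim$volume)
  layers <- delineate_disc_margin(st, segment_layers(st), extent_mm = 2.4)
  ef <- mip_enface(flow, prelc_mask(layers))
  ef <- binarize_vessels(vesselness(ef), roi = layers$disc_mask)
  dice <- dice_coef(ef$vessel_mask & layers$disc_mask,
                    sim$truth$vessel_enface & sim$truth$disc_mask)
  expect_gte(dice, 0.7)
})
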