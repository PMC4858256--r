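test_that("static-only, noise-free scenes are identical across repeats and flow-free", {
  spec <- scene_spec(nx = 16, ny = 16, nz = 32, z_ilm = 8, z_alc = 20,
                     noise_sd = 0, seed = 4)
  sim <- generate_volume(spec)
  dat <- sim$volume$data
  for (k in 2:4) expect_identical(dat[, , , k], dat[, , , 1])
  flow <- compute_flow(sim$volume)
  expect_true(all(flow$flow == 0))
  expect_true(flow$all_zero)
})

test_that("decorrelation appears exactly on the vessel mask when noise is zero", {
  spec <- scene_spec(nx = 32, ny = 32, nz = 48, z_ilm = 10, z_alc = 30,
                     vessels = list(list(y0 = 16, wobble_px = 0, periods = 1,
                                         phase = 0, radius_px = 2, delta = 1)),
                     noise_sd = 0, seed = 4)
  sim <- generate_volume(spec)
  dat <- sim$volume$data
  differs <- Mod(dat[, , , 2] - dat[, , , 1]) > 0
  expect_identical(differs, sim$truth$vessel_mask)
  expect_gt(sum(differs), 0)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- small_scene(seed = 21, nx = 32, ny = 32, nz = 32)
  a <- generate_volume(spec)
  b <- generate_volume(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  # the derived statistic of the spec example: mean |C_{i+1} - C_i| on vessels
  f <- compute_flow(a$volume)$flow
  g <- compute_flow(b$volume)$flow
  expect_identical(mean(f[a$truth$vessel_mask]), mean(g[b$truth$vessel_mask]))
})

test_that("mean vessel flow is monotone nondecreasing in decorrelation delta", {
  flows <- vapply(c(0.2, 0.5, 0.8, 1.0), function(d) {
    spec <- small_scene(n_vessels = 5, delta = d, seed = 33,
                        nx = 48, ny = 48, nz = 48)
    sim <- generate_volume(spec)
    mean(compute_flow(sim$volume)$flow[sim$truth$vessel_mask])
  }, numeric(1))
  expect_true(all(diff(flows) >= 0))
})

test_that("scene invariants are enforced", {
  expect_error(scene_spec(nx = 16, ny = 16, nz = 32, n_repeats = 1),
               "n_repeats")
  expect_error(scene_spec(nx = 16, ny = 16, nz = 32, z_ilm = 20, z_alc = 10),
               "z_ilm < z_alc")
  expect_error(scene_spec(nx = 16, ny = 16, nz = 32, disc_radius_mm = 1.3),
               "disc_radius_mm")
  expect_error(
    scene_spec(nx = 16, ny = 16, nz = 32,
               vessels = list(list(y0 = 8, wobble_px = 0, periods = 1,
                                   phase = 0, radius_px = 2, delta = 1.5))),
    "delta")
})

test_that("simulated cohorts honour the configured moments and correlations", {
  big <- generate_cohort(
    cohort_spec(n = c(normal = 10000, POAG = 10000, NTG = 10000), seed = 7))
  nrm <- dplyr::filter(big, group == "normal")
  # law of large numbers: sample mean within 3 SE of the configured 0.33
  expect_lt(abs(mean(nrm$flux) - 0.33), 3 * 0.04 / sqrt(10000))
  # configured correlation r = sqrt(R^2) = 0.4 between POAG flux and VF MD
  poag <- dplyr::filter(big, group == "POAG")
  expect_lt(abs(cor(poag$flux, poag$vf_md) - 0.4), 0.03)
  expect_true(all(big$sbp >= big$dbp))
  expect_true(all(big$flux >= 0 & big$flux <= 1))
})

test_that("cohort generation is deterministic and rejects invalid specs", {
  spec <- cohort_spec(n = c(normal = 5, POAG = 5, NTG = 5), seed = 12)
  expect_identical(generate_cohort(spec), generate_cohort(spec))

  mom <- cohort_default_moments <- onhperf:::cohort_default_moments()
  mom$normal$sd["flux"] <- 0
  expect_error(cohort_spec(moments = mom), "SDs")

  bad <- onhperf:::cohort_default_correlations()
  bad$normal["flux", "vessel_area_density"] <- 0.95
  bad$normal["vessel_area_density", "flux"] <- 0.95
  bad$normal["flux", "normalized_flux"] <- 0.95
  bad$normal["normalized_flux", "flux"] <- 0.95
  bad$normal["vessel_area_density", "normalized_flux"] <- -0.95
  bad$normal["normalized_flux", "vessel_area_density"] <- -0.95
  expect_error(cohort_spec(correlations = bad), "positive semi-definite")
})
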