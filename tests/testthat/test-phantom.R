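test_that("phantom generation is a pure function of spec and seed", {
  a <- make_brain_phantom(small_phantom_spec())
  b <- make_brain_phantom(small_phantom_spec())
  expect_identical(a$maps, b$maps)
  expect_identical(a$masks, b$masks)
  sa <- render_series(a, "dwi", seed = 4)
  sb <- render_series(b, "dwi", seed = 4)
  expect_identical(sa$volumes, sb$volumes)
  sc <- render_series(a, "dwi", seed = 5)
  expect_false(identical(sa$volumes, sc$volumes))
})

test_that("phantom truth maps are internally consistent", {
  truth <- make_brain_phantom(small_phantom_spec())
  inb <- truth$masks$brain
  # MVD truth satisfies Q^3/(4.725 D) identically
  expect_equal(truth$maps$mvd[inb],
               truth$maps$q[inb]^3 / (4.725 * 800) * 1e6, tolerance = 1e-13)
  # rate-change truth inverts the vessel-size relations: recomputing VSI and
  # Q from the rate maps returns the stated truth
  dwc <- characteristic_frequency(truth$spec$physics)
  ratio <- truth$maps$delta_r2_star[inb] / truth$maps$delta_r2[inb]
  vsi_back <- 0.424 * sqrt(800 / dwc) * ratio^1.5
  expect_equal(vsi_back, truth$maps$vsi[inb], tolerance = 1e-10)
  q_back <- truth$maps$delta_r2[inb] / truth$maps$delta_r2_star[inb]^(2 / 3)
  expect_equal(q_back, truth$maps$q[inb], tolerance = 1e-10)
  # lesion straddles the published cutoffs
  expect_gt(mean(truth$maps$vsi[truth$masks$lesion]), 10)
  expect_lt(mean(truth$maps$vsi[truth$masks$contra_subcortex]), 10)
  expect_lt(mean(truth$maps$adc[truth$masks$lesion]), 650)
  expect_gt(mean(truth$maps$adc[truth$masks$contra_subcortex]), 650)
})

test_that("a zero-size lesion leaves the hemispheres statistically identical", {
  truth <- make_brain_phantom(small_phantom_spec(lesion_radius = 0))
  expect_equal(sum(truth$masks$lesion), 0)
  expect_equal(mean(truth$maps$adc[truth$masks$ipsi_subcortex]),
               mean(truth$maps$adc[truth$masks$contra_subcortex]))
  expect_equal(mean(truth$maps$q[truth$masks$ipsi_subcortex]),
               mean(truth$maps$q[truth$masks$contra_subcortex]))
})

test_that("inconsistent lesion specifications are rejected", {
  expect_error(phantom_spec(adc_lesion = 700), "adc_lesion")
  expect_error(phantom_spec(adc_normal = 600))
  expect_error(phantom_spec(snr = 0))
})

test_that("rendered series follow the protocol axes and Rician noise model", {
  truth <- make_brain_phantom(small_phantom_spec())
  dwi <- render_series(truth, "dwi", snr = Inf)
  expect_equal(dwi$axis_values, c(100, 200, 400, 600, 800, 1000))
  expect_equal(dwi$axis_kind, "bvalue")
  msme <- render_series(truth, "msme_pre", snr = Inf)
  expect_equal(msme$axis_values, seq(8, 160, by = 8))
  mege <- render_series(truth, "mege_pre", snr = Inf)
  expect_equal(mege$axis_values, seq(3, 59, by = 4))
  expect_error(render_series(truth, "bold"), "unknown protocol")

  # background magnitude noise is Rayleigh with mean sigma * sqrt(pi/2)
  noisy <- render_series(truth, "dwi", snr = 40, seed = 11)
  bgsel <- !truth$masks$brain
  sigma <- truth$spec$s0 / 40
  bgvals <- noisy$volumes[, , , 1][bgsel]
  expect_equal(mean(bgvals), sigma * sqrt(pi / 2), tolerance = 0.02)

  # noiseless series invert exactly through the fitting stage
  f <- compute_rate_map(msme)
  inb <- truth$masks$brain
  expect_equal(f$values[inb], truth$maps$r2_pre[inb], tolerance = 1e-6)
})

test_that("tubular phantoms expose exact masks and per-segment truth", {
  segs <- data.frame(x0 = c(10, 2), y0 = c(10, 14), z0 = c(0, 10),
                     x1 = c(10, 18), y1 = c(10, 14), z1 = c(20, 10),
                     radius = c(3, 6))
  tree <- make_vascular_tree(c(20, 20, 20), 1, segs, noise_sd = 2, seed = 2)
  expect_equal(dim(tree$mask), c(20, 20, 20))
  expect_true(all(tree$segments$n_voxels > 0))
  # per-segment thickness ordering follows the true radii
  th <- local_thickness(tree$mask, voxel_size = 1)
  m1 <- mean(th$values[tree$labels == 1], na.rm = TRUE)
  m2 <- mean(th$values[tree$labels == 2], na.rm = TRUE)
  expect_lt(m1, m2)
  expect_error(make_vascular_tree(c(20, 20, 20), 1,
    data.frame(x0 = 1, y0 = 1, z0 = 1, x1 = 2, y1 = 2, z1 = 2, radius = 0)),
    "radius")
  expect_error(make_vascular_tree(c(20, 20, 20), 1,
    data.frame(x0 = -5, y0 = 1, z0 = 1, x1 = 2, y1 = 2, z1 = 2, radius = 1)),
    "inside")
  # background-only volume: thresholding the intensity gives an empty mask
  bg <- make_vascular_tree(c(12, 12, 12), 1,
    data.frame(x0 = 6, y0 = 6, z0 = 0, x1 = 6, y1 = 6, z1 = 12,
               radius = 1))
  expect_warning(vm <- threshold_vasculature(bg$intensity * 0 + 10, 50),
                 "empty")
  expect_equal(sum(vm$mask), 0)
})
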