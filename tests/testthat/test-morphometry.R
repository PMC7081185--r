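test_that("thresholding delineates vasculature and records the threshold", {
  tree <- make_vascular_tree(c(24, 24, 24), 1,
    data.frame(x0 = 12, y0 = 12, z0 = 0, x1 = 12, y1 = 12, z1 = 24,
               radius = 3))
  vm <- threshold_vasculature(tree$intensity, 50, voxel_size = 1)
  expect_equal(sum(vm$mask), sum(tree$mask))
  expect_equal(vm$threshold_used, 50)
  # threshold at the minimum -> full volume
  vol <- array(runif(27, 1, 2), c(3, 3, 3))
  expect_true(all(threshold_vasculature(vol, min(vol))$mask))
  # all intensities below threshold -> empty mask with a warning
  expect_warning(vm0 <- threshold_vasculature(array(c(0, 1), c(2, 1, 1)), 2,
                                              voxel_size = 1),
                 "empty")
  expect_equal(sum(vm0$mask), 0)
})

test_that("an isolated voxel gets the minimal two-voxel thickness", {
  # distance-ridge convention: inscribed radius = distance to the nearest
  # background centre, so a lone voxel reports a diameter of 2 voxels
  m <- array(FALSE, c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  th <- local_thickness(m, voxel_size = 1)
  expect_equal(th$values[4, 4, 4], 2)
  expect_true(all(is.na(th$values[m == FALSE])))
})

test_that("thickness of canonical solids matches their diameters", {
  ball <- digital_ball(21, 8)
  th <- local_thickness(ball, voxel_size = 1)
  expect_lt(abs(max(th$values, na.rm = TRUE) - 16), 1)

  cyl <- digital_cylinder(15, 15, 24, 5)
  thc <- local_thickness(cyl, voxel_size = 1)
  expect_lt(abs(mean(thc$values, na.rm = TRUE) - 10), 1)
})

test_that("fast local thickness equals the exhaustive maximal-sphere oracle", {
  masks <- list(
    digital_ball(15, 5),
    digital_cylinder(14, 14, 18, 4),
    {
      # two overlapping tubes of different radius
      t2 <- make_vascular_tree(c(20, 20, 20), 1, data.frame(
        x0 = c(10, 2), y0 = c(10, 10), z0 = c(0, 10),
        x1 = c(10, 18), y1 = c(10, 10), z1 = c(20, 10),
        radius = c(3, 5)))
      t2$mask
    },
    {
      set.seed(8)
      m <- array(runif(12^3) > 0.45, c(12, 12, 12))  # speckle
      m[1, 1, 1] <- TRUE
      m
    }
  )
  for (m in masks) {
    fast <- local_thickness(m, voxel_size = 1)$values
    slow <- oracle_local_thickness(m)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("thickness respects the distance-transform bound and dilation monotonicity", {
  tree <- make_vascular_tree(c(20, 20, 20), 1, data.frame(
    x0 = 4, y0 = 4, z0 = 0, x1 = 16, y1 = 16, z1 = 20, radius = 4))
  m <- tree$mask
  th <- local_thickness(m, voxel_size = 1)$values
  d2 <- array(vsimri:::cpp_sq_edt(as.integer(m), dim(m)), dim(m))
  edt <- sqrt(d2)
  # every voxel is covered at least by its own inscribed sphere and at most
  # by the largest inscribed sphere anywhere; the ridge attains the bound
  expect_true(all(th[m] >= 2 * edt[m] - 1e-9))
  expect_true(all(th[m] <= 2 * max(edt[m]) + 1e-9))
  expect_equal(max(th[m]), 2 * max(edt[m]))
  # dilate by one voxel (6-neighborhood)
  dil <- m
  idx <- which(m, arr.ind = TRUE)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    sh <- sweep(idx, 2, s, "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= 20 & sh[, 2] >= 1 & sh[, 2] <= 20 &
      sh[, 3] >= 1 & sh[, 3] <= 20
    dil[sh[ok, , drop = FALSE]] <- TRUE
  }
  th_d <- local_thickness(dil, voxel_size = 1)$values
  expect_true(all(th_d[m] >= th[m] - 1e-9))
})

test_that("branch diameter summaries pool voxels correctly", {
  # uniform thickness: mean = value, sd = 0
  cyl <- digital_cylinder(16, 16, 20, 5)
  th <- local_thickness(cyl, voxel_size = 0.059)
  uniform <- th$values == max(th$values, na.rm = TRUE) & !is.na(th$values)
  r <- summarize_vessel_diameter(th, uniform, "core")
  expect_equal(r$sd_diameter, 0)
  expect_equal(r$mean_diameter, max(th$values, na.rm = TRUE))

  # two-segment branch with thickness 6 and 10 in equal counts -> mean 8
  fake <- structure(list(
    values = array(c(rep(6, 10), rep(10, 10), rep(NA, 7)), c(27, 1, 1)),
    voxel_size = 1, units = "mm"), class = "thickness_map")
  bm <- array(c(rep(TRUE, 20), rep(FALSE, 7)), c(27, 1, 1))
  r2 <- summarize_vessel_diameter(fake, bm, "two-seg")
  expect_equal(r2$mean_diameter, 8)
  expect_equal(r2$sd_diameter, sd(c(rep(6, 10), rep(10, 10))))
  expect_equal(r2$n_voxels, 20)

  expect_error(summarize_vessel_diameter(th, array(FALSE, dim(th$values))),
               "empty branch")
  out <- array(FALSE, dim(th$values)); out[1, 1, 1] <- TRUE
  expect_error(summarize_vessel_diameter(th, out), "outside")
})

test_that("anisotropic voxels and empty masks are rejected", {
  m <- digital_ball(9, 3)
  expect_error(local_thickness(m, voxel_size = c(1, 1, 2)), "isotropic")
  expect_error(local_thickness(array(FALSE, c(4, 4, 4))), "empty")
})
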