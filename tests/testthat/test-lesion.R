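test_that("tissue classification applies the edema threshold", {
  expect_equal(classify_tissue(500), "edema")
  expect_equal(classify_tissue(750), "normal")
  expect_equal(classify_tissue(650), "normal")  # boundary convention
  expect_equal(classify_tissue(c(100, 649.9, 650.1)),
               c("edema", "edema", "normal"))
  expect_error(classify_tissue(-5))
  # monotonicity: raising ADC never flips normal back to edema
  adcs <- sort(runif(50, 0, 1300))
  cls <- classify_tissue(adcs)
  expect_true(all(diff(cls == "normal") >= 0))
})

test_that("ROI summaries use valid voxels only", {
  vals <- array(7, c(4, 4, 2))
  map <- parameter_map(vals, "um")
  roi <- array(FALSE, c(4, 4, 2)); roi[1:2, 1:2, 1] <- TRUE
  s <- roi_metric_summary(map, roi, "test-roi", "vsi")
  expect_equal(s$mean, 7)
  expect_equal(s$median, 7)
  expect_equal(s$n_voxels, 4)
  # partially invalid mask: count valid only
  vm <- array(TRUE, c(4, 4, 2)); vm[1, 1, 1] <- FALSE
  map2 <- parameter_map(vals, "um", vm)
  s2 <- roi_metric_summary(map2, roi, "test-roi", "vsi")
  expect_equal(s2$n_voxels, 3)
  empty <- array(FALSE, c(4, 4, 2))
  expect_error(roi_metric_summary(map, empty, "roi-x"), "roi-x")
})

test_that("cutoff proportions count strictly greater values", {
  expect_equal(proportion_above(c(5, 12, 15), 10), 2 / 3)
  expect_equal(proportion_above(c(1, 2), 10), 0)
  expect_equal(proportion_above(c(11, 12), 10), 1)
  x <- rnorm(25)
  expect_equal(proportion_above(x, -Inf), 1)
  expect_equal(proportion_above(x, Inf), 0)
  expect_error(proportion_above(numeric(0), 1), "empty")
})

test_that("Student's t statistic matches hand computation and handles degeneracy", {
  r <- students_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$statistic, -1.095445, tolerance = 1e-6)
  expect_equal(r$df, 6)
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # paired, constant nonzero difference: degenerate
  dg <- students_t(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)
  # zero variance, equal means: t = 0, p = 1
  z <- students_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$degenerate)
  expect_error(students_t(1, c(1, 2)), "at least 2")
  expect_error(students_t(c(1, 2, 3), c(1, 2), paired = TRUE), "equal group")
})

test_that("t computation agrees with the reference implementation", {
  set.seed(123)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1, sd = runif(1, 0.5, 3))
    b <- rnorm(n2, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ours <- students_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
    op <- students_t(a[1:3], b[1:3], paired = TRUE)
    rp <- t.test(a[1:3], b[1:3], paired = TRUE)
    expect_equal(op$statistic, unname(rp$statistic), tolerance = 1e-6)
    expect_equal(op$p_value, rp$p.value, tolerance = 1e-6)
  }
})

test_that("double-box export labels ROIs with their tissue class", {
  tb <- export_double_box(adc_values = c(500, 510, 490, 760, 740, 750),
                          metric_values = c(12, 13, 11, 4, 5, 4),
                          roi_labels = rep(c("lesion", "contra"), each = 3),
                          side = rep(c("ipsi", "contra"), each = 3),
                          metric_name = "vsi")
  expect_equal(nrow(tb), 6)
  expect_equal(unique(tb$tissue_class[tb$roi == "lesion"]), "edema")
  expect_equal(unique(tb$tissue_class[tb$roi == "contra"]), "normal")
  expect_equal(attr(tb, "adc_reference"), 650)
  expect_error(export_double_box(numeric(0), numeric(0), character(0)),
               "empty")
  expect_error(export_double_box(1:3, 1:2, "a"), "equal length")
})

test_that("longitudinal diameters combine as max-venous / min-arterial early, day-7 late", {
  tbl <- tibble::tibble(
    animal = rep("r1", 6),
    day = rep(c(1, 4, 7), 2),
    vessel = rep(c("cRHV", "MCA"), each = 3),
    type = rep(c("venous", "arterial"), each = 3),
    side = "ipsi",
    diameter = c(0.30, 0.40, 0.25, 0.20, 0.15, 0.22))
  out <- combine_vessel_diameters(tbl)
  early_v <- out$diameter[out$phase == "early" & out$vessel == "cRHV"]
  early_a <- out$diameter[out$phase == "early" & out$vessel == "MCA"]
  expect_equal(early_v, 0.40)  # peak venous dilation
  expect_equal(early_a, 0.15)  # peak arterial thinning
  expect_equal(out$diameter[out$phase == "late" & out$vessel == "cRHV"], 0.25)
  expect_equal(out$diameter[out$phase == "late" & out$vessel == "MCA"], 0.22)
  expect_error(combine_vessel_diameters(tbl[, -1]), "columns")
})
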