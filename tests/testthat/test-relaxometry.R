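test_that("mono-exponential fits invert the generative model exactly", {
  b <- c(100, 200, 400, 600, 800, 1000)
  f <- fit_monoexponential(b, 1000 * exp(-8e-4 * b))
  expect_equal(f$rate, 8e-4, tolerance = 1e-8)
  expect_equal(f$s0, 1000, tolerance = 1e-6)
  te <- seq(8, 160, by = 8)
  f2 <- fit_monoexponential(te, exp(-0.02 * te))
  expect_equal(f2$rate * 1000, 20, tolerance = 1e-6)
  # constant signal: zero rate
  f3 <- fit_monoexponential(te, rep(5, length(te)))
  expect_equal(f3$rate, 0, tolerance = 1e-10)
  expect_equal(f3$s0, 5, tolerance = 1e-8)
  expect_error(fit_monoexponential(c(1, 2), c(1, 2)), "3 points")
  expect_false(fit_monoexponential(te, rep(0, length(te)))$converged)
})

test_that("vectorized fits agree with an independent nonlinear LS reference", {
  skip_if_not_installed("minpack.lm")
  set.seed(42)
  te <- seq(3, 59, by = 4)
  for (i in 1:20) {
    s0 <- runif(1, 500, 1500)
    rate <- runif(1, 0.005, 0.06)
    y <- s0 * exp(-rate * te) + rnorm(length(te), 0, s0 / 60)
    y <- pmax(y, 1)
    ours <- fit_monoexponential(te, y)
    ref <- minpack.lm::nlsLM(y ~ a * exp(-r * te),
                             start = list(a = max(y), r = 0.02))
    expect_equal(ours$rate, coef(ref)[["r"]], tolerance = 1e-5)
    expect_equal(ours$s0, coef(ref)[["a"]], tolerance = 1e-5)
  }
})

test_that("ADC maps recover phantom truth and separate lesion from normal", {
  spec <- small_phantom_spec(snr = Inf)
  truth <- make_brain_phantom(spec)
  dwi <- render_series(truth, "dwi", snr = Inf)
  adc <- compute_adc_map(dwi)
  inb <- truth$masks$brain
  expect_true(all(adc$valid_mask[inb]))
  expect_lt(max(abs(adc$values[inb] - truth$maps$adc[inb]) /
                  truth$maps$adc[inb]), 1e-6)
  expect_false(any(adc$valid_mask[!inb]))

  # SNR 40: median relative error < 1%, lesion vs normal separation
  truth_n <- make_brain_phantom(small_phantom_spec(snr = 40))
  dwi_n <- render_series(truth_n, "dwi", seed = 3)
  adc_n <- compute_adc_map(dwi_n)
  # per-voxel precision at SNR 40 with the 6-b-value protocol: the
  # Cramer-Rao floor puts the median relative error near 3-4%
  rel <- abs(adc_n$values[inb] - truth_n$maps$adc[inb]) /
    truth_n$maps$adc[inb]
  expect_lt(median(rel, na.rm = TRUE), 0.05)
  m_les <- mean(adc_n$values[truth_n$masks$lesion], na.rm = TRUE)
  m_nor <- mean(adc_n$values[truth_n$masks$contra_subcortex], na.rm = TRUE)
  expect_gt(m_nor - m_les, 200)
})

test_that("rate-change maps subtract, scale and record provenance", {
  spec <- small_phantom_spec(snr = Inf)
  truth <- make_brain_phantom(spec)
  pre <- render_series(truth, "msme_pre", snr = Inf)
  post <- render_series(truth, "msme_post", snr = Inf)
  inb <- truth$masks$brain

  d0 <- compute_delta_map(pre, pre, mode = "fitted_train", kind = "r2",
                          scale_factor = 1)
  expect_lt(max(abs(d0$values[inb])), 1e-6)

  d1 <- compute_delta_map(pre, post, mode = "fitted_train", kind = "r2",
                          scale_factor = 1)
  expect_equal(d1$values[inb], truth$maps$delta_r2[inb], tolerance = 1e-6)
  expect_equal(d1$provenance$scale_factor, 1)

  d2 <- compute_delta_map(pre, post, mode = "fitted_train", kind = "r2")
  expect_equal(d2$provenance$scale_factor, 4.375)
  expect_equal(d2$values[inb], 4.375 * truth$maps$delta_r2[inb],
               tolerance = 1e-6)

  d3 <- compute_delta_map(pre, post, mode = "first_echo", kind = "r2")
  expect_equal(d3$provenance$scale_factor, 1)
  expect_equal(d3$values[inb], truth$maps$delta_r2[inb], tolerance = 1e-6)

  # synthetic example: pre 20 s^-1, post 24 s^-1 -> 4 s^-1; x4.375 = 17.5
  te <- seq(8, 160, by = 8)
  mk <- function(rate) {
    v <- array(rep(exp(-rate * te / 1000), each = 8), c(2, 2, 2, length(te)))
    echo_series(v, te, "te", 1)
  }
  dd <- compute_delta_map(mk(20), mk(24), mode = "fitted_train", kind = "r2",
                          scale_factor = 1)
  expect_equal(unique(round(as.vector(dd$values), 6)), 4)
  dd2 <- compute_delta_map(mk(20), mk(24), mode = "fitted_train", kind = "r2")
  expect_equal(unique(round(as.vector(dd2$values), 6)), 17.5)
  expect_error(compute_delta_map(mk(20), echo_series(
    array(1, c(2, 2, 2, 3)), c(1, 2, 3), "te", 1)), "share geometry")
})

test_that("fit bias under Rician noise is small in the protocol's sensitive range", {
  # rates around 1/TE_max .. 1/TE_mid of the spin-echo train, SNR 40
  set.seed(99)
  te <- seq(8, 160, by = 8)
  n <- 10000
  for (rate in c(0.008, 0.016)) {
    clean <- matrix(rep(1000 * exp(-rate * te), each = n), nrow = n)
    noisy <- add_rician(clean, 1000 / 40)
    f <- vsimri:::fit_exp_matrix(te, matrix(noisy, nrow = n))
    bias <- mean(f$rate, na.rm = TRUE) - rate
    expect_lt(abs(bias) / rate, 0.02)
  }
})

test_that("echo series container validates its axis", {
  expect_error(echo_series(array(1, c(2, 2, 2, 3)), c(1, 3, 2), "te"),
               "increasing")
  expect_error(echo_series(array(1, c(2, 2, 2, 3)), c(1, 2), "te"),
               "stack length")
})
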