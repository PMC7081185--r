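#' Echo / b-value series container
#'
#' A 4D intensity stack indexed along its fourth dimension by b-value
#' (diffusion weighting, s mm^-2) or echo time (ms).
#'
#' @param volumes 4D numeric array (x, y, z, axis).
#' @param axis_values Strictly increasing numeric vector, one per volume.
#' @param axis_kind `"bvalue"` or `"te"`.
#' @param voxel_size Voxel edge length(s) (mm).
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(volumes, axis_values,
                        axis_kind = c("bvalue", "te"), voxel_size = 1) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(length(dim(volumes)) == 4)
  if (any(diff(axis_values) <= 0))
    stop("axis_values must be strictly increasing")
  if (dim(volumes)[4] != length(axis_values))
    stop("stack length must equal number of axis values")
  structure(
    list(volumes = volumes, axis_values = as.double(axis_values),
         axis_kind = axis_kind, voxel_size = voxel_size),
    class = "echo_series"
  )
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("echo_series: %d x %d x %d, %d %ss (%g..%g)\n",
              d[1], d[2], d[3], d[4], x$axis_kind,
              min(x$axis_values), max(x$axis_values)))
  invisible(x)
}

#' 3D scalar parameter map with units and validity mask
#'
#' @param values 3D numeric array; `NA` on invalid voxels.
#' @param units Unit string (e.g. `"um^2/s"`, `"1/s"`, `"um"`, `"mm^-2"`).
#' @param valid_mask 3D logical array; invalid voxels are excluded from all
#'   downstream statistics.
#' @param provenance Named list of fit metadata (mode, scaling applied, ...).
#' @param voxel_size Voxel edge length(s) (mm).
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, units, valid_mask = NULL,
                          provenance = list(), voxel_size = 1) {
  stopifnot(length(dim(values)) == 3)
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  stopifnot(all(dim(valid_mask) == dim(values)))
  structure(
    list(values = values, units = units, valid_mask = valid_mask,
         provenance = provenance, voxel_size = voxel_size),
    class = "parameter_map"
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$valid_mask]
  cat(sprintf("parameter_map [%s]: %d x %d x %d, %d valid voxels\n",
              x$units, d[1], d[2], d[3], sum(x$valid_mask)))
  if (length(v))
    cat(sprintf("  median %.4g, range [%.4g, %.4g]\n",
                median(v), min(v), max(v)))
  invisible(x)
}

#' Mono-exponential decay fit for one signal series
#'
#' Nonlinear least-squares fit of \eqn{S = S_0 e^{-r x}} initialized from a
#' log-linear regression. The returned rate is in reciprocal units of `x`.
#'
#' @param axis_values Sampling points (b-values or echo times), length >= 3.
#' @param signals Positive signal values, same length.
#' @return List with `s0`, `rate` and `converged`.
#' @examples
#' b <- c(100, 200, 400, 600, 800, 1000)
#' fit_monoexponential(b, 1000 * exp(-8e-4 * b))$rate  # 8e-4
#' @export
fit_monoexponential <- function(axis_values, signals) {
  if (length(axis_values) < 3) stop("need at least 3 points")
  if (length(signals) != length(axis_values)) stop("length mismatch")
  if (all(signals == 0)) return(list(s0 = NA_real_, rate = NA_real_,
                                     converged = FALSE))
  if (any(signals < 0)) stop("signals must be non-negative")
  f <- fit_exp_matrix(axis_values, matrix(signals, nrow = 1))
  list(s0 = f$s0[1], rate = f$rate[1], converged = f$converged[1])
}

# Vectorized Levenberg-Marquardt for S = s0 * exp(-rate * x) across many
# series at once (one row per voxel). Log-linear start; closed-form damped
# 2x2 normal-equation solves; per-voxel step acceptance; voxels whose fit
# has converged drop out of the active set.
fit_exp_matrix <- function(x, y, maxit = 50L, tol = 1e-13) {
  nv <- nrow(y)
  eps <- 1e-12 * max(y, 1e-300)
  ylog <- log(pmax(y, eps))
  # log-linear init: per-row simple regression on x
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(ylog %*% xc) / sxx
  rate <- -slope
  s0 <- exp(rowMeans(ylog) + rate * mean(x))

  sse_of <- function(s0v, ratev, yv) {
    f <- s0v * exp(-outer(ratev, x))
    rowSums((yv - f)^2)
  }
  sse <- sse_of(s0, rate, y)
  lambda <- rep(1e-3, nv)
  active <- which(is.finite(sse))
  for (it in seq_len(maxit)) {
    if (!length(active)) break
    ya <- y[active, , drop = FALSE]
    e <- exp(-outer(rate[active], x))
    f <- s0[active] * e
    r <- ya - f
    j2 <- -f * rep(x, each = length(active))
    g1 <- rowSums(e * r)
    g2 <- rowSums(j2 * r)
    la <- lambda[active]
    a11 <- rowSums(e * e) * (1 + la)
    a22 <- rowSums(j2 * j2) * (1 + la)
    a12 <- rowSums(e * j2)
    det <- a11 * a22 - a12^2
    det[det == 0 | !is.finite(det)] <- NA
    d1 <- (g1 * a22 - g2 * a12) / det
    d2 <- (g2 * a11 - g1 * a12) / det
    s0_t <- s0[active] + d1
    rate_t <- rate[active] + d2
    sse_t <- sse_of(s0_t, rate_t, ya)
    ok <- is.finite(sse_t) & (sse_t <= sse[active])
    gain <- ifelse(ok, (sse[active] - sse_t) / (sse[active] + 1e-300), 1)
    ia <- active[ok]
    s0[ia] <- s0_t[ok]
    rate[ia] <- rate_t[ok]
    sse[ia] <- sse_t[ok]
    lambda[ia] <- lambda[ia] / 3
    lambda[active[!ok]] <- lambda[active[!ok]] * 10
    done <- (ok & gain < tol) | lambda[active] > 1e12
    active <- active[!done]
  }
  conv <- is.finite(s0) & is.finite(rate)
  rate[!conv] <- NA_real_
  s0[!conv] <- NA_real_
  list(s0 = s0, rate = rate, converged = conv)
}

# Shared per-voxel fitting over an echo_series. Returns rate in reciprocal
# axis units plus the validity mask (background + convergence).
fit_series_map <- function(series, mask_floor = 0.05) {
  vols <- series$volumes
  d <- dim(vols)
  nv <- prod(d[1:3])
  y <- matrix(vols, nrow = nv)
  max_i <- apply(y, 1, max)
  floor_i <- mask_floor * quantile(vols, 0.99, names = FALSE)
  in_object <- max_i >= floor_i & is.finite(max_i)
  rate <- rep(NA_real_, nv)
  s0 <- rep(NA_real_, nv)
  conv <- rep(FALSE, nv)
  if (any(in_object)) {
    f <- fit_exp_matrix(series$axis_values, y[in_object, , drop = FALSE])
    rate[in_object] <- f$rate
    s0[in_object] <- f$s0
    conv[in_object] <- f$converged
  }
  list(rate = array(rate, d[1:3]), s0 = array(s0, d[1:3]),
       valid = array(in_object & conv, d[1:3]))
}

#' Voxel-wise apparent diffusion coefficient map
#'
#' Fits \eqn{S = S_0 e^{-ADC \cdot b}} in every voxel of a
#' diffusion-weighted series and reports ADC in um^2/s (b-values in
#' s mm^-2, one 1e6 unit conversion recorded in provenance). Background
#' voxels (maximum series intensity below 5% of the series' 99th-percentile
#' intensity) and non-converged fits are marked invalid.
#'
#' @param dwi An [echo_series()] with `axis_kind = "bvalue"`.
#' @return A [parameter_map()] in um^2/s.
#' @export
compute_adc_map <- function(dwi) {
  stopifnot(inherits(dwi, "echo_series"))
  if (dwi$axis_kind != "bvalue") stop("compute_adc_map needs a b-value series")
  f <- fit_series_map(dwi)
  vals <- f$rate * 1e6  # (s mm^-2)^-1 = mm^2/s -> um^2/s
  vals[!f$valid] <- NA_real_
  parameter_map(vals, "um^2/s", f$valid,
                provenance = list(fit = "monoexp_lm", axis = "bvalue",
                                  unit_scale = 1e6),
                voxel_size = dwi$voxel_size)
}

#' Voxel-wise transverse relaxation rate map (R2 or R2*)
#'
#' Fits \eqn{S = S_0 e^{-TE \cdot R}} over a multi-echo series (TE in ms)
#' and reports the rate in s^-1.
#'
#' @param series An [echo_series()] with `axis_kind = "te"`.
#' @return A [parameter_map()] in 1/s.
#' @export
compute_rate_map <- function(series) {
  stopifnot(inherits(series, "echo_series"))
  if (series$axis_kind != "te") stop("compute_rate_map needs a TE series")
  f <- fit_series_map(series)
  vals <- f$rate * 1000  # ms^-1 -> s^-1
  vals[!f$valid] <- NA_real_
  parameter_map(vals, "1/s", f$valid,
                provenance = list(fit = "monoexp_lm", axis = "te",
                                  unit_scale = 1000),
                voxel_size = series$voxel_size)
}

#' Contrast-induced relaxation-rate change map
#'
#' Builds \eqn{\Delta R_2} or \eqn{\Delta R_2^*} from pre- and post-contrast
#' multi-echo series. `fitted_train` subtracts per-voxel fitted rates
#' (post - pre) and, for spin-echo data (`kind = "r2"`), multiplies by a
#' protocol calibration factor (default 4.375) that rescales the fitted
#' echo-train rate change onto the first-echo scale used by the vessel-size
#' equations. `first_echo` uses
#' \eqn{-\ln(S_{post}(TE_1)/S_{pre}(TE_1))/TE_1} directly (scale 1).
#' Negative voxels are retained in the raw map; downstream vessel-size maps
#' exclude them.
#'
#' @param pre,post Pre-/post-contrast [echo_series()] with identical
#'   geometry and echo times.
#' @param mode `"fitted_train"` or `"first_echo"`.
#' @param kind `"r2"` (spin echo) or `"r2star"` (gradient echo); controls
#'   the default calibration factor.
#' @param scale_factor Override for the calibration factor; default 4.375
#'   for fitted-train \eqn{\Delta R_2}, otherwise 1.
#' @return A [parameter_map()] in 1/s; `provenance$scale_factor` records the
#'   scaling applied.
#' @export
compute_delta_map <- function(pre, post,
                              mode = c("fitted_train", "first_echo"),
                              kind = c("r2", "r2star"),
                              scale_factor = NULL) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  stopifnot(inherits(pre, "echo_series"), inherits(post, "echo_series"))
  if (!all(dim(pre$volumes) == dim(post$volumes)) ||
      !isTRUE(all.equal(pre$axis_values, post$axis_values)))
    stop("pre and post series must share geometry and axis values")
  if (pre$axis_kind != "te") stop("delta maps need TE series")
  if (is.null(scale_factor))
    scale_factor <- if (mode == "fitted_train" && kind == "r2") 4.375 else 1.0

  if (mode == "fitted_train") {
    fp <- fit_series_map(pre)
    fq <- fit_series_map(post)
    valid <- fp$valid & fq$valid
    vals <- (fq$rate - fp$rate) * 1000 * scale_factor
  } else {
    te1 <- pre$axis_values[1]
    d3 <- dim(pre$volumes)[1:3]
    s_pre <- array(pre$volumes[, , , 1], d3)
    s_post <- array(post$volumes[, , , 1], d3)
    valid <- is.finite(s_pre) & is.finite(s_post) & s_pre > 0 & s_post > 0
    vals <- array(NA_real_, dim(s_pre))
    vals[valid] <- -log(s_post[valid] / s_pre[valid]) / (te1 / 1000) *
      scale_factor
  }
  vals[!valid] <- NA_real_
  parameter_map(vals, "1/s", valid,
                provenance = list(mode = mode, kind = kind,
                                  scale_factor = scale_factor),
                voxel_size = pre$voxel_size)
}
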