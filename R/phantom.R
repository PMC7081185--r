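#' Rician noise for magnitude MR images
#'
#' Adds complex Gaussian noise of standard deviation `sigma` per channel and
#' takes the magnitude, the noise model of magnitude-reconstructed MRI. On
#' signal-free background the result is Rayleigh with mean
#' \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param x Noise-free signal array.
#' @param sigma Per-channel noise SD (same units as `x`).
#' @return Array of noisy magnitudes.
#' @export
add_rician <- function(x, sigma) {
  if (sigma == 0) return(x)
  stopifnot(sigma > 0)
  n <- length(x)
  out <- sqrt((x + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  array(out, dim(x))
}

#' Specification of the two-hemisphere brain phantom
#'
#' The phantom emulates the ROI structure of a rodent ischemic-stroke
#' study: two half-ellipsoid hemispheres with a cortical shell and
#' subcortical core, and a spherical subcortical lesion in the ipsilateral
#' hemisphere carrying reduced ADC (edema), elevated vessel size index and
#' reduced density index Q relative to normal tissue. Default effect sizes
#' straddle the classification cutoffs (ADC 650 um^2/s, VSI 10 um,
#' MVD 200 mm^-2): lesion ADC 500 vs normal 750 um^2/s, VSI 12 vs 4 um,
#' Q 0.6 vs 1.07 s^-1/3. The default grid (96 x 96 x 48 at 0.3 mm) matches
#' a 300 um in-plane acquisition at desk-test scale.
#'
#' @param grid_dims Grid dimensions (voxels).
#' @param voxel_size Voxel edge (mm).
#' @param cortex_thickness Cortical shell thickness (voxels).
#' @param lesion_radius Lesion radius (voxels); 0 disables the lesion.
#' @param adc_lesion,adc_normal ADC truth values (um^2/s); must straddle
#'   650.
#' @param vsi_lesion,vsi_normal VSI truth values (um).
#' @param q_lesion,q_normal Q truth values (s^-1/3).
#' @param r2_pre,r2star_pre Pre-contrast relaxation rates (s^-1).
#' @param snr Rician SNR (S0 / noise SD); `Inf` for noiseless.
#' @param s0 Baseline signal amplitude.
#' @param d_water Water diffusion coefficient (um^2/s) used in the
#'   vessel-size relations.
#' @param physics A [physics_config()].
#' @param seed Default seed for series rendering.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(96L, 96L, 48L), voxel_size = 0.3,
                         cortex_thickness = 4, lesion_radius = 9,
                         adc_lesion = 500, adc_normal = 750,
                         vsi_lesion = 12, vsi_normal = 4,
                         q_lesion = 0.6, q_normal = 1.07,
                         r2_pre = 20, r2star_pre = 30,
                         snr = 40, s0 = 1000, d_water = 800,
                         physics = physics_config(), seed = 1L) {
  stopifnot(adc_lesion < 650, adc_normal > 650, snr > 0, s0 > 0,
            lesion_radius >= 0, all(grid_dims > 0))
  structure(
    list(grid_dims = as.integer(grid_dims), voxel_size = voxel_size,
         cortex_thickness = cortex_thickness, lesion_radius = lesion_radius,
         adc_lesion = adc_lesion, adc_normal = adc_normal,
         vsi_lesion = vsi_lesion, vsi_normal = vsi_normal,
         q_lesion = q_lesion, q_normal = q_normal,
         r2_pre = r2_pre, r2star_pre = r2star_pre,
         snr = snr, s0 = s0, d_water = d_water, physics = physics,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Invert the vessel-size relations: given VSI and Q, recover the rate pair.
# ratio = dR2*/dR2 from VSI; then dR2 = Q^3 ratio^2, dR2* = Q^3 ratio^3.
rates_from_vsi_q <- function(vsi, q, d_water, dwc) {
  ratio <- (vsi / (0.424 * sqrt(d_water / dwc)))^(2 / 3)
  dr2 <- q^3 * ratio^2
  dr2s <- q^3 * ratio^3
  if (any(dr2 <= 0) || any(dr2s < dr2))
    stop("inconsistent lesion spec: implied rate changes are not physical")
  list(delta_r2 = dr2, delta_r2_star = dr2s, ratio = ratio)
}

#' Build the brain phantom ground truth
#'
#' Piecewise-constant truth maps on the two-hemisphere geometry. The truth
#' \eqn{\Delta R_2}/\eqn{\Delta R_2^*} maps are back-computed from the VSI
#' and Q truth by inverting the vessel-size relations, so the mapping stage
#' has an exact target, and the MVD truth satisfies
#' \eqn{MVD = Q^3/(4.725 D)} identically.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `spec`, `maps`
#'   (adc, vsi, q, mvd, delta_r2, delta_r2_star, r2_pre, r2_post,
#'   r2star_pre, r2star_post as 3D arrays, `NA` outside the brain), `masks`
#'   (brain, ipsi/contra x cortex/subcortex, lesion as logical arrays).
#' @export
make_brain_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)

  hemi <- function(cx) {
    ((ix - cx) / (0.21 * d[1]))^2 + ((iy - 0.5 * d[2]) / (0.38 * d[2]))^2 +
      ((iz - 0.5 * d[3]) / (0.38 * d[3]))^2 <= 1
  }
  contra_h <- hemi(0.28 * d[1])   # left hemisphere
  ipsi_h <- hemi(0.72 * d[1])     # right hemisphere (lesion side)
  brain <- contra_h | ipsi_h

  # cortical shell: voxels within cortex_thickness of the brain surface
  d2 <- array(cpp_sq_edt(as.integer(brain), as.integer(d)), d)
  cortex <- brain & sqrt(d2) <= spec$cortex_thickness
  subcortex <- brain & !cortex

  lesion <- array(FALSE, d)
  if (spec$lesion_radius > 0) {
    ctr <- c(0.72 * d[1], 0.5 * d[2], 0.5 * d[3])
    lesion <- (ix - ctr[1])^2 + (iy - ctr[2])^2 + (iz - ctr[3])^2 <=
      spec$lesion_radius^2
    lesion <- lesion & subcortex & ipsi_h
    if (!any(lesion))
      stop("lesion specification places no voxels inside the ipsilateral subcortex")
  }

  fill <- function(normal, lesion_value) {
    v <- array(NA_real_, d)
    v[brain] <- normal
    v[lesion] <- lesion_value
    v
  }
  adc <- fill(spec$adc_normal, spec$adc_lesion)
  vsi <- fill(spec$vsi_normal, spec$vsi_lesion)
  q <- fill(spec$q_normal, spec$q_lesion)

  dwc <- characteristic_frequency(spec$physics)
  rt <- rates_from_vsi_q(vsi[brain], q[brain], spec$d_water, dwc)
  delta_r2 <- array(NA_real_, d); delta_r2[brain] <- rt$delta_r2
  delta_r2s <- array(NA_real_, d); delta_r2s[brain] <- rt$delta_r2_star
  mvd <- array(NA_real_, d); mvd[brain] <- mvd_value(q[brain], spec$d_water)

  r2_pre <- fill(spec$r2_pre, spec$r2_pre)
  r2s_pre <- fill(spec$r2star_pre, spec$r2star_pre)
  r2_post <- r2_pre + delta_r2
  r2s_post <- r2s_pre + delta_r2s

  half <- ix > d[1] / 2
  masks <- list(
    brain = brain, lesion = lesion,
    ipsi_cortex = cortex & half, contra_cortex = cortex & !half,
    ipsi_subcortex = subcortex & half, contra_subcortex = subcortex & !half)

  structure(
    list(spec = spec,
         maps = list(adc = adc, vsi = vsi, q = q, mvd = mvd,
                     delta_r2 = delta_r2, delta_r2_star = delta_r2s,
                     r2_pre = r2_pre, r2_post = r2_post,
                     r2star_pre = r2s_pre, r2star_post = r2s_post),
         masks = masks),
    class = "phantom_truth"
  )
}

#' Protocol axis values for the phantom series
#'
#' b-values 100-1000 s mm^-2 for DWI; spin-echo train TE 8-160 ms (8 ms
#' spacing); gradient-echo train TE 3-59 ms (4 ms spacing).
#'
#' @param protocol One of `"dwi"`, `"msme_pre"`, `"msme_post"`,
#'   `"mege_pre"`, `"mege_post"`.
#' @return List with `axis_values` and `axis_kind`.
#' @export
protocol_axis <- function(protocol) {
  switch(protocol,
    dwi = list(axis_values = c(100, 200, 400, 600, 800, 1000),
               axis_kind = "bvalue"),
    msme_pre = , msme_post = list(axis_values = seq(8, 160, by = 8),
                                  axis_kind = "te"),
    mege_pre = , mege_post = list(axis_values = seq(3, 59, by = 4),
                                  axis_kind = "te"),
    stop(sprintf("unknown protocol '%s'", protocol))
  )
}

#' Render a noisy acquisition series from phantom truth
#'
#' Generates \eqn{S = S_0 e^{-rate \cdot x}} per voxel at the protocol's
#' axis values from the corresponding truth map and adds Rician noise at
#' the given SNR (noise SD = `s0 / snr`). Background voxels are pure noise.
#'
#' @param truth A [make_brain_phantom()] result.
#' @param protocol Protocol name, see [protocol_axis()].
#' @param snr Rician SNR; defaults to the phantom spec; `Inf` = noiseless.
#' @param seed RNG seed.
#' @return An [echo_series()].
#' @export
render_series <- function(truth, protocol, snr = truth$spec$snr,
                          seed = truth$spec$seed) {
  stopifnot(inherits(truth, "phantom_truth"))
  ax <- protocol_axis(protocol)
  spec <- truth$spec
  rate_map <- switch(protocol,
    dwi = truth$maps$adc * 1e-6,          # um^2/s -> mm^2/s per (s mm^-2)
    msme_pre = truth$maps$r2_pre / 1000,  # s^-1 -> ms^-1
    msme_post = truth$maps$r2_post / 1000,
    mege_pre = truth$maps$r2star_pre / 1000,
    mege_post = truth$maps$r2star_post / 1000)
  d <- spec$grid_dims
  n_ax <- length(ax$axis_values)
  vols <- array(0, c(d, n_ax))
  r <- rate_map
  r[is.na(r)] <- 0
  inb <- truth$masks$brain
  for (k in seq_len(n_ax)) {
    s <- array(0, d)
    s[inb] <- spec$s0 * exp(-r[inb] * ax$axis_values[k])
    vols[, , , k] <- s
  }
  if (is.finite(snr)) {
    set.seed(seed)
    vols <- array(add_rician(vols, spec$s0 / snr), c(d, n_ax))
  }
  echo_series(vols, ax$axis_values, ax$axis_kind, spec$voxel_size)
}

#' Tubular vascular phantom with known radii
#'
#' Rasterizes straight cylindrical segments of known radius into a 3D grid
#' and returns both a noisy intensity volume (for thresholding tests) and
#' the exact binary mask with per-segment labels (for thickness tests). A
#' voxel belongs to a tube when its centre lies within the segment radius.
#'
#' @param grid_dims Grid dimensions (voxels).
#' @param voxel_size Isotropic voxel edge (mm).
#' @param segments Data frame / tibble with columns `x0, y0, z0, x1, y1,
#'   z1` (segment endpoints, mm) and `radius` (mm). Segments may overlap;
#'   zero radius is an error.
#' @param intensity_fg,intensity_bg Foreground / background intensities.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed RNG seed for the noise.
#' @return List with `intensity` (3D array), `mask` (3D logical),
#'   `labels` (3D integer, 0 = background, i = segment row), `segments`
#'   (the input tibble with an added `n_voxels` column), `voxel_size`.
#' @export
make_vascular_tree <- function(grid_dims, voxel_size = 1, segments,
                               intensity_fg = 100, intensity_bg = 10,
                               noise_sd = 0, seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  segments <- tibble::as_tibble(segments)
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius")
  if (!all(need %in% names(segments)))
    stop("segments needs columns ", paste(need, collapse = ", "))
  if (any(segments$radius <= 0)) stop("zero or negative tube radius")
  lim <- grid_dims * voxel_size
  for (cc in c("x0", "x1")) if (any(segments[[cc]] < 0 | segments[[cc]] > lim[1]))
    stop("segment endpoints must lie inside the grid")
  for (cc in c("y0", "y1")) if (any(segments[[cc]] < 0 | segments[[cc]] > lim[2]))
    stop("segment endpoints must lie inside the grid")
  for (cc in c("z0", "z1")) if (any(segments[[cc]] < 0 | segments[[cc]] > lim[3]))
    stop("segment endpoints must lie inside the grid")

  occ <- integer(prod(grid_dims))
  labels <- integer(prod(grid_dims))
  nvox <- integer(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    p0 <- c(segments$x0[i], segments$y0[i], segments$z0[i]) / voxel_size
    p1 <- c(segments$x1[i], segments$y1[i], segments$z1[i]) / voxel_size
    nvox[i] <- cpp_mark_tube(occ, grid_dims, p0, p1,
                             segments$radius[i] / voxel_size, FALSE,
                             labels, i)
  }
  segments$n_voxels <- nvox
  mask <- array(occ != 0, grid_dims)
  set.seed(seed)
  intensity <- array(intensity_bg, grid_dims)
  intensity[mask] <- intensity_fg
  if (noise_sd > 0)
    intensity <- intensity + array(rnorm(length(intensity), 0, noise_sd),
                                   grid_dims)
  list(intensity = intensity, mask = mask,
       labels = array(labels, grid_dims), segments = segments,
       voxel_size = voxel_size)
}
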