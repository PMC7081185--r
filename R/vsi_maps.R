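#' Vessel size index (VSI) map
#'
#' Voxel-wise
#' \deqn{VSI\,(\mu m) = 0.424\,(D/\Delta\omega_c)^{1/2}
#'       (\Delta R_2^*/\Delta R_2)^{3/2}}
#' with \eqn{\Delta\omega_c = \gamma\Delta\chi B_0} (see
#' [characteristic_frequency()]). Voxels where either rate change is
#' non-positive, or invalid in either input map, are marked invalid.
#'
#' @param delta_r2_map,delta_r2_star_map Co-registered [parameter_map()]s
#'   (1/s).
#' @param d_water Water diffusion coefficient (um^2/s).
#' @param delta_omega_c Characteristic frequency (rad/s).
#' @return A [parameter_map()] in um.
#' @export
compute_vsi <- function(delta_r2_map, delta_r2_star_map, d_water = 800,
                        delta_omega_c = characteristic_frequency(physics_config())) {
  check_same_maps(delta_r2_map, delta_r2_star_map)
  stopifnot(d_water > 0, delta_omega_c > 0)
  dr2 <- delta_r2_map$values
  dr2s <- delta_r2_star_map$values
  valid <- delta_r2_map$valid_mask & delta_r2_star_map$valid_mask &
    !is.na(dr2) & !is.na(dr2s) & dr2 > 0 & dr2s > 0
  vals <- array(NA_real_, dim(dr2))
  vals[valid] <- vsi_value(dr2[valid], dr2s[valid], d_water, delta_omega_c)
  parameter_map(vals, "um", valid,
                provenance = list(d_water = d_water,
                                  delta_omega_c = delta_omega_c),
                voxel_size = delta_r2_map$voxel_size)
}

#' Microvessel density index Q map
#'
#' Voxel-wise \eqn{Q\,(s^{-1/3}) = \Delta R_2 / (\Delta R_2^*)^{2/3}}.
#' Voxels with \eqn{\Delta R_2^* \le 0} or \eqn{\Delta R_2 < 0} are invalid
#' (Q maps are non-negative on valid voxels); \eqn{\Delta R_2 = 0} gives
#' Q = 0.
#'
#' @param delta_r2_map,delta_r2_star_map Co-registered [parameter_map()]s.
#' @return A [parameter_map()] in s^-1/3.
#' @export
compute_q <- function(delta_r2_map, delta_r2_star_map) {
  check_same_maps(delta_r2_map, delta_r2_star_map)
  dr2 <- delta_r2_map$values
  dr2s <- delta_r2_star_map$values
  valid <- delta_r2_map$valid_mask & delta_r2_star_map$valid_mask &
    !is.na(dr2) & !is.na(dr2s) & dr2 >= 0 & dr2s > 0
  vals <- array(NA_real_, dim(dr2))
  vals[valid] <- q_value(dr2[valid], dr2s[valid])
  parameter_map(vals, "s^-1/3", valid, provenance = list(),
                voxel_size = delta_r2_map$voxel_size)
}

#' Microvessel density (MVD) map
#'
#' Voxel-wise \eqn{MVD \approx Q^3 / (4.725\,D)}, converted from um^-2 to
#' mm^-2 (one 1e6 factor, recorded in provenance).
#'
#' @param q_map A [compute_q()] result.
#' @param d_water Water diffusion coefficient (um^2/s).
#' @return A [parameter_map()] in mm^-2.
#' @export
compute_mvd <- function(q_map, d_water = 800) {
  stopifnot(inherits(q_map, "parameter_map"), d_water > 0)
  q <- q_map$values
  valid <- q_map$valid_mask & !is.na(q)
  vals <- array(NA_real_, dim(q))
  vals[valid] <- mvd_value(q[valid], d_water)
  parameter_map(vals, "mm^-2", valid,
                provenance = list(d_water = d_water, unit_scale = 1e6),
                voxel_size = q_map$voxel_size)
}

check_same_maps <- function(a, b) {
  stopifnot(inherits(a, "parameter_map"), inherits(b, "parameter_map"))
  if (!all(dim(a$values) == dim(b$values)))
    stop("maps are not co-registered: grid dimensions differ")
  invisible(TRUE)
}
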