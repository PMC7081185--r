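# Independent oracles and digital-geometry builders shared across tests.

# Exhaustive maximal-sphere local thickness: brute-force distances from every
# foreground voxel to every background voxel give the inscribed radius
# rho(c) = min distance to a background centre (distance-ridge convention);
# thickness(p) is twice the largest rho(c) among spheres covering p.
# Quadratic cost; only for small masks.
oracle_local_thickness <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0, nrow(bg) > 0)
  fg <- matrix(as.double(fg), ncol = 3)
  bg <- matrix(as.double(bg), ncol = 3)
  bg_n2 <- rowSums(bg^2)
  d2min <- rep(Inf, nrow(fg))
  chunk <- 512L
  for (i0 in seq(1, nrow(fg), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(fg))
    cross <- fg[ii, , drop = FALSE] %*% t(bg)
    d2 <- outer(rowSums(fg[ii, , drop = FALSE]^2), bg_n2, "+") - 2 * cross
    d2min[ii] <- apply(d2, 1, min)
  }
  rho <- sqrt(pmax(d2min, 0))
  th <- rep(0, nrow(fg))
  for (i0 in seq(1, nrow(fg), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(fg))
    cross <- fg[ii, , drop = FALSE] %*% t(fg)
    d2 <- outer(rowSums(fg[ii, , drop = FALSE]^2), rowSums(fg^2), "+") -
      2 * cross
    covered <- sweep(d2, 2, rho^2, "<=")  # sphere c covers p
    th[ii] <- apply(sweep(covered, 2, 2 * rho, "*"), 1, max)
  }
  out <- array(NA_real_, dims)
  out[cbind(fg[, 1], fg[, 2], fg[, 3])] <- th
  out
}

# Digital solid ball: voxel centers within radius r of the center voxel.
digital_ball <- function(n, r, center = rep(floor((n + 1) / 2), 3)) {
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  array(d2 <= r^2, c(n, n, n))
}

# Digital cylinder along z spanning the volume, radius r; the axis passes
# through voxel centers.
digital_cylinder <- function(nx, ny, nz, r, cx = floor((nx + 1) / 2),
                             cy = floor((ny + 1) / 2)) {
  m <- array(FALSE, c(nx, ny, nz))
  for (i in 1:nx) for (j in 1:ny)
    if ((i - cx)^2 + (j - cy)^2 <= r^2) m[i, j, ] <- TRUE
  m
}

# small default physics/simulation fixtures
test_physics <- function() physics_config()

small_phantom_spec <- function(...) {
  args <- modifyList(list(grid_dims = c(48L, 48L, 24L), cortex_thickness = 3,
                          lesion_radius = 6), list(...))
  do.call(phantom_spec, args)
}
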