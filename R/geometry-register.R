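# Rigid (6-DOF) same-modality registration: mean-squared-difference metric,
# two-level multiresolution, trilinear resampling. Parameters are
# (tx, ty, tz) in mm and (rx, ry, rz) in degrees about the volume center.

# Internal: rotation matrix from Euler angles in degrees (applied as Rz Ry Rx).
euler_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Internal: trilinear interpolation of `vol` at (n x 3) 1-based voxel coords.
# Returns list(values, valid); out-of-volume samples are invalid.
trilinear_interp <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  valid <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  lin <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- lin(x0, y0, z0);     v100 <- lin(x0 + 1, y0, z0)
  v010 <- lin(x0, y0 + 1, z0); v110 <- lin(x0 + 1, y0 + 1, z0)
  v001 <- lin(x0, y0, z0 + 1); v101 <- lin(x0 + 1, y0, z0 + 1)
  v011 <- lin(x0, y0 + 1, z0 + 1); v111 <- lin(x0 + 1, y0 + 1, z0 + 1)
  vals <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz + v111 * fx * fy * fz
  list(values = vals, valid = valid)
}

#' Resample a volume through a rigid transform
#'
#' Samples `volume` at the rigidly transformed positions of every voxel of
#' the target grid: out(p) = volume(R (p - c) + c + t) with the rotation
#' about the grid center, translation in mm, trilinear interpolation, and
#' `NA` outside the source volume.
#'
#' @param volume 3D numeric array.
#' @param parameters numeric length-6: tx, ty, tz (mm), rx, ry, rz (deg).
#' @param spacing voxel spacing in mm per axis (default 1,1,1).
#' @param target_dim dimensions of the output grid (default: same as input).
#' @return list `volume` (resampled, `NA` where unsampled) and
#'   `valid_fraction`.
#' @export
transform_volume <- function(volume, parameters, spacing = c(1, 1, 1),
                             target_dim = dim(volume)) {
  d <- target_dim
  R <- euler_matrix(parameters[4], parameters[5], parameters[6])
  t <- parameters[1:3]
  ctr <- (d + 1) / 2 * spacing
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  phys <- sweep(g, 2, spacing, "*")
  moved <- sweep(phys, 2, ctr, "-") %*% t(R)
  moved <- sweep(moved, 2, ctr + t, "+")
  vox <- sweep(moved, 2, spacing, "/")
  s <- trilinear_interp(volume, vox)
  out <- array(NA_real_, d)
  out[g] <- ifelse(s$valid, s$values, NA_real_)
  list(volume = out, valid_fraction = mean(s$valid))
}

# Internal: 2x downsampling by mean pooling (odd trailing voxels dropped).
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2L
  if (any(d < 2)) return(vol)
  ix <- seq_len(d[1]) * 2L; iy <- seq_len(d[2]) * 2L; iz <- seq_len(d[3]) * 2L
  (vol[ix - 1L, iy - 1L, iz - 1L] + vol[ix, iy - 1L, iz - 1L] +
     vol[ix - 1L, iy, iz - 1L] + vol[ix, iy, iz - 1L] +
     vol[ix - 1L, iy - 1L, iz] + vol[ix, iy - 1L, iz] +
     vol[ix - 1L, iy, iz] + vol[ix, iy, iz]) / 8
}

#' Rigid registration of a moving to a fixed volume
#'
#' Estimates the 6-DOF rigid transform (3 translations in mm, 3 rotations in
#' degrees about the volume center) that minimizes the mean squared
#' intensity difference between the resampled moving volume and the fixed
#' volume, using a 2-level multiresolution Nelder-Mead search, then returns
#' the moving volume resampled onto the fixed grid.
#'
#' @param moving,fixed 3D numeric arrays.
#' @param spacing voxel spacing in mm (shared; same-scanner contrasts).
#' @param levels multiresolution levels (default 2).
#' @param maxit Nelder-Mead iteration budget per level.
#' @param init optional length-6 starting transform.
#' @return list `parameters` (tx, ty, tz, rx, ry, rz), `metric` (final MSD),
#'   `resampled` (moving on the fixed grid, `NA` outside), `valid_fraction`.
#' @export
register_rigid <- function(moving, fixed, spacing = c(1, 1, 1), levels = 2L,
                           maxit = 300L, init = rep(0, 6)) {
  if (length(dim(moving)) != 3 || length(dim(fixed)) != 3) {
    stop_ligrelax("volumes must be 3D", "ligrelax_shape_error")
  }
  # Out-of-volume samples are zero-filled and the denominator is the fixed
  # voxel count, so the metric is continuous in the transform (a varying
  # valid-voxel denominator puts a spurious minimum at the identity).
  msd <- function(par, mv, fx, sp) {
    r <- transform_volume(mv, par, spacing = sp, target_dim = dim(fx))
    if (r$valid_fraction < 0.1) return(1e12)
    v <- r$volume
    v[is.na(v)] <- 0
    mean((v - fx)^2)
  }
  par <- init
  scales <- rev(seq_len(max(1L, as.integer(levels))) - 1L) # coarsest first
  for (s in scales) {
    mv <- moving; fx <- fixed; sp <- spacing
    for (k in seq_len(s)) {
      mv <- downsample2(mv); fx <- downsample2(fx); sp <- sp * 2
    }
    opt <- optim(par, msd, mv = mv, fx = fx, sp = sp, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = c(1, 1, 1, 1, 1, 1)))
    par <- opt$par
  }
  final <- transform_volume(moving, par, spacing = spacing,
                            target_dim = dim(fixed))
  if (final$valid_fraction < 0.1) {
    stop_ligrelax("registration failed: fields of view barely overlap",
                  "ligrelax_registration_error")
  }
  list(parameters = par,
       metric = mean((final$volume - fixed)^2, na.rm = TRUE),
       resampled = final$volume,
       valid_fraction = final$valid_fraction)
}
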