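#' Build a tubular ligament mask around a centerline
#'
#' Stands in for manual segmentation: the mask is the set of voxels whose
#' centers lie within `radius_voxels` of a smooth centerline interpolated
#' through the given control points. Anatomical fidelity is a non-goal; the
#' tube is elongated and may run oblique to the craniocaudal axis, which is
#' all the thirds partition needs.
#'
#' @param grid_shape integer vector of 3 positive extents (voxels).
#' @param centerline_control_points numeric matrix (>= 2 rows x 3 columns)
#'   of voxel coordinates (1-based voxel centers) inside the grid.
#' @param radius_voxels tube radius in voxels, >= 1.
#' @return 3D logical array of dim `grid_shape`.
#' @examples
#' m <- make_ligament_mask(c(16, 16, 16), rbind(c(8, 8, 3), c(8, 8, 14)), 1.5)
#' sum(m) > 0
#' @export
make_ligament_mask <- function(grid_shape, centerline_control_points, radius_voxels) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop_ligrelax("grid_shape must be 3 positive integers", "ligrelax_geometry_error")
  }
  cp <- as.matrix(centerline_control_points)
  if (nrow(cp) < 2 || ncol(cp) != 3) {
    stop_ligrelax("need at least 2 three-dimensional control points",
                  "ligrelax_geometry_error")
  }
  if (radius_voxels < 1) {
    stop_ligrelax("radius_voxels must be >= 1", "ligrelax_geometry_error")
  }
  inside <- cp >= 1 & sweep(cp, 2, grid_shape, "<=")
  if (!all(inside)) {
    stop_ligrelax("centerline control points must lie inside the grid",
                  "ligrelax_geometry_error")
  }

  poly <- densify_centerline(cp, step = 0.25)

  # Only voxels inside the centerline bounding box (+radius) can qualify.
  lo <- pmax(1L, floor(apply(poly, 2, min) - radius_voxels))
  hi <- pmin(grid_shape, ceiling(apply(poly, 2, max) + radius_voxels))
  xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2]); zs <- seq.int(lo[3], hi[3])
  box <- as.matrix(expand.grid(x = xs, y = ys, z = zs))

  d2min <- rep(Inf, nrow(box))
  for (i in seq_len(nrow(poly))) {
    d2 <- (box[, 1] - poly[i, 1])^2 + (box[, 2] - poly[i, 2])^2 +
      (box[, 3] - poly[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- box[d2min <= radius_voxels^2, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop_ligrelax("radius too small: no voxel center lies within it",
                  "ligrelax_geometry_error")
  }
  mask <- array(FALSE, dim = grid_shape)
  mask[hit] <- TRUE
  mask
}

# Internal: interpolate a polyline densely through control points with a
# natural cubic spline per axis (straight chords when only 2 points).
densify_centerline <- function(cp, step = 0.25) {
  n <- nrow(cp)
  arc <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  total <- arc[n]
  if (total <= 0) {
    stop_ligrelax("degenerate centerline: zero length", "ligrelax_geometry_error")
  }
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  if (n == 2) {
    t <- s / total
    return(cbind(cp[1, 1] + t * (cp[2, 1] - cp[1, 1]),
                 cp[1, 2] + t * (cp[2, 2] - cp[1, 2]),
                 cp[1, 3] + t * (cp[2, 3] - cp[1, 3])))
  }
  sapply(1:3, function(ax) stats::spline(arc, cp[, ax], xout = s)$y)
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical arrays with matching dimensions.
#' @return 2|A n B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_ligrelax("masks must share a grid", "ligrelax_shape_error")
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Simulate a second rater's segmentation by boundary perturbation
#'
#' Randomly flips boundary voxels (erosion and dilation moves in equal
#' expectation) until the Dice overlap with the input mask falls within
#' 0.05 of `target_dice`. Emulates an independent reader re-segmenting the
#' same ligament.
#'
#' @param mask non-empty 3D logical array.
#' @param target_dice target Dice overlap in (0, 1].
#' @param seed RNG seed.
#' @param max_passes bounded number of perturbation passes before giving up.
#' @return logical array, same dim as `mask`, non-empty.
#' @export
perturb_mask <- function(mask, target_dice, seed, max_passes = 200L) {
  if (!is.logical(mask)) mask <- mask > 0
  if (sum(mask) == 0) {
    stop_ligrelax("cannot perturb an empty mask", "ligrelax_geometry_error")
  }
  if (target_dice <= 0 || target_dice > 1) {
    stop_ligrelax("target_dice must be in (0, 1]", "ligrelax_parameter_error")
  }
  if (target_dice == 1) return(mask)

  set.seed(seed)
  cur <- mask
  for (pass in seq_len(max_passes)) {
    d <- dice_coefficient(mask, cur)
    if (abs(d - target_dice) <= 0.05 && sum(cur) > 0) return(cur)
    if (d < target_dice - 0.05) break # overshot; flips only lower Dice further
    cur <- flip_boundary(cur, ref = mask,
                         n_flips = max(1L, round(0.02 * sum(mask))))
    if (sum(cur) == 0) break
  }
  d <- dice_coefficient(mask, cur)
  if (abs(d - target_dice) <= 0.05 && sum(cur) > 0) return(cur)
  stop_ligrelax(
    sprintf("could not reach Dice %.2f on this mask (got %.3f)", target_dice, d),
    "ligrelax_convergence_error"
  )
}

# Internal: one perturbation step. Only Dice-decreasing flips are candidates
# (remove a surface voxel the reference also has; add a background voxel the
# reference lacks), so Dice is monotone non-increasing in the flip count.
flip_boundary <- function(mask, ref, n_flips) {
  nb <- neighbor_count(mask)
  inner <- which(mask & nb < 6L & ref)     # true-positive surface voxels
  outer <- which(!mask & nb > 0L & !ref)   # background touching the mask
  cand <- c(inner, outer)
  if (length(cand) == 0) return(mask)
  pick <- cand[sample.int(length(cand), min(n_flips, length(cand)))]
  mask[pick] <- !mask[pick]
  mask
}

# Internal: 6-connected neighbour count of TRUE voxels, zero-padded edges.
neighbor_count <- function(mask) {
  d <- dim(mask)
  m <- array(0L, d)
  m[] <- as.integer(mask)
  out <- array(0L, d)
  sh <- function(src, ax, by) {
    res <- array(0L, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1) {
      idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax]
    }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      src[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (ax in 1:3) {
    out <- out + sh(m, ax, 1) + sh(m, ax, -1)
  }
  out
}
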