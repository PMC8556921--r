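make_slab_mask <- function(z_from, z_to, grid = c(8, 8, 32)) {
  m <- array(FALSE, grid)
  m[3:6, 3:6, z_from:z_to] <- TRUE
  m
}

test_that("a 9-slice span splits exactly 3/3/3 with distal at the caudal end", {
  m <- make_slab_mask(10, 18)
  p <- partition_thirds(m, 3)
  expect_equal(p$region_slices$distal, 10:12)
  expect_equal(p$region_slices$middle, 13:15)
  expect_equal(p$region_slices$proximal, 16:18)
  expect_equal(sum(p$labels != "none"), sum(m))
})

test_that("non-divisible spans follow the half-open voxel-center rule", {
  # brute-force oracle: centers i+0.5 of slices z_lo..z_hi assigned to equal
  # thirds of [z_lo, z_hi+1)
  for (span in c(4, 5, 7, 10, 11, 13)) {
    z_lo <- 6
    z_hi <- z_lo + span - 1
    m <- make_slab_mask(z_lo, z_hi)
    p <- partition_thirds(m, 3)
    centers <- (z_lo:z_hi) + 0.5
    b <- z_lo + span * c(1, 2) / 3
    expected <- ifelse(centers < b[1], "distal",
                       ifelse(centers < b[2], "middle", "proximal"))
    got <- character(span)
    for (r in c("distal", "middle", "proximal")) {
      got[p$region_slices[[r]] - z_lo + 1] <- r
    }
    expect_equal(got, expected, info = paste("span", span))
    extents <- vapply(p$region_slices, length, 0L)
    expect_lte(diff(range(extents)), 1)
    expect_equal(sum(extents), span)
  }
})

test_that("partition covers the mask disjointly and is translation-equivariant", {
  m <- tiny_tube(grid = c(24, 24, 40), from = c(8, 10, 6), to = c(16, 14, 30))
  p <- partition_thirds(m, 3)
  lab <- p$labels
  expect_equal(sum(lab != "none"), sum(m))
  expect_true(all(lab[m] != "none"))
  expect_true(all(lab[!m] == "none"))
  # shifting the mask 4 slices up shifts the labels identically
  m2 <- array(FALSE, dim(m))
  m2[, , 5:40] <- m[, , 1:36]
  p2 <- partition_thirds(m2, 3)
  expect_equal(p2$labels[, , 5:40], p$labels[, , 1:36])
  # flipped caudal end swaps distal and proximal
  pf <- partition_thirds(m, 3, caudal_end = "high")
  expect_equal(pf$region_slices$distal, p$region_slices$proximal)
})

test_that("partition rejects degenerate inputs", {
  expect_error(partition_thirds(array(FALSE, c(8, 8, 8)), 3),
               class = "ligrelax_partition_error")
  expect_error(partition_thirds(make_slab_mask(10, 11), 3),
               class = "ligrelax_partition_error")
  expect_error(partition_thirds(make_slab_mask(5, 20), 5),
               class = "ligrelax_parameter_error")
})

test_that("region summaries report exact means on piecewise-constant maps", {
  m <- tiny_tube()
  p <- partition_thirds(m, 3)
  vals <- c(distal = 54.5, middle = 46.9, proximal = 47.0)
  tm <- render_truth_map(m, p, vals)
  pm <- structure(list(T = tm,
                       status = ifelse(is.na(tm), "outside_mask", "ok")),
                  class = "parameter_map")
  rs <- region_summaries(pm, p)
  expect_equal(rs$mean_ms[rs$region == "distal"], 54.5)
  expect_equal(rs$mean_ms[rs$region == "middle"], 46.9)
  expect_equal(rs$mean_ms[rs$region == "proximal"], 47.0)
  expect_true(all(rs$sd_ms[1:3] == 0))
  # whole-ligament mean is the voxel-count-weighted mean of the regions
  w <- rs$n_included[1:3]
  expect_equal(rs$mean_ms[rs$region == "whole"],
               sum(w * rs$mean_ms[1:3]) / sum(w))

  # knocking out one region flags it missing without touching the others
  pm2 <- pm
  pm2$status[p$labels == "middle"] <- "poor_fit"
  rs2 <- region_summaries(pm2, p)
  expect_true(rs2$missing[rs2$region == "middle"])
  expect_false(rs2$missing[rs2$region == "distal"])
  expect_true(is.na(rs2$mean_ms[rs2$region == "middle"]))
})

test_that("rigid registration recovers identity and known translations", {
  # asymmetric smooth phantom (two blobs) so rotations are identifiable
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  fixed <- array(
    100 * exp(-((g$x - 10)^2 + (g$y - 11)^2 + (g$z - 9)^2) / 30) +
      60 * exp(-((g$x - 15)^2 + (g$y - 13)^2 + (g$z - 17)^2) / 20),
    c(24, 24, 24))
  set.seed(8)
  fixed <- fixed + array(rnorm(24^3, 0, 0.5), c(24, 24, 24))

  reg0 <- register_rigid(fixed, fixed)
  expect_lt(max(abs(reg0$parameters[1:3])), 0.01)
  expect_lt(max(abs(reg0$parameters[4:6])), 0.01)

  applied <- c(2, -1, 0, 0, 0, 0) # 2-voxel x, 1-voxel y translation (1 mm/voxel)
  mv <- transform_volume(fixed, applied)$volume
  mv[is.na(mv)] <- 0
  reg <- register_rigid(mv, fixed)
  expect_lt(max(abs(reg$parameters[1:3] + applied[1:3])), 0.5)

  # composing the recovered transform with the applied one is the identity,
  # checked on physical coordinates of probe points
  Ra <- ligrelax:::euler_matrix(applied[4], applied[5], applied[6])
  Rr <- ligrelax:::euler_matrix(reg$parameters[4], reg$parameters[5],
                                reg$parameters[6])
  ctr <- (dim(fixed) + 1) / 2
  pts <- rbind(c(8, 8, 8), c(16, 12, 10), c(12, 18, 18))
  for (i in seq_len(nrow(pts))) {
    p1 <- as.vector(Rr %*% (pts[i, ] - ctr)) + ctr + reg$parameters[1:3]
    p2 <- as.vector(Ra %*% (p1 - ctr)) + ctr + applied[1:3]
    expect_lt(max(abs(p2 - pts[i, ])), 0.5)
  }
})

test_that("resampling through a transform and its inverse is consistent", {
  f <- array(0, c(8, 8, 8)); f[4, 5, 6] <- 100
  w <- transform_volume(f, c(1, 0, 0, 0, 0, 0))$volume
  expect_equal(unname(which(w == 100, arr.ind = TRUE)[1, ]), c(3, 5, 6))
  w2 <- transform_volume(w, c(-1, 0, 0, 0, 0, 0))$volume
  expect_equal(w2[4, 5, 6], 100)
  expect_error(register_rigid(array(0, c(4, 4)), array(0, c(4, 4, 4))),
               class = "ligrelax_shape_error")
})
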