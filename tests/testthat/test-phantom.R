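test_that("straight tube mask spans its control points and nothing more", {
  m <- make_ligament_mask(c(32, 32, 32), rbind(c(16, 16, 8), c(16, 16, 24)), 1.5)
  expect_true(sum(m) > 0)
  # the tube covers the control-point span plus (at most) its spherical end
  # caps of one slice each
  zs <- which(apply(m, 3, any))
  expect_true(all(8:24 %in% zs))
  expect_gte(min(zs), 8 - 1)
  expect_lte(max(zs), 24 + 1)
  # radius 1.5 around a straight line: in-plane extent stays within 2 voxels
  xs <- which(apply(m, 1, any))
  expect_true(all(xs >= 15 & xs <= 17))
})

test_that("degenerate geometry is rejected", {
  expect_error(make_ligament_mask(c(16, 16, 16), rbind(c(8, 8, 2), c(8, 8, 30)), 2),
               class = "ligrelax_geometry_error")
  expect_error(make_ligament_mask(c(16, 16, 16), rbind(c(8, 8, 2), c(8, 8, 12)), 0.5),
               class = "ligrelax_geometry_error")
  expect_error(make_ligament_mask(c(16, 16, 16), matrix(c(8, 8, 8), 1, 3), 2),
               class = "ligrelax_geometry_error")
})

test_that("curved-centerline mask equals the brute-force distance ball", {
  cp <- rbind(c(6, 6, 4), c(10, 9, 9), c(13, 14, 14), c(18, 16, 20))
  r <- 2.2
  m <- make_ligament_mask(c(24, 24, 24), cp, r)
  poly <- ligrelax:::densify_centerline(cp, step = 0.25)
  # exhaustive scan over every voxel center, independent of the bbox logic
  g <- as.matrix(expand.grid(x = 1:24, y = 1:24, z = 1:24))
  d2 <- apply(g, 1, function(v) min(colSums((t(poly) - v)^2)))
  expected <- array(d2 <= r^2, dim = c(24, 24, 24))
  expect_identical(m, expected)
})

test_that("subject truth draws honour the configured means and dispersion", {
  cfg <- small_cohort_config()
  # zero dispersion returns the configured means exactly
  cfg0 <- cfg
  cfg0$region_truth$sd_ms <- 0
  v <- sample_subject_truth(cfg0, "OA", "ACL", "T1rho", seed = 3)
  expect_equal(unname(v), c(54.5, 46.9, 47.0))
  # draws centre on the configured OA/ACL/T1rho means
  draws <- t(vapply(1:4000, function(s)
    sample_subject_truth(cfg, "OA", "ACL", "T1rho", seed = s), numeric(3)))
  expect_equal(unname(colMeans(draws)), c(54.5, 46.9, 47.0), tolerance = 0.02)
  # law of large numbers at mean 50, sd 5
  cfg50 <- cfg
  cfg50$region_truth$mean_ms <- 50
  cfg50$region_truth$sd_ms <- 5
  big <- t(vapply(1:10000, function(s)
    sample_subject_truth(cfg50, "OA", "ACL", "T1rho", seed = s), numeric(3)))
  expect_lt(abs(mean(big) - 50), 0.2)
  # reproducibility and missing-cell error
  expect_identical(sample_subject_truth(cfg, "OA", "PCL", "T2", seed = 9),
                   sample_subject_truth(cfg, "OA", "PCL", "T2", seed = 9))
  expect_error(sample_subject_truth(cfg, "OA", "LCL", "T2", seed = 1),
               class = "ligrelax_config_error")
})

test_that("rendered truth maps are piecewise constant with exact means", {
  m <- tiny_tube()
  p <- partition_thirds(m, 3)
  const <- render_truth_map(m, p, c(distal = 50, middle = 50, proximal = 50))
  expect_true(all(const[m] == 50))
  expect_true(all(is.na(const[!m])))

  vals <- c(distal = 54.5, middle = 46.9, proximal = 47.0)
  tm <- render_truth_map(m, p, vals)
  for (r in names(vals)) {
    expect_equal(mean(tm[p$labels == r]), unname(vals[[r]]))
  }
  # whole-mask mean is the voxel-count-weighted mean of region values
  n_r <- vapply(names(vals), function(r) sum(p$labels == r), 0)
  expect_equal(mean(tm[m]), sum(n_r * vals) / sum(n_r))

  bad <- partition_thirds(tiny_tube(grid = c(20, 20, 20), from = c(8, 8, 4),
                                    to = c(12, 12, 16)), 3)
  expect_error(render_truth_map(m, bad, vals), class = "ligrelax_shape_error")
})

test_that("simulated series follow the closed-form decay and Rician noise model", {
  m <- array(FALSE, c(6, 6, 6)); m[3, 3, 2:5] <- TRUE
  Tmap <- array(NA_real_, c(6, 6, 6)); Tmap[m] <- 50
  s <- simulate_series(Tmap, 100, default_schedules()$T1rho, 0, seed = 1)
  vox <- s[3, 3, 2, ]
  expect_equal(vox, c(98.02, 81.87, 67.03, 49.66), tolerance = 0.005)

  # Rayleigh background: mean sigma*sqrt(pi/2), sd sigma*sqrt(2 - pi/2)
  sigma <- 3
  Tbig <- array(NA_real_, c(50, 50, 50))
  bg <- simulate_series(Tbig, 100, default_schedules()$T1rho, sigma, seed = 2)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(sd(bg), sigma * sqrt(2 - pi / 2), tolerance = 0.02)

  # bit-identical reproducibility
  s1 <- simulate_series(Tmap, 100, default_schedules()$T2, 2, seed = 7)
  s2 <- simulate_series(Tmap, 100, default_schedules()$T2, 2, seed = 7)
  expect_identical(s1, s2)
  expect_error(simulate_series(Tmap, 100, default_schedules()$T2, -1, seed = 1),
               class = "ligrelax_parameter_error")
})

test_that("mask perturbation hits the Dice target and is monotone in flips", {
  m <- tiny_tube(grid = c(32, 32, 32), radius = 2.5, from = c(10, 12, 5),
                 to = c(20, 18, 27))
  expect_identical(perturb_mask(m, 1, seed = 1), m)
  p8 <- perturb_mask(m, 0.8, seed = 5)
  expect_gte(dice_coefficient(m, p8), 0.75)
  expect_lte(dice_coefficient(m, p8), 0.85)
  expect_gt(sum(p8), 0)

  # Dice never increases as boundary flips accumulate
  set.seed(11)
  cur <- m
  d_prev <- 1
  for (i in 1:12) {
    cur <- ligrelax:::flip_boundary(cur, ref = m, n_flips = 15)
    d_now <- dice_coefficient(m, cur)
    expect_lte(d_now, d_prev + 1e-12)
    d_prev <- d_now
  }

  empty <- array(FALSE, c(8, 8, 8))
  expect_error(perturb_mask(empty, 0.8, seed = 1),
               class = "ligrelax_geometry_error")
})

test_that("cohort simulation writes the expected tree deterministically", {
  cfg <- small_cohort_config(n_oa = 2, n_control = 1)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  man <- simulate_cohort(cfg, d1)
  expect_length(man$subjects, 3)
  for (subj in man$subjects) {
    files <- list.files(file.path(d1, subj$id))
    expect_length(grep("^series_", files), 2)   # one series per parameter
    expect_length(grep("^mask_", files), 6)     # 2 ligaments x 3 readings
  }
  expect_equal(vapply(man$subjects, `[[`, "", "group"),
               c("OA", "OA", "control"))
  # deterministic re-run: identical manifests and identical mask volumes
  simulate_cohort(cfg, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.json"))),
                   unname(tools::md5sum(file.path(d2, "manifest.json"))))
  f <- man$subjects[[1]]$files[["mask_ACL_r1_t1"]]
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("phantom ligaments are disjoint and the default cohort is 15 + 6", {
  cfg <- phantom_config()
  expect_equal(cfg$n_oa + cfg$n_control, 21)
  masks <- ligrelax:::phantom_masks(small_cohort_config())
  expect_false(any(masks$ACL & masks$PCL))
  expect_gt(sum(masks$ACL), 0)
  expect_gt(sum(masks$PCL), 0)
})
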