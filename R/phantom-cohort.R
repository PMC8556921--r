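#' Configuration for a synthetic ligament cohort
#'
#' Defines the digital phantom: grid geometry, cohort sizes (15 OA and 6
#' control subjects by default), the generating subregional relaxation
#' structure (defaults from [default_region_truth()]), signal level and
#' Rician channel noise (default SNR S0/sigma = 50, at which exclusion
#' rates at truth are near zero), the two acquisition schedules, and the
#' Dice targets for the simulated second reader and second timepoint.
#'
#' @param grid_shape 3 positive integers (voxels); default 64^3.
#' @param voxel_spacing mm per axis; default 1 mm isotropic.
#' @param craniocaudal_axis array axis running superior-inferior (default 3).
#' @param n_oa,n_control subject counts (defaults 15 and 6).
#' @param region_truth data.frame as [default_region_truth()].
#' @param s0_mean equilibrium signal inside ligaments (arbitrary units).
#' @param noise_sigma Rician channel SD in signal units.
#' @param schedules named list of [acquisition_schedule()]s, one per parameter.
#' @param dice_inter,dice_intra Dice targets for the second rater's mask and
#'   the first rater's second-timepoint mask.
#' @param tube_radius ligament tube radius in voxels.
#' @param seed base RNG seed; every stochastic step derives from it.
#' @return `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           voxel_spacing = c(1, 1, 1),
                           craniocaudal_axis = 3,
                           n_oa = 15, n_control = 6,
                           region_truth = default_region_truth(),
                           s0_mean = 100, noise_sigma = 2,
                           schedules = default_schedules(),
                           dice_inter = 0.85, dice_intra = 0.92,
                           tube_radius = 2.5,
                           seed = 42) {
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stop_ligrelax("grid_shape must be 3 integers >= 8", "ligrelax_config_error")
  }
  if (n_oa < 1 || n_control < 1) {
    stop_ligrelax("subject counts must be >= 1", "ligrelax_config_error")
  }
  if (noise_sigma < 0 || s0_mean <= 0) {
    stop_ligrelax("need s0_mean > 0 and noise_sigma >= 0", "ligrelax_config_error")
  }
  if (!(craniocaudal_axis %in% 1:3)) {
    stop_ligrelax("craniocaudal_axis must be 1, 2 or 3", "ligrelax_config_error")
  }
  if (any(region_truth$mean_ms <= 0) || any(region_truth$sd_ms < 0)) {
    stop_ligrelax("region_truth means must be > 0 ms and SDs >= 0",
                  "ligrelax_config_error")
  }
  for (s in schedules) {
    if (!inherits(s, "acquisition_schedule")) {
      stop_ligrelax("schedules must be acquisition_schedule objects",
                    "ligrelax_config_error")
    }
  }
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    craniocaudal_axis = as.integer(craniocaudal_axis),
    n_oa = as.integer(n_oa), n_control = as.integer(n_control),
    region_truth = region_truth,
    s0_mean = s0_mean, noise_sigma = noise_sigma,
    schedules = schedules,
    dice_inter = dice_inter, dice_intra = dice_intra,
    tube_radius = tube_radius,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Internal: the two ligament tubes, oblique to the craniocaudal axis, in
# normalized coordinates scaled to the grid. Disjointness is asserted.
phantom_masks <- function(config) {
  g <- config$grid_shape
  scale3 <- function(m) sweep(m, 2, g, "*")
  acl_cp <- scale3(rbind(c(0.30, 0.40, 0.18), c(0.42, 0.45, 0.50),
                         c(0.55, 0.52, 0.82)))
  pcl_cp <- scale3(rbind(c(0.72, 0.55, 0.18), c(0.62, 0.62, 0.50),
                         c(0.48, 0.68, 0.82)))
  # keep the craniocaudal extent on the configured axis
  if (config$craniocaudal_axis != 3) {
    ord <- switch(config$craniocaudal_axis, `1` = c(3, 2, 1), `2` = c(1, 3, 2))
    acl_cp <- acl_cp[, ord]; pcl_cp <- pcl_cp[, ord]
  }
  acl <- make_ligament_mask(g, acl_cp, config$tube_radius)
  pcl <- make_ligament_mask(g, pcl_cp, config$tube_radius)
  if (any(acl & pcl)) {
    stop_ligrelax("phantom geometry error: ACL and PCL masks overlap",
                  "ligrelax_geometry_error")
  }
  list(ACL = acl, PCL = pcl)
}

# Internal: write a 3D/4D array as NIfTI with the configured spacing.
write_volume <- function(arr, path, spacing, datatype = "float") {
  img <- RNifti::asNifti(arr)
  pd <- c(spacing, rep(1, length(dim(arr)) - 3))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Simulate and write a full synthetic cohort
#'
#' Generates the whole study on disk: for every subject, a 4D magnitude
#' series per parameter (mono-exponential decay through the subject's true
#' subregional relaxation times, Rician noise everywhere), the two ligament
#' masks for the first reader plus Dice-calibrated second-timepoint and
#' second-reader masks, the true relaxation maps, and a JSON manifest with
#' group labels, per-subject seeds and the generating region values.
#' Deterministic for a fixed config seed.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
simulate_cohort <- function(config, out_dir) {
  if (!inherits(config, "phantom_config")) {
    stop_ligrelax("config must be a phantom_config", "ligrelax_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_ligrelax(sprintf("cannot create output directory %s", out_dir),
                  "ligrelax_io_error")
  }
  masks <- phantom_masks(config)
  labels <- lapply(masks, partition_thirds,
                   craniocaudal_axis = config$craniocaudal_axis)
  n_total <- config$n_oa + config$n_control
  groups <- c(rep("OA", config$n_oa), rep("control", config$n_control))
  params <- names(config$schedules)
  ligaments <- names(masks)

  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    sid <- sprintf("S%02d", s)
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    entry <- list(id = sid, group = groups[s], files = list(), truth = list(),
                  seeds = list())

    # masks: rater 1 timepoint 1 is the base tube; the second timepoint and
    # second reader are Dice-calibrated perturbations
    for (li in seq_along(ligaments)) {
      lig <- ligaments[li]
      seed_t2 <- derive_seed(config$seed, s, li, 3)
      seed_r2 <- derive_seed(config$seed, s, li, 4)
      m_r1t1 <- masks[[lig]]
      m_r1t2 <- perturb_mask(m_r1t1, config$dice_intra, seed_t2)
      m_r2t1 <- perturb_mask(m_r1t1, config$dice_inter, seed_r2)
      for (mk in list(list(m_r1t1, "r1_t1"), list(m_r1t2, "r1_t2"),
                      list(m_r2t1, "r2_t1"))) {
        fn <- sprintf("mask_%s_%s.nii.gz", lig, mk[[2]])
        write_volume(array(as.integer(mk[[1]]), dim = dim(mk[[1]])),
                     file.path(sdir, fn), config$voxel_spacing,
                     datatype = "uint8")
        entry$files[[sprintf("mask_%s_%s", lig, mk[[2]])]] <- file.path(sid, fn)
      }
      entry$seeds[[paste0("mask_", lig)]] <- c(t2 = seed_t2, r2 = seed_r2)
    }

    # true maps and noisy series per parameter
    for (pi in seq_along(params)) {
      par <- params[pi]
      Tmap <- array(NA_real_, dim = config$grid_shape)
      for (li in seq_along(ligaments)) {
        lig <- ligaments[li]
        seed_truth <- derive_seed(config$seed, s, li, pi, 1)
        vals <- sample_subject_truth(config, groups[s], lig, par, seed_truth)
        entry$truth[[paste(lig, par, sep = "_")]] <- as.list(vals)
        entry$seeds[[paste("truth", lig, par, sep = "_")]] <- seed_truth
        part <- render_truth_map(masks[[lig]], labels[[lig]], vals)
        Tmap[!is.na(part)] <- part[!is.na(part)]
      }
      S0map <- array(NA_real_, dim = config$grid_shape)
      S0map[!is.na(Tmap)] <- config$s0_mean
      seed_noise <- derive_seed(config$seed, s, pi, 2)
      series <- simulate_series(Tmap, S0map, config$schedules[[par]],
                                config$noise_sigma, seed_noise)
      entry$seeds[[paste0("noise_", par)]] <- seed_noise
      fn_series <- sprintf("series_%s.nii.gz", par)
      fn_truth <- sprintf("truth_%s.nii.gz", par)
      write_volume(series, file.path(sdir, fn_series), config$voxel_spacing)
      truth_out <- Tmap
      truth_out[is.na(truth_out)] <- -1 # sentinel for "undefined"
      write_volume(truth_out, file.path(sdir, fn_truth), config$voxel_spacing)
      entry$files[[paste0("series_", par)]] <- file.path(sid, fn_series)
      entry$files[[paste0("truth_", par)]] <- file.path(sid, fn_truth)
    }
    subjects[[s]] <- entry
  }

  manifest <- list(
    format = "ligrelax-cohort-1",
    grid_shape = config$grid_shape,
    voxel_spacing = config$voxel_spacing,
    craniocaudal_axis = config$craniocaudal_axis,
    s0_mean = config$s0_mean,
    noise_sigma = config$noise_sigma,
    seed = config$seed,
    schedules = lapply(config$schedules, function(s) {
      list(mode = s$mode, times = s$times)
    }),
    ligaments = ligaments,
    parameters = params,
    subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param dataset_dir directory written by [simulate_cohort()].
#' @return the manifest list.
#' @export
read_manifest <- function(dataset_dir) {
  path <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(path)) {
    stop_ligrelax(sprintf("no manifest.json under %s", dataset_dir),
                  "ligrelax_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
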