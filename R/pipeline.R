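# Pipeline orchestration: simulate -> (register) -> fit -> regions -> stats.
# All file I/O lives here; the compute modules stay pure.

STATUS_CODES <- c(outside_mask = 0L, ok = 1L, below_noise_floor = 2L,
                  poor_fit = 3L, not_converged = 4L)

# Internal: read a NIfTI volume as a plain array.
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Fit parameter maps for every subject of a cohort
#'
#' For each subject and parameter: optionally register every contrast
#' volume rigidly to the first (anatomical reference) contrast, estimate
#' the noise floor from the out-of-ligament background, fit the
#' mono-exponential map over the union of all available masks, and write
#' the relaxation-time map, R-squared map and status map as NIfTI. A
#' failing subject is recorded and the run continues.
#'
#' @param dataset_dir cohort directory with a `manifest.json`.
#' @param out_dir output directory for maps and the QC table.
#' @param options a [fit_options()]; its `noise_floor` is overridden per
#'   series unless `noise_floor_method = "fixed"`.
#' @param register run rigid registration of each later contrast to the
#'   first (default FALSE; the phantom is pre-aligned).
#' @param noise_floor_method `"background"` (mean + 2 SD outside the
#'   ligaments), `"percentile"` (25th of the first contrast) or `"fixed"`
#'   (use `options$noise_floor` as given).
#' @return list `qc` (data.frame: subject, parameter, noise_floor, counts
#'   per status) and `failures` (data.frame subject/parameter/message).
#' @export
run_fit_stage <- function(dataset_dir, out_dir, options = fit_options(),
                          register = FALSE,
                          noise_floor_method = c("background", "percentile",
                                                 "fixed")) {
  noise_floor_method <- match.arg(noise_floor_method)
  man <- read_manifest(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc_rows <- list(); fail_rows <- list()

  for (subj in man$subjects) {
    sdir <- file.path(out_dir, subj$id)
    dir.create(sdir, showWarnings = FALSE)
    # union of every rater's masks, both ligaments: fit once per parameter
    mask_names <- grep("^mask_", names(subj$files), value = TRUE)
    masks <- lapply(mask_names, function(nm) {
      read_volume(file.path(dataset_dir, subj$files[[nm]])) > 0
    })
    fit_mask <- Reduce(`|`, masks)

    for (par in man$parameters) {
      res <- tryCatch({
        series <- read_volume(file.path(dataset_dir,
                                        subj$files[[paste0("series_", par)]]))
        if (register) {
          spacing <- unlist(man$voxel_spacing)
          for (j in seq_len(dim(series)[4])[-1]) {
            reg <- register_rigid(series[, , , j], series[, , , 1],
                                  spacing = spacing)
            resampled <- reg$resampled
            resampled[is.na(resampled)] <- 0
            series[, , , j] <- resampled
          }
        }
        floor_est <- switch(
          noise_floor_method,
          background = estimate_noise_floor(series, background_mask = !fit_mask),
          percentile = estimate_noise_floor(series, percentile = 25),
          fixed = options$noise_floor
        )
        opt <- options
        opt$noise_floor <- floor_est
        map <- build_map(series, fit_mask, unlist(man$schedules[[par]]$times),
                         opt)
        tmap_out <- map$T
        tmap_out[is.na(tmap_out)] <- -1
        r2_out <- map$r_squared
        r2_out[is.na(r2_out)] <- -1
        status_out <- array(STATUS_CODES[map$status], dim = dim(map$status))
        spacing <- unlist(man$voxel_spacing)
        write_volume(tmap_out, file.path(sdir, sprintf("map_%s.nii.gz", par)),
                     spacing)
        write_volume(r2_out, file.path(sdir, sprintf("r2_%s.nii.gz", par)),
                     spacing)
        write_volume(status_out,
                     file.path(sdir, sprintf("status_%s.nii.gz", par)),
                     spacing, datatype = "uint8")
        counts <- as.list(map$qc)
        data.frame(subject = subj$id, parameter = par,
                   noise_floor = floor_est,
                   n_ok = counts$ok %||% 0,
                   n_below_noise_floor = counts$below_noise_floor %||% 0,
                   n_poor_fit = counts$poor_fit %||% 0,
                   n_not_converged = counts$not_converged %||% 0,
                   stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fail_rows[[length(fail_rows) + 1]] <- data.frame(
          subject = subj$id, parameter = par,
          message = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        qc_rows[[length(qc_rows) + 1]] <- res
      }
    }
  }
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else NULL
  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else
    data.frame(subject = character(), parameter = character(),
               message = character())
  if (!is.null(qc)) {
    write.csv(qc, file.path(out_dir, "qc_fit.csv"), row.names = FALSE)
  }
  list(qc = qc, failures = failures)
}

#' Extract the long-format regional measure table
#'
#' For every subject, parameter, ligament and mask reading (rater x
#' timepoint): partition the mask into thirds along the craniocaudal axis
#' and summarize the fitted map over quality-passing voxels, yielding one
#' row per region (distal, middle, proximal, whole).
#'
#' @param dataset_dir cohort directory (masks + manifest).
#' @param maps_dir output of [run_fit_stage()].
#' @param out_dir where `measures.csv` is written (default `maps_dir`).
#' @param min_included minimum included voxels per region summary.
#' @return data.frame: subject, group, ligament, parameter, region, rater,
#'   timepoint, value_ms, median_ms, sd_ms, n_included.
#' @export
run_regions_stage <- function(dataset_dir, maps_dir, out_dir = maps_dir,
                              min_included = 5L) {
  man <- read_manifest(dataset_dir)
  axis <- man$craniocaudal_axis
  rows <- list()
  for (subj in man$subjects) {
    for (par in man$parameters) {
      map_path <- file.path(maps_dir, subj$id, sprintf("map_%s.nii.gz", par))
      status_path <- file.path(maps_dir, subj$id,
                               sprintf("status_%s.nii.gz", par))
      if (!file.exists(map_path)) next # subject failed in the fit stage
      Tmap <- read_volume(map_path)
      Tmap[Tmap < 0] <- NA
      status_code <- read_volume(status_path)
      status <- array(names(STATUS_CODES)[match(status_code, STATUS_CODES)],
                      dim = dim(status_code))
      pm <- structure(list(T = Tmap, status = status), class = "parameter_map")
      for (lig in man$ligaments) {
        for (reading in list(c("r1", "t1", 1L), c("r1", "t2", 2L),
                             c("r2", "t1", 1L))) {
          key <- sprintf("mask_%s_%s_%s", lig, reading[1], reading[2])
          if (is.null(subj$files[[key]])) next
          mask <- read_volume(file.path(dataset_dir, subj$files[[key]])) > 0
          labels <- partition_thirds(mask, axis)
          summ <- region_summaries(pm, labels, min_included = min_included)
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj$id, group = subj$group, ligament = lig,
            parameter = par, region = summ$region,
            rater = toupper(reading[1]), timepoint = as.integer(reading[3]),
            value_ms = summ$mean_ms, median_ms = summ$median_ms,
            sd_ms = summ$sd_ms, n_included = summ$n_included,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out, file.path(out_dir, "measures.csv"), row.names = FALSE)
  out
}

#' Cohort statistics stage
#'
#' Runs the three cohort analyses on a long-format measure table and writes
#' them as CSV: the within-ligament variation table (per-region means/SDs,
#' omnibus test and effect size), the between-group Kruskal-Wallis table on
#' percentage differences, and the inter/intra-rater ICC table. Groups with
#' fewer than 2 subjects skip the statistics with a notice.
#'
#' @param measure_table data.frame from [run_regions_stage()] or a CSV path.
#' @param out_dir where the tables are written.
#' @param alpha significance level (default 0.05).
#' @param subgroup_col optional extra grouping column: adds a supplementary
#'   Kruskal-Wallis table split by it.
#' @return list `variation`, `group_comparison`, `reliability`, and
#'   optionally `supplementary`.
#' @export
run_stats_stage <- function(measure_table, out_dir, alpha = 0.05,
                            subgroup_col = NULL) {
  if (is.character(measure_table)) {
    measure_table <- read.csv(measure_table, stringsAsFactors = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- table(unique(measure_table[, c("subject", "group")])$group)
  if (any(counts < 2)) {
    message("statistics skipped: a group has fewer than 2 subjects")
    return(invisible(NULL))
  }
  drop_missing <- measure_table[!is.na(measure_table$value_ms), ]

  t4 <- variation_analysis(drop_missing, alpha = alpha)
  t5 <- group_variation_comparison(drop_missing)
  t6 <- reliability_analysis(drop_missing)
  write.csv(t4, file.path(out_dir, "variation.csv"), row.names = FALSE)
  write.csv(t5, file.path(out_dir, "group_comparison.csv"),
            row.names = FALSE)
  write.csv(t6, file.path(out_dir, "reliability.csv"),
            row.names = FALSE)
  out <- list(variation = t4, group_comparison = t5, reliability = t6)
  if (!is.null(subgroup_col) && subgroup_col %in% names(drop_missing)) {
    supp <- group_variation_comparison(drop_missing, group_col = subgroup_col)
    write.csv(supp, file.path(out_dir, "supplementary_subgroup.csv"),
              row.names = FALSE)
    out$supplementary <- supp
  }
  out
}

#' Run the full pipeline
#'
#' simulate (when given a [phantom_config()]) -> fit -> regions -> stats.
#' A run manifest records the package version, seed and a hash of the
#' configuration.
#'
#' @param config a [phantom_config()], or the path of an existing cohort
#'   directory.
#' @param out_dir output root; gets `dataset/` (if simulated), `maps/` and
#'   `stats/` subdirectories.
#' @param fit_opts a [fit_options()].
#' @param register enable rigid registration in the fit stage.
#' @param alpha significance level for the statistics stage.
#' @return list `dataset_dir`, `fit` (QC + failures), `measures`, `stats`.
#' @export
run_all <- function(config, out_dir, fit_opts = fit_options(),
                    register = FALSE, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(config, "phantom_config")) {
    dataset_dir <- file.path(out_dir, "dataset")
    simulate_cohort(config, dataset_dir)
    cfg_for_hash <- config
  } else if (is.character(config) && dir.exists(config)) {
    dataset_dir <- config
    cfg_for_hash <- read_manifest(dataset_dir)
  } else {
    stop_ligrelax("config must be a phantom_config or a dataset directory",
                  "ligrelax_config_error")
  }
  maps_dir <- file.path(out_dir, "maps")
  stats_dir <- file.path(out_dir, "stats")
  fit <- run_fit_stage(dataset_dir, maps_dir, options = fit_opts,
                       register = register)
  if (is.null(fit$qc)) {
    stop_ligrelax("fit stage failed for every subject", "ligrelax_stage_error")
  }
  measures <- run_regions_stage(dataset_dir, maps_dir)
  stats <- run_stats_stage(measures, stats_dir, alpha = alpha)

  cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  run_manifest <- list(
    package = "ligrelax",
    version = as.character(utils::packageVersion("ligrelax")),
    config_hash = unname(tools::md5sum(tmp)),
    dataset_dir = dataset_dir,
    registered = register,
    alpha = alpha
  )
  unlink(tmp)
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(dataset_dir = dataset_dir, fit = fit, measures = measures,
       stats = stats, run_manifest = run_manifest)
}

#' Load a phantom configuration from YAML
#'
#' Accepts the [phantom_config()] fields; `schedules` as a mapping of
#' parameter name to `{mode, times}`.
#'
#' @param path YAML file.
#' @return a [phantom_config()].
#' @export
load_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$schedules)) {
    y$schedules <- lapply(y$schedules, function(s) {
      acquisition_schedule(s$mode, as.numeric(s$times))
    })
  }
  if (!is.null(y$region_truth)) {
    y$region_truth <- as.data.frame(lapply(y$region_truth, unlist),
                                    stringsAsFactors = FALSE)
  }
  do.call(phantom_config, y)
}
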