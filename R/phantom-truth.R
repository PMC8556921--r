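#' Draw one subject's true subregional relaxation times
#'
#' Samples the (distal, middle, proximal) true relaxation times for one
#' subject, ligament and parameter from normal distributions with the
#' configured per-region mean/SD, truncated below at 1 ms. This reproduces
#' the between-subject dispersion that cohort tables report as SDs.
#'
#' @param config a [phantom_config()].
#' @param group `"OA"` or `"control"`.
#' @param ligament `"ACL"` or `"PCL"`.
#' @param parameter `"T1rho"` or `"T2"`.
#' @param seed RNG seed; draws are reproducible for a fixed seed.
#' @return named numeric vector `c(distal=, middle=, proximal=)` in ms.
#' @export
sample_subject_truth <- function(config, group, ligament, parameter, seed) {
  cell <- lookup_region_truth(config$region_truth, group, ligament, parameter)
  set.seed(seed)
  vals <- rnorm(3, mean = cell$mean_ms, sd = cell$sd_ms)
  vals <- pmax(vals, 1)
  names(vals) <- c("distal", "middle", "proximal")
  vals
}

#' Render a piecewise-constant true relaxation map
#'
#' Paints each subregion of a mask with its true relaxation time; voxels
#' outside the mask carry `NA` (undefined).
#'
#' @param mask 3D logical array.
#' @param subregion_labels a [partition_thirds()] result on the same grid.
#' @param region_values named numeric vector with entries `distal`,
#'   `middle`, `proximal`, all > 0 ms.
#' @return numeric 3D array, `NA` outside the mask.
#' @export
render_truth_map <- function(mask, subregion_labels, region_values) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(subregion_labels$labels))) {
    stop_ligrelax("labels and mask must share a grid", "ligrelax_shape_error")
  }
  need <- c("distal", "middle", "proximal")
  if (!all(need %in% names(region_values)) || any(region_values[need] <= 0)) {
    stop_ligrelax("region_values must name distal/middle/proximal, all > 0 ms",
                  "ligrelax_parameter_error")
  }
  lab <- subregion_labels$labels
  if (!all(which(lab != "none") %in% which(mask)) ||
      sum(lab != "none") != sum(mask)) {
    stop_ligrelax("subregion labels must exactly cover the mask",
                  "ligrelax_shape_error")
  }
  out <- array(NA_real_, dim = dim(mask))
  for (r in need) out[lab == r] <- region_values[[r]]
  out
}
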