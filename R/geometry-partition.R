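#' Partition a ligament mask into proximal/middle/distal thirds
#'
#' Splits the mask along the craniocaudal axis by its maximal extent: the
#' continuous interval from the first to one past the last in-mask slice is
#' divided into three equal half-open sub-intervals, and every in-mask voxel
#' is assigned by its slice center. The most caudal third is distal (tibial
#' end) and the most cranial is proximal (femoral end), for both cruciate
#' ligaments.
#'
#' @param mask non-empty 3D logical array spanning >= 3 slices along the axis.
#' @param craniocaudal_axis which array axis (1, 2 or 3) runs
#'   superior-inferior.
#' @param caudal_end `"low"` if low indices along that axis are caudal
#'   (default), `"high"` otherwise.
#' @return `subregion_labels` object: `labels` (character 3D array with
#'   values distal/middle/proximal/none), `axis`, `boundaries` (the two
#'   interior split points in continuous slice coordinates), `slice_range`,
#'   and `region_slices` (slice indices per region).
#' @examples
#' m <- array(FALSE, c(4, 4, 12)); m[2:3, 2:3, 3:11] <- TRUE
#' p <- partition_thirds(m, 3)
#' p$region_slices
#' @export
partition_thirds <- function(mask, craniocaudal_axis,
                             caudal_end = c("low", "high")) {
  caudal_end <- match.arg(caudal_end)
  if (!is.logical(mask)) mask <- mask > 0
  if (!(craniocaudal_axis %in% 1:3)) {
    stop_ligrelax("craniocaudal_axis must be 1, 2 or 3", "ligrelax_parameter_error")
  }
  if (sum(mask) == 0) {
    stop_ligrelax("mask is empty", "ligrelax_partition_error")
  }
  present <- apply(mask, craniocaudal_axis, any)
  z_lo <- which(present)[1]
  z_hi <- tail(which(present), 1)
  if (z_hi - z_lo + 1 < 3) {
    stop_ligrelax("mask must span at least 3 slices along the craniocaudal axis",
                  "ligrelax_partition_error")
  }

  # Half-open thirds of [z_lo, z_hi + 1); slice i has center i + 0.5.
  L <- z_hi + 1 - z_lo
  b1 <- z_lo + L / 3
  b2 <- z_lo + 2 * L / 3
  slices <- z_lo:z_hi
  centers <- slices + 0.5
  third <- ifelse(centers < b1, 1L, ifelse(centers < b2, 2L, 3L))

  # Order along the axis: third 1 is at the low-index end.
  region_of_third <- if (caudal_end == "low") {
    c("distal", "middle", "proximal")
  } else {
    c("proximal", "middle", "distal")
  }

  labels <- array("none", dim = dim(mask))
  idx_mask <- which(mask, arr.ind = TRUE)
  voxel_third <- third[match(idx_mask[, craniocaudal_axis], slices)]
  labels[idx_mask] <- region_of_third[voxel_third]

  region_slices <- lapply(1:3, function(t) slices[third == t])
  names(region_slices) <- region_of_third

  structure(list(
    labels = labels,
    axis = craniocaudal_axis,
    caudal_end = caudal_end,
    boundaries = c(b1, b2),
    slice_range = c(z_lo, z_hi),
    region_slices = region_slices[c("distal", "middle", "proximal")]
  ), class = "subregion_labels")
}

#' Per-region summary statistics of a parameter map
#'
#' Computes mean, SD and median relaxation time over the quality-passing
#' (status `ok`) voxels of each third and of the whole ligament. Regions
#' with fewer included voxels than `min_included` are flagged missing.
#'
#' @param parameter_map a [build_map()] result.
#' @param labels a [partition_thirds()] result on the same grid.
#' @param min_included minimum `ok` voxels for a summary to count (default 5).
#' @param sd_denominator `"n"` for the population SD (default) or `"n-1"`.
#' @return data.frame with rows distal, middle, proximal, whole and columns
#'   `region`, `n_total`, `n_included`, `mean_ms`, `sd_ms`, `median_ms`,
#'   `missing`.
#' @export
region_summaries <- function(parameter_map, labels, min_included = 5L,
                             sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!identical(dim(parameter_map$T), dim(labels$labels))) {
    stop_ligrelax("map and labels must share a grid", "ligrelax_shape_error")
  }
  lab <- as.vector(labels$labels)
  Tv <- as.vector(parameter_map$T)
  ok <- as.vector(parameter_map$status) == "ok"

  one <- function(sel, name) {
    n_total <- sum(sel)
    inc <- sel & ok
    n_inc <- sum(inc)
    if (n_inc >= min_included) {
      x <- Tv[inc]
      m <- mean(x)
      s <- if (sd_denominator == "n") sqrt(mean((x - m)^2)) else sd(x)
      data.frame(region = name, n_total = n_total, n_included = n_inc,
                 mean_ms = m, sd_ms = s, median_ms = median(x),
                 missing = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(region = name, n_total = n_total, n_included = n_inc,
                 mean_ms = NA_real_, sd_ms = NA_real_, median_ms = NA_real_,
                 missing = TRUE, stringsAsFactors = FALSE)
    }
  }

  out <- rbind(
    one(lab == "distal", "distal"),
    one(lab == "middle", "middle"),
    one(lab == "proximal", "proximal"),
    one(lab != "none", "whole")
  )
  rownames(out) <- NULL
  out
}
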