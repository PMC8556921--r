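# Cohort-level statistical tables from the long-format measure table.
# Expected columns: subject, group, ligament, parameter, region, value_ms,
# and optionally rater and timepoint (defaulting to the first rater's first
# timepoint for all group-level analyses).

# Internal: restrict a measure table to the primary reading (first rater,
# first timepoint) and check required columns.
primary_reading <- function(tab, required = c("subject", "group", "ligament",
                                              "parameter", "region", "value_ms")) {
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop_ligrelax(paste("measure table lacks columns:",
                        paste(miss, collapse = ", ")),
                  "ligrelax_parameter_error")
  }
  if ("rater" %in% names(tab)) {
    tab <- tab[tab$rater == sort(unique(tab$rater))[1], , drop = FALSE]
  }
  if ("timepoint" %in% names(tab)) {
    tab <- tab[tab$timepoint == min(tab$timepoint), , drop = FALSE]
  }
  tab
}

# Internal: subjects x regions value matrix for one (group, ligament,
# parameter) cell. A subject can lose a region legitimately (e.g. every
# voxel below the noise floor); with `drop_incomplete` those subjects are
# removed with a notice, otherwise incomplete cells are an error.
region_matrix <- function(tab, regions = c("distal", "middle", "proximal"),
                          drop_incomplete = FALSE) {
  subjects <- sort(unique(tab$subject))
  M <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  for (r in seq_along(regions)) {
    sub <- tab[tab$region == regions[r], ]
    M[match(sub$subject, subjects), r] <- sub$value_ms
  }
  if (anyNA(M)) {
    if (!drop_incomplete) {
      stop_ligrelax("incomplete region values for some subjects",
                    "ligrelax_incomplete_data_error")
    }
    bad <- rownames(M)[!complete.cases(M)]
    message(sprintf("dropping %d subject(s) with incomplete region values: %s",
                    length(bad), paste(bad, collapse = ", ")))
    M <- M[complete.cases(M), , drop = FALSE]
  }
  M
}

#' Within-ligament variation analysis across the three subregions
#'
#' For every (group, ligament, parameter) cell: per-region means and SDs
#' across subjects, the within-ligament test via [rm_anova()] routing
#' (repeated-measures ANOVA, Greenhouse-Geisser corrected, or Friedman),
#' the matching effect size (partial eta squared or Kendall's W), and -
#' when the omnibus test is significant - pairwise post-hoc flags in M/P/D
#' notation (paired t after ANOVA routes, exact Wilcoxon signed-rank after
#' Friedman routes). No multiplicity correction is applied.
#'
#' @param cohort_table long-format measure table (see module docs).
#' @param alpha significance level (default 0.05).
#' @param exact_n_max exact-Friedman threshold, passed through.
#' @return data.frame with one row per (group, ligament, parameter):
#'   region means/SDs, pairwise flags, `p_value`, `route`, `effect_size`.
#' @export
variation_analysis <- function(cohort_table, alpha = 0.05, exact_n_max = 8L) {
  tab <- primary_reading(cohort_table)
  tab <- tab[tab$region %in% c("distal", "middle", "proximal"), ]
  cells <- unique(tab[, c("group", "ligament", "parameter")])
  cells <- cells[order(cells$group, cells$ligament, cells$parameter), ]
  regions <- c("distal", "middle", "proximal")
  letter <- c(distal = "D", middle = "M", proximal = "P")

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- tab[tab$group == cell$group & tab$ligament == cell$ligament &
                 tab$parameter == cell$parameter, ]
    M <- region_matrix(sub, regions, drop_incomplete = TRUE)
    res <- rm_anova(M, alpha = alpha, exact_n_max = exact_n_max)

    flags <- setNames(rep("", 3), regions)
    if (is.finite(res$p_reported) && res$p_reported < alpha) {
      parametric <- res$route != "friedman"
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        pc <- pairwise_compare(M[, pair[1]], M[, pair[2]],
                               parametric = parametric)
        if (pc$p < alpha) {
          a <- regions[pair[1]]; b <- regions[pair[2]]
          flags[a] <- paste0(flags[a], ifelse(nzchar(flags[a]), ", ", ""), letter[b])
          flags[b] <- paste0(flags[b], ifelse(nzchar(flags[b]), ", ", ""), letter[a])
        }
      }
    }
    data.frame(
      group = cell$group, ligament = cell$ligament, parameter = cell$parameter,
      n = nrow(M),
      distal_mean = mean(M[, 1]), distal_sd = sd(M[, 1]), distal_sig = flags[1],
      middle_mean = mean(M[, 2]), middle_sd = sd(M[, 2]), middle_sig = flags[2],
      proximal_mean = mean(M[, 3]), proximal_sd = sd(M[, 3]), proximal_sig = flags[3],
      p_value = res$p_reported, route = res$route,
      effect_size = res$effect_size,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-group comparison of within-ligament variation
#'
#' For each (ligament, parameter) and each contrast (distal vs middle,
#' distal vs proximal): compute per-subject percentage differences
#' 100 (distal - other) / other and compare their distribution across
#' groups with a Kruskal-Wallis test. Also serves subgroup splits by
#' passing a different grouping column.
#'
#' @param cohort_table long-format measure table.
#' @param group_col grouping column name (default `"group"`).
#' @return data.frame with 2 x parameters x ligaments rows: per-group mean
#'   ranks and n, `H`, `df`, `p`.
#' @export
group_variation_comparison <- function(cohort_table, group_col = "group") {
  tab <- primary_reading(cohort_table,
                         required = c("subject", group_col, "ligament",
                                      "parameter", "region", "value_ms"))
  contrasts <- list(`D and M` = "middle", `D and P` = "proximal")
  cells <- unique(tab[, c("ligament", "parameter")])
  cells <- cells[order(cells$ligament, cells$parameter), ]
  groups <- unique(tab[[group_col]])
  groups <- if (setequal(groups, c("OA", "control"))) {
    c("OA", "control")
  } else {
    sort(groups)
  }

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- tab[tab$ligament == cell$ligament & tab$parameter == cell$parameter, ]
    M <- region_matrix(sub, drop_incomplete = TRUE)
    subj_group <- sub[[group_col]][match(rownames(M), sub$subject)]
    for (cn in names(contrasts)) {
      other <- contrasts[[cn]]
      pd <- percent_difference(M[, "distal"], M[, other])
      byg <- split(pd, factor(subj_group, levels = groups))
      kw <- kruskal_wallis(byg)
      row <- data.frame(ligament = cell$ligament, parameter = cell$parameter,
                        contrast = cn, H = kw$H, df = kw$df, p = kw$p,
                        stringsAsFactors = FALSE)
      for (g in seq_along(groups)) {
        row[[paste0("mean_rank_", groups[g])]] <- kw$mean_ranks[g]
        row[[paste0("n_", groups[g])]] <- kw$n[g]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter- and intra-rater reliability table
#'
#' Intraclass correlations per (ligament, parameter, region): inter-rater
#' from the two raters' first-timepoint values (two-way random effects,
#' single measures, absolute agreement) and intra-rater from the first
#' rater's two timepoints (two-way mixed effects, single measures, absolute
#' agreement), each with its 95% CI and qualitative band.
#'
#' @param measure_table long-format table with `rater` and `timepoint`
#'   columns.
#' @return data.frame: `type` (inter/intra), `ligament`, `parameter`,
#'   `region`, `icc`, `ci_lower`, `ci_upper`, `band`, `n`.
#' @export
reliability_analysis <- function(measure_table) {
  need <- c("subject", "ligament", "parameter", "region", "value_ms",
            "rater", "timepoint")
  miss <- setdiff(need, names(measure_table))
  if (length(miss)) {
    stop_ligrelax(paste("reliability analysis needs columns:",
                        paste(miss, collapse = ", ")),
                  "ligrelax_parameter_error")
  }
  raters <- sort(unique(measure_table$rater))
  t1 <- min(measure_table$timepoint)
  t2 <- max(measure_table$timepoint)
  regions <- c("whole", "distal", "middle", "proximal")
  cells <- unique(measure_table[, c("ligament", "parameter")])
  cells <- cells[order(cells$ligament, cells$parameter), ]

  pick <- function(rater, timepoint, cell, region) {
    sub <- measure_table[
      measure_table$rater == rater & measure_table$timepoint == timepoint &
        measure_table$ligament == cell$ligament &
        measure_table$parameter == cell$parameter &
        measure_table$region == region, ]
    setNames(sub$value_ms, sub$subject)
  }

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    for (region in regions) {
      a <- pick(raters[1], t1, cell, region)
      designs <- list()
      if (length(raters) >= 2) {
        designs$inter <- list(b = pick(raters[2], t1, cell, region),
                              model = "two_way_random_single_abs")
      }
      if (t2 > t1) {
        designs$intra <- list(b = pick(raters[1], t2, cell, region),
                              model = "two_way_mixed_single_abs")
      }
      for (type in names(designs)) {
        b <- designs[[type]]$b
        common <- intersect(names(a), names(b))
        if (length(common) < 2) next
        icc <- icc_single(cbind(a[common], b[common]),
                          model = designs[[type]]$model)
        rows[[length(rows) + 1]] <- data.frame(
          type = type, ligament = cell$ligament, parameter = cell$parameter,
          region = region, icc = icc$value,
          ci_lower = icc$ci95[["lower"]], ci_upper = icc$ci95[["upper"]],
          band = icc$band, n = length(common), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
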