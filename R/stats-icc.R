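#' Qualitative agreement band for an ICC value
#'
#' Below 0.4 is poor agreement, 0.4 to 0.75 (inclusive) fair to good, and
#' strictly above 0.75 excellent.
#'
#' @param icc_value ICC estimate (<= 1; may be negative).
#' @return `"poor"`, `"fair_to_good"` or `"excellent"`.
#' @export
classify_agreement <- function(icc_value) {
  if (any(icc_value > 1 + 1e-12)) {
    stop_ligrelax("an ICC cannot exceed 1", "ligrelax_parameter_error")
  }
  ifelse(icc_value < 0.4, "poor",
         ifelse(icc_value <= 0.75, "fair_to_good", "excellent"))
}

#' Single-measures absolute-agreement intraclass correlation
#'
#' Two-way ANOVA decomposition of an n targets x k raters matrix into row
#' (MSR), column (MSC) and error (MSE) mean squares; the absolute-agreement
#' single-measures ICC is (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC -
#' MSE)). The random- vs mixed-effects distinction (inter- vs intra-rater
#' designs) shares this point estimate and is recorded as metadata. The 95%
#' confidence interval uses the F-based method of McGraw & Wong.
#'
#' @param ratings n x k numeric matrix, complete; n >= 5 recommended, k >= 2.
#' @param model `"two_way_random_single_abs"` (inter-rater) or
#'   `"two_way_mixed_single_abs"` (intra-rater).
#' @param conf_level confidence level (default 0.95).
#' @return `icc_result` list: `model`, `value`, `ci95` (lower, upper),
#'   `band`, plus mean squares `MSR`, `MSC`, `MSE`.
#' @export
icc_single <- function(ratings,
                       model = c("two_way_random_single_abs",
                                 "two_way_mixed_single_abs"),
                       conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2 || anyNA(ratings)) {
    stop_ligrelax("need a complete matrix with >= 2 targets and >= 2 raters",
                  "ligrelax_parameter_error")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  MSR <- ssr / (n - 1)
  MSC <- ssc / (k - 1)
  MSE <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) {
    stop_ligrelax("total variance is zero; ICC undefined", "ligrelax_undefined_icc_error")
  }
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < 1e-300) {
    stop_ligrelax("degenerate mean squares; ICC undefined", "ligrelax_undefined_icc_error")
  }
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  if (MSE <= 1e-12 * max(MSR, 1e-300) && MSC <= 1e-12 * max(MSR, 1e-300)) {
    ci <- c(icc, icc) # perfect agreement: interval degenerates
  } else {
    # r_ab = a/b computed in a form finite as icc -> 1
    r_ab <- k * icc / (n * (1 - icc) + k * icc * (n - 1))
    num_v <- (r_ab * MSC + MSE)^2
    den_v <- (r_ab * MSC)^2 / (k - 1) + MSE^2 / ((n - 1) * (k - 1))
    v <- num_v / den_v
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  structure(list(model = model, value = icc,
                 ci95 = c(lower = min(ci[1], icc), upper = max(ci[2], icc)),
                 band = classify_agreement(icc),
                 MSR = MSR, MSC = MSC, MSE = MSE),
            class = "icc_result")
}
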