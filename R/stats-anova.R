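#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, n >= 3, not constant.
#' @return list `statistic`, `p`.
#' @export
check_normality <- function(values) {
  if (length(values) < 3) {
    stop_ligrelax("normality check needs n >= 3", "ligrelax_parameter_error")
  }
  if (length(unique(values)) == 1) {
    stop_ligrelax("normality check undefined on a constant sample",
                  "ligrelax_degenerate_sample_error")
  }
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

# Internal: orthonormal contrast matrix ((k-1) x k) orthogonal to the unit
# vector, via QR of the centering projector.
orthonormal_contrasts <- function(k) {
  M <- diag(k) - 1 / k
  q <- qr(M)
  t(qr.Q(q)[, seq_len(k - 1), drop = FALSE])
}

#' One-way repeated-measures ANOVA with assumption routing
#'
#' Within-subject ANOVA on an n x k matrix with the assumption checks and
#' fallbacks applied in the conventional order: Shapiro-Wilk normality per
#' condition (violation routes to the Friedman test), then Mauchly's
#' sphericity test (violation applies the Greenhouse-Geisser correction to
#' the F-test degrees of freedom). Effect size is partial eta squared
#' SS_effect / (SS_effect + SS_error) on ANOVA routes and Kendall's W on
#' the Friedman route.
#'
#' @param values n x k numeric matrix (subjects x conditions), complete,
#'   n >= 3, k >= 2.
#' @param alpha level for the assumption checks (default 0.05).
#' @param exact_n_max passed to [friedman_test()] when routed there.
#' @return `rm_anova_result` list: `F`, `df_num`, `df_den`, `gg_epsilon`,
#'   `p_uncorrected`, `p_reported`, `mauchly_W`, `mauchly_p`,
#'   `normality_p` (per condition), `partial_eta_sq`, `route`
#'   (`anova`, `anova_gg` or `friedman`), `effect_size` and, on the
#'   Friedman route, the embedded `friedman` result.
#' @export
rm_anova <- function(values, alpha = 0.05, exact_n_max = 8L) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3 || k < 2) {
    stop_ligrelax("need a complete n >= 3 by k >= 2 matrix", "ligrelax_parameter_error")
  }
  if (anyNA(values)) {
    stop_ligrelax("matrix must be complete", "ligrelax_incomplete_data_error")
  }

  norm_p <- apply(values, 2, function(col) {
    if (length(unique(col)) == 1) return(0) # constant condition: treat as violation
    shapiro.test(col)$p.value
  })

  grand <- mean(values)
  row_m <- rowMeans(values); col_m <- colMeans(values)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_num <- k - 1
  df_den <- (n - 1) * (k - 1)
  if (ss_cond + ss_err <= 1e-10 * max(ss_tot, 1e-300)) {
    # all within-subject variance is zero (identical conditions per subject):
    # there is no condition effect by construction
    return(structure(list(
      F = 0, df_num = df_num, df_den = df_den, gg_epsilon = 1,
      p_uncorrected = 1, p_reported = 1, mauchly_W = 1, mauchly_p = 1,
      normality_p = norm_p, partial_eta_sq = 0, route = "anova",
      effect_size = 0
    ), class = "rm_anova_result"))
  }
  Fstat <- (ss_cond / df_num) / (ss_err / df_den)
  p_unc <- pf(Fstat, df_num, df_den, lower.tail = FALSE)
  peta <- ss_cond / (ss_cond + ss_err)

  # sphericity on the orthonormal-contrast covariance
  C <- orthonormal_contrasts(k)
  S <- C %*% stats::cov(values) %*% t(C)
  if (k == 2) {
    mauchly_W <- 1; mauchly_p <- 1; eps <- 1
  } else {
    trS <- sum(diag(S))
    W <- det(S) / (trS / (k - 1))^(k - 1)
    W <- max(min(W, 1), 1e-300)
    dcor <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    chi <- -(n - 1) * dcor * log(W)
    df_m <- k * (k - 1) / 2 - 1
    mauchly_W <- W
    mauchly_p <- pchisq(chi, df_m, lower.tail = FALSE)
    eps <- trS^2 / ((k - 1) * sum(S^2))
    eps <- max(min(eps, 1), 1 / (k - 1))
  }

  if (any(norm_p < alpha) && k >= 3) {
    fr <- friedman_test(values, exact_n_max = exact_n_max)
    res <- list(F = NA_real_, df_num = NA_real_, df_den = NA_real_,
                gg_epsilon = eps, p_uncorrected = p_unc, p_reported = fr$p,
                mauchly_W = mauchly_W, mauchly_p = mauchly_p,
                normality_p = norm_p, partial_eta_sq = NA_real_,
                route = "friedman", effect_size = fr$kendall_W, friedman = fr)
  } else if (mauchly_p < alpha) {
    p_gg <- pf(Fstat, eps * df_num, eps * df_den, lower.tail = FALSE)
    res <- list(F = Fstat, df_num = eps * df_num, df_den = eps * df_den,
                gg_epsilon = eps, p_uncorrected = p_unc, p_reported = p_gg,
                mauchly_W = mauchly_W, mauchly_p = mauchly_p,
                normality_p = norm_p, partial_eta_sq = peta,
                route = "anova_gg", effect_size = peta)
  } else {
    res <- list(F = Fstat, df_num = df_num, df_den = df_den,
                gg_epsilon = eps, p_uncorrected = p_unc, p_reported = p_unc,
                mauchly_W = mauchly_W, mauchly_p = mauchly_p,
                normality_p = norm_p, partial_eta_sq = peta,
                route = "anova", effect_size = peta)
  }
  structure(res, class = "rm_anova_result")
}
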