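#' Percentage difference between two subregional values
#'
#' Defined as 100 * (a - b) / b, with `a` conventionally the distal third
#' and `b` the comparison third. Only the rank order of these values enters
#' the between-group comparison, so any strictly monotone variant would
#' give the same test; this form is chosen for interpretability. Note the
#' definition is not antisymmetric in its arguments.
#'
#' @param value_a,value_b values in ms; `value_b` must be > 0.
#' @return percentage (scalar or vector).
#' @examples
#' percent_difference(54.5, 47.0) # 15.957
#' @export
percent_difference <- function(value_a, value_b) {
  if (any(value_b <= 0)) {
    stop_ligrelax("percentage difference needs a positive denominator",
                  "ligrelax_domain_error")
  }
  100 * (value_a - value_b) / value_b
}

# Internal: pooled mid-ranks and tie bookkeeping.
midranks <- function(x) rank(x, ties.method = "average")

#' Kruskal-Wallis rank test with explicit rank bookkeeping
#'
#' Pooled mid-ranks across groups; H = 12/(N(N+1)) * sum n_i * Rbar_i^2 -
#' 3(N+1), divided by the tie correction 1 - sum(t^3 - t)/(N^3 - N) when
#' ties are present; chi-squared p with df = groups - 1. Mean ranks per
#' group are reported (they satisfy sum n_i * Rbar_i = N(N+1)/2).
#'
#' @param group_values named list of >= 2 numeric vectors (one per group).
#' @return `kw_result` list: `H`, `df`, `p`, `mean_ranks`, `n`,
#'   `tie_correction_factor`.
#' @export
kruskal_wallis <- function(group_values) {
  if (!is.list(group_values) || length(group_values) < 2) {
    stop_ligrelax("need at least 2 groups", "ligrelax_parameter_error")
  }
  n <- vapply(group_values, length, 0L)
  if (any(n == 0)) {
    stop_ligrelax("every group must be non-empty", "ligrelax_parameter_error")
  }
  N <- sum(n)
  if (N < 3) {
    stop_ligrelax("need at least 3 observations in total", "ligrelax_parameter_error")
  }
  g <- rep(seq_along(group_values), n)
  x <- unlist(group_values, use.names = FALSE)
  r <- midranks(x)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  tie_sizes <- table(x)
  tie_sizes <- tie_sizes[tie_sizes > 1]
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  if (length(tie_sizes) > 0) H <- H / C
  df <- length(group_values) - 1
  structure(list(
    H = H, df = df, p = pchisq(H, df, lower.tail = FALSE),
    mean_ranks = setNames(as.numeric(rbar),
                          names(group_values) %||% paste0("group", seq_along(n))),
    n = setNames(as.integer(n),
                 names(group_values) %||% paste0("group", seq_along(n))),
    tie_correction_factor = C
  ), class = "kw_result")
}

#' Recompute a two-group Kruskal-Wallis H from printed mean ranks
#'
#' Published tables often print only the per-group mean ranks (to 1 decimal)
#' and the H statistic. With two groups of known sizes the integer rank
#' sums are recoverable: they must total N(N+1)/2 and round back to the
#' printed mean ranks. H is then recomputed with the no-ties formula.
#'
#' @param mean_ranks printed per-group mean ranks (length 2).
#' @param n per-group sample sizes (length 2).
#' @param digits decimals the mean ranks were printed to (default 1).
#' @return list `rank_sums`, `mean_ranks_exact`, `H`, `p`, `unique`
#'   (whether exactly one integer solution is rounding-consistent).
#' @export
kw_h_from_mean_ranks <- function(mean_ranks, n, digits = 1) {
  if (length(mean_ranks) != 2 || length(n) != 2) {
    stop_ligrelax("two groups expected", "ligrelax_parameter_error")
  }
  N <- sum(n)
  total <- N * (N + 1) / 2
  half <- 0.5 * 10^(-digits) + 1e-9
  r1_cand <- seq.int(ceiling((mean_ranks[1] - half) * n[1]),
                     floor((mean_ranks[1] + half) * n[1]))
  ok <- vapply(r1_cand, function(r1) {
    r2 <- total - r1
    abs(r2 / n[2] - mean_ranks[2]) <= half
  }, logical(1))
  sols <- r1_cand[ok]
  if (length(sols) == 0) {
    stop_ligrelax("no integer rank sums are consistent with the printed mean ranks",
                  "ligrelax_parameter_error")
  }
  err <- vapply(sols, function(r1) {
    abs(r1 / n[1] - mean_ranks[1]) + abs((total - r1) / n[2] - mean_ranks[2])
  }, numeric(1))
  r1 <- sols[which.min(err)]
  rs <- c(r1, total - r1)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  list(rank_sums = rs, mean_ranks_exact = rs / n, H = H,
       p = pchisq(H, 1, lower.tail = FALSE), unique = length(sols) == 1)
}

# Internal: all permutations of 1..k (k small).
perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Internal: exact null distribution of the Friedman column rank sums by
# dynamic-programming convolution over per-subject rank permutations --
# mathematically identical to enumerating all (k!)^n configurations.
friedman_exact_p <- function(chi_obs, n, k) {
  P <- perms(k)
  keys <- apply(P[, -k, drop = FALSE], 1, paste, collapse = ",")
  dist <- setNames(rep(1 / nrow(P), nrow(P)), keys)
  add <- function(d1) {
    out <- new.env(hash = TRUE, parent = emptyenv())
    for (key in names(d1)) {
      s <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      p0 <- d1[[key]]
      for (i in seq_len(nrow(P))) {
        s2 <- s + P[i, -k]
        k2 <- paste(s2, collapse = ",")
        prev <- out[[k2]]
        out[[k2]] <- (if (is.null(prev)) 0 else prev) + p0 / nrow(P)
      }
    }
    lst <- as.list(out)
    setNames(unlist(lst), names(lst))
  }
  for (s in seq_len(n - 1)) dist <- add(dist)
  tot <- n * k * (k + 1) / 2
  p <- 0
  for (key in names(dist)) {
    rs <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    rs <- c(rs, tot - sum(rs))
    chi <- 12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
    if (chi >= chi_obs - 1e-9) p <- p + dist[[key]]
  }
  p
}

#' Friedman rank test with Kendall's W and exact small-sample p
#'
#' Within-subject mid-ranks; chi^2_r = 12/(nk(k+1)) * sum R_j^2 -
#' 3n(k+1); Kendall's coefficient of concordance W = chi^2_r / (n(k-1)).
#' For n <= `exact_n_max` tie-free data the p-value is exact over all
#' (k!)^n rank configurations (computed by convolution); otherwise the
#' chi-squared approximation with df = k - 1 is used.
#'
#' @param values n x k numeric matrix (subjects x conditions), complete.
#' @param exact_n_max largest n for which the exact null is enumerated
#'   (default 8).
#' @return `friedman_result` list: `chi_r_sq`, `df`, `p`, `method`,
#'   `kendall_W`, `rank_sums`.
#' @export
friedman_test <- function(values, exact_n_max = 8L) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 3) {
    stop_ligrelax("Friedman needs k >= 3 conditions; use pairwise_compare for k = 2",
                  "ligrelax_parameter_error")
  }
  if (anyNA(values)) {
    stop_ligrelax("matrix must be complete", "ligrelax_incomplete_data_error")
  }
  Rk <- t(apply(values, 1, midranks))
  rank_sums <- colSums(Rk)
  chi <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
  has_ties <- any(apply(values, 1, function(r) anyDuplicated(r) > 0))
  if (n <= exact_n_max && !has_ties) {
    p <- friedman_exact_p(chi, n, k)
    method <- "exact"
  } else {
    p <- pchisq(chi, k - 1, lower.tail = FALSE)
    method <- "asymptotic"
  }
  structure(list(
    chi_r_sq = chi, df = k - 1, p = p, method = method,
    kendall_W = chi / (n * (k - 1)), rank_sums = rank_sums
  ), class = "friedman_result")
}

# Internal: exact two-sided signed-rank p by subset-sum convolution over all
# 2^n sign patterns (doubled smaller tail, capped at 1). Ranks may be
# mid-ranks; they are doubled to keep the lattice integral.
wilcoxon_exact_p <- function(w_plus, ranks) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  f <- numeric(tot + 1) # counts over achievable 2*W+ values 0..tot
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(tot + 1)] <- g[(r + 1):(tot + 1)] + f[1:(tot + 1 - r)]
    f <- g
  }
  f <- f / 2^length(ranks)
  w2 <- round(2 * w_plus)
  upper <- sum(f[(w2 + 1):(tot + 1)])
  lower <- sum(f[1:(w2 + 1)])
  min(1, 2 * min(lower, upper))
}

#' Paired comparison between two conditions
#'
#' Paired t-test when `parametric`, otherwise an exact two-sided Wilcoxon
#' signed-rank test (full enumeration of the 2^n sign patterns for
#' n <= 20, normal approximation beyond). Zero differences are dropped
#' before ranking; if every difference is zero the p-value is 1 with a
#' warning.
#'
#' @param values_a,values_b paired samples (same length, n >= 3).
#' @param parametric use the paired t-test instead of the rank test.
#' @return list `statistic`, `p`, `method`, `n_effective`.
#' @export
pairwise_compare <- function(values_a, values_b, parametric = FALSE) {
  if (length(values_a) != length(values_b) || length(values_a) < 3) {
    stop_ligrelax("need paired samples with n >= 3", "ligrelax_parameter_error")
  }
  d <- values_a - values_b
  if (parametric) {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                method = "paired_t", n_effective = length(d)))
  }
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, method = "wilcoxon_exact",
                n_effective = 0L))
  }
  r <- midranks(abs(d))
  w_plus <- sum(r[d > 0])
  if (length(d) <= 20) {
    p <- wilcoxon_exact_p(w_plus, r)
    method <- "wilcoxon_exact"
  } else {
    n <- length(d)
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "wilcoxon_normal"
  }
  list(statistic = w_plus, p = min(p, 1), method = method,
       n_effective = length(d))
}
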