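#' Two-sided Wilcoxon rank-sum p-value
#'
#' Computes the two-sided Mann-Whitney/Wilcoxon rank-sum p-value comparing two
#' numeric samples. For small pooled samples the p-value is exact: when the
#' pooled values are tie-free the classical null distribution
#' ([stats::pwilcox]) is used; when ties are present the conditional
#' permutation distribution of the midrank sum is enumerated exhaustively and
#' the two-sided p-value is the null probability of a rank-sum deviation from
#' its mean at least as large as observed. For larger samples the normal
#' approximation with tie correction and continuity correction is used (the
#' same formula as [stats::wilcox.test] with `exact = FALSE, correct = TRUE`).
#'
#' @param x,y numeric vectors, the two groups.
#' @param exact_max_n largest pooled sample size for which an exact p-value is
#'   attempted (default 25).
#' @param enum_cap largest number of group assignments that will be enumerated
#'   when ties force full permutation enumeration (default 2e5); above this the
#'   normal approximation is used.
#' @return a single p-value in (0, 1].
#' @examples
#' rank_sum_pvalue(c(0, 0, 0), c(2, 2, 2))   # exact 2/20 = 0.1
#' rank_sum_pvalue(1:4, 5:8)                  # exact 2/70
#' @export
rank_sum_pvalue <- function(x, y, exact_max_n = 25, enum_cap = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); k <- length(y); n <- m + k
  if (m == 0L || k == 0L) return(1)
  pooled <- c(x, y)
  if (n <= exact_max_n) {
    has_ties <- anyDuplicated(pooled) > 0L
    if (!has_ties) {
      # classical exact null distribution of the Mann-Whitney U statistic
      r <- rank(pooled)
      U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
      if (U > m * k / 2) {
        p <- stats::pwilcox(U - 1, m, k, lower.tail = FALSE) * 2
      } else if (U < m * k / 2) {
        p <- stats::pwilcox(U, m, k) * 2
      } else {
        p <- 1
      }
      return(min(1, p))
    }
    if (choose(n, m) <= enum_cap) {
      return(rank_sum_enumerated(pooled, m))
    }
  }
  rank_sum_normal(pooled, m)
}

# Exact conditional permutation p-value with midranks: enumerate every
# assignment of m of the n pooled values to group one and count rank-sum
# deviations from the null mean at least as extreme as observed.
rank_sum_enumerated <- function(pooled, m) {
  n <- length(pooled)
  r <- rank(pooled)
  mu <- m * (n + 1) / 2
  obs <- abs(sum(r[seq_len(m)]) - mu)
  idx <- utils::combn(n, m)
  sums <- colSums(matrix(r[idx], nrow = m))
  # small tolerance so midrank halves do not break equality at the boundary
  mean(abs(sums - mu) >= obs - 1e-9)
}

# Normal approximation with tie correction and continuity correction,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE).
rank_sum_normal <- function(pooled, m) {
  n <- length(pooled)
  k <- n - m
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  nties <- table(pooled)
  z <- U - m * k / 2
  sigma2 <- (m * k / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

# One-vs-rest Wilcoxon p-values for every (cluster, gene).
# mat: cells x genes (dense), labels: per-cell cluster factor.
# Ranks are computed once per gene; for small systems the exact machinery in
# rank_sum_pvalue is used instead.
one_vs_rest_pvalues <- function(mat, labels, exact_max_n = 25) {
  labels <- as.factor(labels)
  cl <- levels(labels)
  n <- nrow(mat)
  out <- matrix(NA_real_, nrow = length(cl), ncol = ncol(mat),
                dimnames = list(cl, colnames(mat)))
  if (n <= exact_max_n) {
    for (g in seq_len(ncol(mat))) {
      v <- mat[, g]
      for (ci in seq_along(cl)) {
        inside <- labels == cl[ci]
        out[ci, g] <- rank_sum_pvalue(v[inside], v[!inside], exact_max_n = exact_max_n)
      }
    }
    return(out)
  }
  sizes <- table(labels)
  for (g in seq_len(ncol(mat))) {
    v <- mat[, g]
    r <- rank(v)
    nties <- tabulate(match(v, unique(v)))
    tie_term <- sum(nties^3 - nties) / (n * (n - 1))
    for (ci in seq_along(cl)) {
      m <- sizes[[cl[ci]]]
      k <- n - m
      U <- sum(r[labels == cl[ci]]) - m * (m + 1) / 2
      sigma2 <- (m * k / 12) * ((n + 1) - tie_term)
      if (sigma2 <= 0) { out[ci, g] <- 1; next }
      z <- U - m * k / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      out[ci, g] <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  out
}
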