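# Rank statistics shared by the gating, GO-enrichment and subtype modules.

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation p-value (enumeration over all \eqn{C(n_1+n_2, n_1)}
#' placements of the observed, tie-averaged ranks) when the combined sample
#' size is at most `exact_max`; tie-corrected normal approximation with
#' continuity correction otherwise. Two-sided throughout. Unlike
#' [stats::wilcox.test()], the exact branch handles ties, because it
#' enumerates the permutation distribution of the actual rank multiset.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max largest combined sample size for which the exact
#'   enumeration is used (default 20).
#' @return List with `U` (statistic for the first sample), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_max = 20L) {
  if (!length(x) || !length(y))
    validation_error("Mann-Whitney needs non-empty groups")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= U + eps), mean(us >= U - eps))
    list(U = U, p = min(1, p), method = "exact")
  } else {
    tie <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values, order-preserving with the input.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    validation_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Welch two-sample t statistics row-wise over a genes x samples matrix.
# Returns per-row difference of means (b - a), t, Welch-Satterthwaite df, p.
# Degenerate rows (zero variance in both groups): t = 0, p = 1 when the
# means agree; t = +/-Inf, p = 0 when they differ (documented convention).
welch_rows <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- rowMeans(mat[, idx_a, drop = FALSE])
  mb <- rowMeans(mat[, idx_b, drop = FALSE])
  va <- rowSums((mat[, idx_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, idx_b, drop = FALSE] - mb)^2) / (nb - 1)
  d <- mb - ma
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), ifelse(d == 0, 1, 0))
  data.frame(diff = d, t = t, df = df, p = p)
}
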