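# shared fixture builders (all fixtures are generated in code)

# tiny event table with explicit intensities
make_events <- function(mat, panel = "test", ...) {
  event_table(as.data.frame(mat), panel = panel, ...)
}

# fixed thresholds without isotype derivation, for counting tests
make_thresholds <- function(theta_pos, theta_split = NULL) {
  structure(list(theta_pos = theta_pos, theta_split = theta_split,
                 pos_quantile = NA_real_, split_channel = "CD45"),
            class = "gate_thresholds")
}

# small two-group study from explicit per-gene values
make_study <- function(control, tumor, genes = NULL) {
  control <- as.matrix(control); tumor <- as.matrix(tumor)
  expr <- cbind(control, tumor)
  rownames(expr) <- genes %||% sprintf("g%03d", seq_len(nrow(expr)))
  colnames(expr) <- c(sprintf("c%d", seq_len(ncol(control))),
                      sprintf("t%d", seq_len(ncol(tumor))))
  groups <- stats::setNames(rep(c("control", "tumor"),
                                c(ncol(control), ncol(tumor))),
                            colnames(expr))
  expression_study(expr, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sided Mann-Whitney p by enumeration over rank placements
brute_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2, function(i)
    sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
}

# textbook Welch t and Welch-Satterthwaite df
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# hand step-up BH adjustment
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# rank-then-Pearson Spearman with average ranks
spearman_by_hand <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
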