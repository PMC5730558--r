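# Gene-level differential expression between control and glioma groups:
# probe aggregation, Welch testing, plug-in FDR, control-centred heatmap
# matrices, top-K lists and marker-panel reports.

#' Aggregate probe-level values to gene level
#'
#' Only probes mapping to exactly one gene are retained; each gene's value is
#' the arithmetic mean of its retained probes, per sample. Multi-mapping and
#' unmapped probes are dropped and counted in the report.
#'
#' @param probe_matrix numeric matrix, probes x samples, with probe rownames.
#' @param annotation named list probe id -> character vector of gene symbols
#'   (possibly empty or of length > 1).
#' @param groups named character vector sample -> `"control"`/`"tumor"`.
#' @return List with `study` (an [expression_study()]) and `report`
#'   (counts of unique / multi-mapping / unmapped probes).
#' @export
aggregate_probes <- function(probe_matrix, annotation, groups) {
  probe_matrix <- as.matrix(probe_matrix)
  probes <- rownames(probe_matrix)
  if (is.null(probes)) schema_error("probe matrix needs probe rownames")
  if (anyDuplicated(names(annotation)))
    validation_error("probe ids in the annotation must be unique")
  n_genes <- vapply(annotation[probes], function(g) length(g %||% character()),
                    integer(1))
  n_genes[!probes %in% names(annotation)] <- 0L
  keep <- n_genes == 1L
  if (!any(keep))
    validation_error("no probe maps uniquely to a gene")
  gene_of <- vapply(annotation[probes[keep]], `[`, character(1), 1L)
  sub <- probe_matrix[keep, , drop = FALSE]
  agg <- rowsum(sub, group = gene_of) /
    as.vector(table(gene_of)[sort(unique(gene_of))])
  list(
    study = expression_study(agg, groups),
    report = list(n_probes = length(probes), n_unique = sum(keep),
                  n_multi = sum(n_genes > 1L), n_unmapped = sum(n_genes == 0L))
  )
}

#' Welch differential expression with discovery counts and plug-in FDR
#'
#' Per gene: log2 fold change (mean tumor minus mean control), two-sided
#' Welch t-test with Welch-Satterthwaite degrees of freedom, and a
#' Benjamini-Hochberg q-value. Discoveries are genes with `p < alpha`
#' (optionally further restricted to `|log2fc| >= min_abs_fc`); the plug-in
#' FDR estimate is `m * alpha / k`. Genes with zero variance in both groups
#' and equal means get `t = 0, p = 1`.
#'
#' @param study an [expression_study()] with >= 2 samples per group.
#' @param alpha uniform alpha level in (0, 1) (default 0.01).
#' @param min_abs_fc optional minimum `|log2fc|` a discovery must reach
#'   (default `NULL`: p-value criterion only).
#' @return Object of class `de_result`: list with `table` (gene, log2fc, t,
#'   df, p, q, significant, direction), `alpha`, `m`, `k`, `up`, `down`,
#'   `fdr_hat`.
#' @export
welch_de <- function(study, alpha = 0.01, min_abs_fc = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (alpha <= 0 || alpha >= 1) validation_error("alpha must lie in (0, 1)")
  idx_c <- which(study$groups == "control")
  idx_t <- which(study$groups == "tumor")
  if (length(idx_c) < 2L || length(idx_t) < 2L)
    validation_error("both groups need >= 2 samples")
  w <- welch_rows(study$expr, idx_c, idx_t)
  sig <- w$p < alpha
  if (!is.null(min_abs_fc)) sig <- sig & abs(w$diff) >= min_abs_fc
  tab <- data.frame(
    gene = rownames(study$expr), log2fc = w$diff, t = w$t, df = w$df,
    p = w$p, q = bh_adjust(w$p), significant = sig,
    direction = ifelse(w$diff > 0, "up", ifelse(w$diff < 0, "down", "none")),
    row.names = NULL
  )
  k <- sum(sig)
  structure(
    list(table = tab, alpha = alpha, m = nrow(tab), k = k,
         up = sum(sig & tab$direction == "up"),
         down = sum(sig & tab$direction == "down"),
         fdr_hat = if (k > 0) estimate_fdr(nrow(tab), k, alpha)
                   else NA_real_),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "<de_result> m = %d genes, alpha = %g: k = %d discoveries (%d up, %d down)\n",
    x$m, x$alpha, x$k, x$up, x$down))
  cat(sprintf("  plug-in FDR_hat = %s\n",
              if (is.na(x$fdr_hat)) "undefined (k = 0)"
              else sprintf("%.4f", x$fdr_hat)))
  invisible(x)
}

#' Plug-in FDR estimate at a uniform alpha level
#'
#' Expected false positives (`m * alpha`) over observed discoveries (`k`).
#' Undefined (`NA`, with a warning) when `k = 0`.
#'
#' @param m number of genes tested.
#' @param k number of discoveries (`p < alpha`), `k <= m`.
#' @param alpha the uniform alpha level used.
#' @return The estimate `m * alpha / k`, or `NA` when `k = 0`.
#' @export
estimate_fdr <- function(m, k, alpha) {
  if (k > m) validation_error("k cannot exceed m")
  if (k == 0) {
    warning("no discoveries: FDR estimate undefined", call. = FALSE)
    return(NA_real_)
  }
  m * alpha / k
}

#' Centre each gene's profile on its control-group mean
#'
#' Subtracts, per gene, the mean log2 value over control samples, so the
#' centred values are log2 ratios relative to the control mean. Idempotent.
#'
#' @param study an [expression_study()] with a non-empty control group.
#' @return Centred matrix (same dimnames as `study$expr`).
#' @export
center_on_control <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  idx_c <- which(study$groups == "control")
  if (!length(idx_c)) validation_error("control group is empty")
  study$expr - rowMeans(study$expr[, idx_c, drop = FALSE])
}

#' Top regulated genes among the discoveries
#'
#' Discoveries sorted by `|log2fc|` descending (ties broken by smaller p,
#' then lexicographic gene id), truncated to `K`. An alternative p-value
#' ranking is available.
#'
#' @param result a [welch_de()] result.
#' @param K list length (default 50); `K` beyond the discovery count returns
#'   all discoveries.
#' @param rank_by `"fc"` (default) or `"p"`.
#' @return Data frame of the top discoveries in rank order.
#' @export
top_regulated <- function(result, K = 50L, rank_by = c("fc", "p")) {
  stopifnot(inherits(result, "de_result"), K >= 1L)
  rank_by <- match.arg(rank_by)
  disc <- result$table[result$table$significant, , drop = FALSE]
  ord <- if (rank_by == "fc")
    order(-abs(disc$log2fc), disc$p, disc$gene)
  else
    order(disc$p, -abs(disc$log2fc), disc$gene)
  utils::head(disc[ord, , drop = FALSE], K)
}

#' Built-in M1 / M2 / GAM marker panels
#'
#' Gene panels used to characterise the activation state of glioma-infiltrating
#' microglia: classical inflammatory (M1) markers, alternative/pro-tumorigenic
#' (M2) markers, and genes recurrently upregulated in glioma-associated
#' microglia/macrophages (GAM) including cell-cycle and kinesin genes.
#'
#' @return Named list of `marker_panel` objects (`M1`, `M2`, `GAM`).
#' @export
marker_panels <- function() {
  list(
    M1 = marker_panel("M1", c("Tlr2", "Tlr4", "Il18", "Cd80", "Il12a",
                              "Il15", "Cxcl9", "Nos2", "Il1b")),
    M2 = marker_panel("M2", c("Tgm2", "Il1rn", "Cxcl10", "Cxcl16", "Ccl2",
                              "Ccl17", "Ccl22", "Ccl24", "Vegfa", "Stat3",
                              "Arg1", "Mmp2", "Mmp14")),
    GAM = marker_panel("GAM", c("Rrm2", "Top2a", "Kif2c", "Kif11", "Kif20a",
                                "Stmn1", "E2f7", "E2f8", "Cdk1", "Cdca2"))
  )
}

#' Construct a marker panel
#'
#' @param name panel name (e.g. `"M1"`, `"M2"`, `"GAM"`).
#' @param genes ordered, unique gene symbols.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) validation_error("marker panel must be non-empty")
  if (anyDuplicated(genes))
    validation_error("marker panel symbols must be unique")
  structure(list(name = name, genes = genes), class = "marker_panel")
}

#' Marker-panel report: fold change and p per panel gene
#'
#' One row per panel gene in panel order. Fold change is reported on the
#' signed linear scale: `sign(log2fc) * 2^|log2fc|`, so -2 means halved
#' (a common microarray reporting convention; note it is *not* `2^log2fc`).
#' Panel genes absent from the study are flagged missing rather than raising
#' an error.
#'
#' @param result a [welch_de()] result.
#' @param panel a [marker_panel()].
#' @return Data frame with columns `gene`, `log2fc`, `fold_change`, `p`,
#'   `direction`, `significant`, `missing`.
#' @export
marker_panel_report <- function(result, panel) {
  stopifnot(inherits(result, "de_result"), inherits(panel, "marker_panel"))
  idx <- match(panel$genes, result$table$gene)
  tab <- result$table[idx, , drop = FALSE]
  data.frame(
    gene = panel$genes,
    log2fc = tab$log2fc,
    fold_change = sign(tab$log2fc) * 2^abs(tab$log2fc),
    p = tab$p,
    direction = tab$direction,
    significant = tab$significant,
    missing = is.na(idx),
    row.names = NULL
  )
}
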