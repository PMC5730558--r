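# Rank-based GO-term enrichment: genes carrying signed log2 fold changes are
# ranked, and each term's member ranks are compared with the remaining genes
# by a two-sided rank-sum (Mann-Whitney) test with Benjamini-Hochberg
# correction. Annotations are consumed flat (no ontology-graph propagation).

#' Rank-based GO-term enrichment
#'
#' Genes are ranked by signed log2 fold change (so up- and down-shifted terms
#' are distinguishable). For each annotated term with at least
#' `min_term_size` genes present in the input, the ranks of in-term genes are
#' compared against the ranks of all other input genes with a two-sided
#' rank-sum test (exact by enumeration when the input has at most 20 genes,
#' tie-corrected normal approximation above; average ranks for ties).
#' Direction is the side of the global median the in-term median rank falls
#' on. A term containing every input gene has `p = 1` (no rank contrast is
#' possible). Benjamini-Hochberg correction is applied across tested terms.
#'
#' @param gene_fc named numeric vector, gene -> log2 fold change.
#' @param annotation a [go_annotation()].
#' @param min_term_size smallest number of in-input genes a term needs to be
#'   tested (default 3).
#' @param min_fc optional pre-filter: keep only genes with
#'   `log2fc > min_fc` before ranking (e.g. `1` restricts to >2-fold
#'   upregulated genes).
#' @return Data frame of class `go_result` sorted by p: `term`, `name`,
#'   `n_in`, `U`, `p`, `q`, `direction`, `median_log2fc`. Skipped terms are
#'   recorded in the `"skipped"` attribute; the rank statistic used is noted
#'   in the `"statistic"` attribute.
#' @export
rank_enrichment <- function(gene_fc, annotation, min_term_size = 3L,
                            min_fc = NULL) {
  stopifnot(inherits(annotation, "go_annotation"))
  if (is.null(names(gene_fc)))
    schema_error("gene_fc must be a named vector (gene -> log2fc)")
  if (!is.null(min_fc)) gene_fc <- gene_fc[gene_fc > min_fc]
  genes <- names(gene_fc)
  if (length(genes) < 2L)
    validation_error("need >= 2 genes after filtering")
  r <- rank(gene_fc)
  rows <- list(); skipped <- character()
  for (term in names(annotation$terms)) {
    members <- intersect(annotation$terms[[term]], genes)
    if (length(members) == 0L ||
        (length(members) < min_term_size &&
         length(members) < length(genes))) {
      skipped <- c(skipped, term)
      next
    }
    inr <- r[members]
    outr <- r[setdiff(genes, members)]
    if (!length(outr)) {
      p <- 1; U <- NA_real_
    } else {
      mw <- mann_whitney(inr, outr)
      p <- mw$p; U <- mw$U
    }
    rows[[term]] <- data.frame(
      term = term, name = annotation$term_names[[term]],
      n_in = length(members), U = U, p = p,
      direction = if (stats::median(inr) >= stats::median(r)) "up" else "down",
      median_log2fc = stats::median(gene_fc[members]),
      row.names = NULL
    )
  }
  if (length(rows) < 2L)
    validation_error("fewer than 2 terms testable after size filtering")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, -out$n_in, out$term),
             c("term", "name", "n_in", "U", "p", "q", "direction",
               "median_log2fc")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "statistic") <- "two-sided rank-sum (Mann-Whitney)"
  class(out) <- c("go_result", "data.frame")
  out
}

#' Top enriched terms in one direction
#'
#' Filters to the requested direction, sorts by p ascending (ties broken by
#' larger `n_in`, then term id) and truncates to `K`.
#'
#' @param results a [rank_enrichment()] result.
#' @param direction `"up"` or `"down"`.
#' @param K list length (default 30).
#' @return Data frame of at most `K` rows with non-decreasing p.
#' @export
summarize_terms <- function(results, direction = c("up", "down"), K = 30L) {
  direction <- match.arg(direction)
  stopifnot(K >= 1L)
  sub <- results[results$direction == direction, , drop = FALSE]
  sub <- sub[order(sub$p, -sub$n_in, sub$term), , drop = FALSE]
  rownames(sub) <- NULL
  utils::head(as.data.frame(sub), K)
}
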