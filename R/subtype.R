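# Cross-species subtype similarity: assign human tumor samples to molecular
# subtypes by a one-sample Kolmogorov-Smirnov statistic on signature-gene
# ranks, map rat genes to human orthologues, build tumor/normal fold-change
# vectors, and rank subtypes by Spearman correlation with the rat model.

# signed one-sample KS statistics of u against Uniform(0,1):
# d_up measures an upward shift (mass near 1), d_down a downward one;
# the two-sided D is their maximum.
.ks_signed <- function(u) {
  u <- sort(u); n <- length(u)
  i <- seq_len(n)
  d_up <- max(u - (i - 1) / n)
  d_down <- max(i / n - u)
  list(d_up = d_up, d_down = d_down, D = max(d_up, d_down))
}

#' Assign human tumor samples to subtypes by one-sample KS on signature ranks
#'
#' Per tumor sample, all genes are ranked by expression within the sample
#' (ascending: the highest-expressed gene gets the largest rank) and the
#' normalized ranks `rank / (G + 1)` of each subtype's signature genes are
#' compared with the Uniform(0,1) distribution by a one-sample
#' Kolmogorov-Smirnov statistic, signed toward high expression. The sample is
#' assigned the subtype with the largest upward-shift D. When no subtype
#' shows an upward shift the maximal-D subtype is still assigned but flagged
#' low-confidence. Two-sided D and p values for all subtypes are reported so
#' alternative decision rules can be audited.
#'
#' @param human an [expression_study()]; only tumor samples are assigned.
#' @param sig a [signature_set()]; each subtype needs >= 3 signature genes
#'   present in the matrix.
#' @return Object of class `subtype_assignment`: list with `assignments`
#'   (data frame: sample, subtype, low_confidence), `D_up`, `D` and `p`
#'   (samples x subtypes matrices).
#' @export
assign_subtypes <- function(human, sig) {
  stopifnot(inherits(human, "expression_study"),
            inherits(sig, "signature_set"))
  genes <- rownames(human$expr)
  present <- lapply(sig$sets, intersect, x = genes)
  sizes <- lengths(present)
  if (any(sizes < 3L))
    validation_error("subtype(s) with < 3 signature genes in the matrix: %s",
                     paste(names(present)[sizes < 3L], collapse = ", "))
  tumors <- names(human$groups)[human$groups == "tumor"]
  subtypes <- names(sig$sets)
  G <- length(genes)
  d_up <- d_down <- d_two <- pmat <- matrix(
    NA_real_, length(tumors), length(subtypes),
    dimnames = list(tumors, subtypes))
  for (s in tumors) {
    rk <- rank(human$expr[, s]) / (G + 1)
    for (st in subtypes) {
      u <- rk[present[[st]]]
      ks <- .ks_signed(u)
      d_up[s, st] <- ks$d_up
      d_down[s, st] <- ks$d_down
      d_two[s, st] <- ks$D
      pmat[s, st] <- suppressWarnings(
        stats::ks.test(u, "punif")$p.value)
    }
  }
  best <- subtypes[max.col(d_up, ties.method = "first")]
  # low confidence when even the winning subtype's shift is not upward-dominant
  low_conf <- vapply(seq_along(tumors), function(i) {
    d_up[i, best[i]] <= d_down[i, best[i]]
  }, logical(1))
  structure(
    list(assignments = data.frame(sample = tumors, subtype = best,
                                  low_confidence = low_conf,
                                  row.names = NULL),
         D_up = d_up, D = d_two, p = pmat),
    class = "subtype_assignment"
  )
}

#' Map rat genes to human orthologues (one-to-one)
#'
#' Restricts the map to the supplied rat genes, then drops any pair involved
#' in a one-to-many relationship in either direction, so that no rat or human
#' symbol appears twice in the output. Unmapped genes and dropped pairs are
#' counted.
#'
#' @param genes character vector of rat gene symbols.
#' @param map an [ortholog_map()].
#' @return List with `pairs` (data frame rat/human), `n_unmapped` and
#'   `n_dropped_multi`.
#' @export
map_orthologs <- function(genes, map) {
  stopifnot(inherits(map, "ortholog_map"))
  sub <- map$pairs[map$pairs$rat %in% genes, , drop = FALSE]
  if (!nrow(sub))
    validation_error("no input gene is present in the ortholog map")
  multi <- sub$rat %in% sub$rat[duplicated(sub$rat)] |
    sub$human %in% sub$human[duplicated(sub$human)]
  pairs <- sub[!multi, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_unmapped = length(setdiff(genes, map$pairs$rat)),
       n_dropped_multi = sum(multi))
}

#' Tumor/normal log2 fold-change vectors
#'
#' Per gene, the log2 difference between tumor expression and the mean log2
#' expression of the normal (control) samples. With `per_sample = TRUE`
#' (default) one vector per tumor sample is returned; otherwise a single
#' vector from the tumor-group mean.
#'
#' @param study an [expression_study()] with >= 1 control sample.
#' @param per_sample logical (see above).
#' @return Matrix genes x tumor samples, or a named numeric vector.
#' @export
fold_change_vector <- function(study, per_sample = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  idx_c <- which(study$groups == "control")
  idx_t <- which(study$groups == "tumor")
  if (!length(idx_c)) validation_error("no normal/control samples")
  ref <- rowMeans(study$expr[, idx_c, drop = FALSE])
  if (per_sample)
    study$expr[, idx_t, drop = FALSE] - ref
  else
    rowMeans(study$expr[, idx_t, drop = FALSE]) - ref
}

#' Rank subtypes by Spearman similarity with the rat fold-change profile
#'
#' Each subtype's reference vector is the mean fold change over human tumor
#' samples assigned to it. For every rat replicate, the Spearman correlation
#' between the rat vector and each subtype reference is computed over the
#' ortholog-mapped genes (average ranks for ties). Subtypes are ranked by
#' mean correlation; pairwise two-sided Mann-Whitney tests compare the
#' replicate correlation lists (with the default 3 replicates per group the
#' smallest attainable two-sided p is 0.1, and a small-sample warning is
#' attached). Subtypes with no assigned samples are excluded and flagged.
#'
#' @param rat_fcs matrix of rat fold changes, genes x replicates (rat gene
#'   rownames); at least one replicate.
#' @param human_fcs matrix of per-sample human fold changes, genes x tumor
#'   samples (human gene rownames).
#' @param assign an [assign_subtypes()] result covering the human samples.
#' @param mapped output of [map_orthologs()] (or its `pairs` data frame);
#'   >= 3 mapped genes present in both matrices are required.
#' @param replicate_mode `"rat"` (default): each rat replicate is correlated
#'   against subtype-mean human references, so n = number of rat replicates.
#'   `"human"`: the rat mean fold-change vector is correlated against each
#'   assigned human sample individually, so n varies per subtype.
#' @return Object of class `similarity_result`: list with `rho` (subtypes x
#'   replicates, or a per-subtype list in `"human"` mode), `summary` (data
#'   frame: subtype, mean_rho, sd_rho, n), `pairwise_p`, `ranking`,
#'   `winner`, `excluded_subtypes`, `small_sample_warning`, `n_genes`.
#' @export
similarity_ranking <- function(rat_fcs, human_fcs, assign, mapped,
                               replicate_mode = c("rat", "human")) {
  replicate_mode <- match.arg(replicate_mode)
  rat_fcs <- as.matrix(rat_fcs)
  human_fcs <- as.matrix(human_fcs)
  pairs <- if (is.data.frame(mapped)) mapped else mapped$pairs
  keep <- pairs$rat %in% rownames(rat_fcs) &
    pairs$human %in% rownames(human_fcs)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L)
    validation_error("need >= 3 mapped genes present in both fold-change sets")
  if (ncol(rat_fcs) < 1L)
    validation_error("need >= 1 rat replicate vector")
  ass <- assign$assignments
  subtypes <- colnames(assign$D_up)
  counts <- table(factor(ass$subtype, levels = subtypes))
  excluded <- names(counts)[counts == 0]
  used <- setdiff(subtypes, excluded)
  rat_m <- rat_fcs[pairs$rat, , drop = FALSE]
  if (replicate_mode == "rat") {
    rho <- matrix(NA_real_, length(used), ncol(rat_fcs),
                  dimnames = list(used, colnames(rat_fcs)))
    for (st in used) {
      samp <- ass$sample[ass$subtype == st]
      ref <- rowMeans(human_fcs[pairs$human, samp, drop = FALSE])
      for (j in seq_len(ncol(rat_m)))
        rho[st, j] <- stats::cor(rat_m[, j], ref, method = "spearman")
    }
    rho_list <- lapply(used, function(st) rho[st, ])
  } else {
    rat_mean <- rowMeans(rat_m)
    rho_list <- lapply(used, function(st) {
      samp <- ass$sample[ass$subtype == st]
      vapply(samp, function(s)
        stats::cor(rat_mean, human_fcs[pairs$human, s],
                   method = "spearman"), numeric(1))
    })
    rho <- rho_list
    names(rho) <- used
  }
  names(rho_list) <- used
  summary <- data.frame(
    subtype = used,
    mean_rho = vapply(rho_list, mean, numeric(1)),
    sd_rho = vapply(rho_list, stats::sd, numeric(1)),
    n = vapply(rho_list, length, integer(1)), row.names = NULL
  )
  ranking <- summary$subtype[order(-summary$mean_rho)]
  pw <- matrix(NA_real_, length(used), length(used),
               dimnames = list(used, used))
  if (length(used) >= 2L) {
    for (a in used) for (b in used) if (a != b)
      pw[a, b] <- mann_whitney(rho_list[[a]], rho_list[[b]])$p
  }
  structure(
    list(rho = rho, summary = summary, pairwise_p = pw,
         ranking = ranking, winner = ranking[1],
         excluded_subtypes = excluded,
         small_sample_warning = min(summary$n) < 6L,
         n_genes = nrow(pairs), replicate_mode = replicate_mode),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %d mapped genes, mode '%s'\n",
              x$n_genes, x$replicate_mode))
  s <- x$summary[order(-x$summary$mean_rho), ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s mean rho = %+.3f (sd %.3f)%s\n", s$subtype[i],
                s$mean_rho[i], s$sd_rho[i],
                if (i == 1) "  <- winner" else ""))
  if (length(x$excluded_subtypes))
    cat("  excluded (no assigned samples):",
        paste(x$excluded_subtypes, collapse = ", "), "\n")
  invisible(x)
}
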