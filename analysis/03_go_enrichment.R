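#!/usr/bin/env Rscript
# Rank-based GO ("biological process") enrichment of the hemisphere
# fold-change profile: a planted immune-activation-like term plus random
# background terms, rank-sum tested with Benjamini-Hochberg correction;
# top-30 up- and down-shifted term lists.

suppressPackageStartupMessages(library(gliomaTME))
dir.create("results", showWarnings = FALSE)
seed <- 1L

# regenerate the same study as analysis/02 so the fold changes match
set.seed(101)
genes <- sprintf("g%05d", seq_len(2000))
de_genes <- data.frame(gene = sample(genes, 150),
                       effect = sample(c(-1, 1), 150, TRUE) * runif(150, 2, 5))
sim <- generate_expression_study(
  expr_sim_config(n_genes = 2000L, n_control = 4L, n_tumor = 3L,
                  de_genes = de_genes, noise_sd = 0.5, seed = seed))
de <- welch_de(sim$study, alpha = 0.01)
fc <- setNames(de$table$log2fc, de$table$gene)

planted <- list(
  `GO:IMMUNE_UP` = de_genes$gene[de_genes$effect > 0],
  `GO:NEURO_DOWN` = de_genes$gene[de_genes$effect < 0])
annot <- generate_go_annotation(genes, n_random = 48L, planted = planted,
                                seed = seed)

res <- rank_enrichment(fc, annot, min_term_size = 3L)
message(sprintf("%d terms tested (%d skipped); statistic: %s",
                nrow(res), length(attr(res, "skipped")),
                attr(res, "statistic")))
message("most enriched terms:")
print(head(as.data.frame(res)[c("term", "n_in", "p", "q", "direction")], 5),
      row.names = FALSE)

up30 <- summarize_terms(res, "up", K = 30L)
down30 <- summarize_terms(res, "down", K = 30L)

write.table(as.data.frame(res), "results/go_results.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(up30, "results/go_top30_up.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(down30, "results/go_top30_down.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_json_report(list(seed = seed, n_tested = nrow(res),
                       best_up = up30$term[1], best_up_q = up30$q[1],
                       best_down = down30$term[1]),
                  "results/go_summary.json")
message("wrote results/go_* files")
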