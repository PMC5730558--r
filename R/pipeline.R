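# End-to-end orchestration: simulate -> gate -> differential expression ->
# GO enrichment -> subtype similarity, with a consolidated report. All
# randomness flows from the single configured seed; the report carries the
# seed and a configuration hash so runs are reproducible and auditable.

#' Default pipeline configuration
#'
#' A fully-simulated demonstration run: day-21 myeloid/T-cell/MDSC panels,
#' a two-group expression study with planted effects and planted GO terms,
#' and a four-subtype human cohort with a Mesenchymal-like rat study.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param alpha uniform alpha level for differential expression.
#' @param pos_quantile isotype quantile for gate positivity cutoffs.
#' @param top_genes,top_terms list lengths for the top-gene and top-GO-term
#'   summaries.
#' @param stages named logical list toggling `gating`, `diffexpr`,
#'   `go`, `subtype`.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = NULL, alpha = 0.01,
                                    pos_quantile = 0.99, top_genes = 50L,
                                    top_terms = 30L,
                                    stages = list(gating = TRUE,
                                                  diffexpr = TRUE,
                                                  go = TRUE,
                                                  subtype = TRUE)) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, alpha = alpha,
         pos_quantile = pos_quantile, top_genes = as.integer(top_genes),
         top_terms = as.integer(top_terms), stages = stages,
         n_panel_events = 50000L,
         expr = list(n_genes = 2000L, n_de = 100L, effect = 2.5,
                     noise_sd = 0.5, n_go_terms = 40L),
         cohort = list(samples_per_subtype = 20L, n_normals = 10L)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The configuration file is YAML (the only supported dialect); keys mirror
#' the arguments of [default_pipeline_config()] and unknown keys are an
#' error.
#'
#' @param path YAML path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    validation_error("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the enabled stages in dependency order on freshly simulated
#' inputs, writes intermediate files under `config$out_dir` when set, and
#' returns a consolidated report. Identical configuration and seed give an
#' identical report.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return A `run_report` list: per-stage summary blocks plus provenance
#'   (seed, configuration hash, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  seed <- config$seed
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  report <- list(provenance = list(
    seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("gliomaTME"))
  ))
  on_fail <- function(stage, e) {
    if (!is.null(out))
      writeLines(sprintf("pipeline failed in stage '%s': %s", stage,
                         conditionMessage(e)),
                 file.path(out, "FAILED"))
    tme_stop("gliomaTME_stage_error", "stage '%s' failed: %s", stage,
             conditionMessage(e))
  }

  if (isTRUE(config$stages$gating)) {
    report$gating <- tryCatch(.stage_gating(config, seed, out),
                              error = function(e) on_fail("gating", e))
  }
  needs_de <- isTRUE(config$stages$diffexpr) || isTRUE(config$stages$go)
  if (needs_de) {
    de_bundle <- tryCatch(.stage_diffexpr(config, seed, out),
                          error = function(e) on_fail("diffexpr", e))
    if (isTRUE(config$stages$diffexpr)) report$diffexpr <- de_bundle$summary
    if (isTRUE(config$stages$go)) {
      report$go <- tryCatch(.stage_go(config, seed, out, de_bundle),
                            error = function(e) on_fail("go", e))
    }
  }
  if (isTRUE(config$stages$subtype)) {
    report$subtype <- tryCatch(.stage_subtype(config, seed, out),
                               error = function(e) on_fail("subtype", e))
  }
  if (!is.null(out))
    write_json_report(report, file.path(out, "run_report.json"))
  structure(report, class = "run_report")
}

.stage_gating <- function(config, seed, out) {
  q <- config$pos_quantile
  n <- config$n_panel_events
  res <- list()
  # myeloid panel, sham vs day-21 glioma
  gl <- generate_event_panel(myeloid_panel_config("glioma", 21L, n, seed))
  sh <- generate_event_panel(myeloid_panel_config("sham", 21L, n,
                                                  seed = seed + 1L))
  th_gl <- derive_thresholds(gl$stained, gl$isotype, q)
  th_sh <- derive_thresholds(sh$stained, sh$isotype, q,
                             manual_split = th_gl$theta_split)
  fr_gl <- classify_myeloid(gl$stained, th_gl)
  fr_sh <- classify_myeloid(sh$stained, th_sh)
  res$myeloid <- list(
    glioma = as.list(fr_gl$fractions), sham = as.list(fr_sh$fractions),
    kinetics_day21 = kinetics_ratio(fr_gl, fr_sh))
  # single-marker T-cell panels
  res$tcell <- list()
  for (mk in c("FOXP3", "CD4", "CD8a")) {
    p <- generate_event_panel(tcell_panel_config(mk, "glioma",
                                                 n_events = n, seed = seed))
    th <- derive_thresholds(p$stained, p$isotype, q, split_channel = NULL)
    res$tcell[[mk]] <-
      classify_tcell_panel(p$stained, th, mk)$fractions[[paste0(mk, "_pos")]]
  }
  # MDSC panels, brain and blood
  res$mdsc <- list()
  for (cp in c("brain", "blood")) {
    p <- generate_event_panel(mdsc_panel_config("glioma", cp, n, seed))
    th <- derive_thresholds(p$stained, p$isotype, q, split_channel = NULL)
    cl <- classify_mdsc(p$stained, th)
    res$mdsc[[cp]] <- list(double_positive = cl$fractions[["mdsc"]],
                           within_cd11b = cl$conditional_fraction)
  }
  if (!is.null(out)) {
    rows <- data.frame(
      population = names(fr_gl$fractions),
      glioma = as.numeric(fr_gl$fractions),
      sham = as.numeric(fr_sh$fractions))
    utils::write.table(rows, file.path(out, "myeloid_fractions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

.stage_diffexpr <- function(config, seed, out) {
  e <- config$expr
  set.seed(child_seed(seed, "pipeline:de_genes"))
  genes <- sprintf("g%05d", seq_len(e$n_genes))
  de_genes <- data.frame(
    gene = sample(genes, e$n_de),
    effect = sample(c(-1, 1), e$n_de, replace = TRUE) * e$effect)
  cfg <- expr_sim_config(n_genes = e$n_genes, de_genes = de_genes,
                         noise_sd = e$noise_sd, seed = seed)
  sim <- generate_expression_study(cfg)
  de <- welch_de(sim$study, alpha = config$alpha)
  top <- top_regulated(de, config$top_genes)
  centred <- center_on_control(sim$study)
  if (!is.null(out)) {
    utils::write.table(de$table, file.path(out, "de_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(gene = rownames(centred), centred, check.names = FALSE),
      file.path(out, "centred_matrix.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    write_json_report(sim$de_truth, file.path(out, "de_ground_truth.json"))
  }
  list(
    summary = list(m = de$m, k = de$k, up = de$up, down = de$down,
                   alpha = de$alpha, fdr_hat = de$fdr_hat,
                   top_genes = utils::head(top$gene, 10L)),
    de = de, study = sim$study, de_truth = sim$de_truth
  )
}

.stage_go <- function(config, seed, out, de_bundle) {
  e <- config$expr
  up_genes <- de_bundle$de_truth$gene[de_bundle$de_truth$effect > 0]
  planted <- list(`GO:PLANTED_UP` = up_genes)
  annot <- generate_go_annotation(rownames(de_bundle$study$expr),
                                  n_random = e$n_go_terms,
                                  planted = planted, seed = seed)
  fc <- stats::setNames(de_bundle$de$table$log2fc, de_bundle$de$table$gene)
  res <- rank_enrichment(fc, annot)
  top_up <- summarize_terms(res, "up", config$top_terms)
  if (!is.null(out))
    utils::write.table(as.data.frame(res), file.path(out, "go_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(n_terms_tested = nrow(res), best_term = res$term[1],
       best_p = res$p[1], top_up_terms = utils::head(top_up$term, 5L))
}

.stage_subtype <- function(config, seed, out) {
  cc <- config$cohort
  cfg <- cohort_sim_config(samples_per_subtype = cc$samples_per_subtype,
                           n_normals = cc$n_normals, seed = seed)
  sim <- generate_human_cohort(cfg)
  ass <- assign_subtypes(sim$human, sim$signature)
  acc <- mean(ass$assignments$subtype ==
                sim$truth$subtype_of[ass$assignments$sample])
  mapped <- map_orthologs(rownames(sim$rat$expr), sim$orthologs)
  rat_fcs <- fold_change_vector(sim$rat, per_sample = TRUE)
  human_fcs <- fold_change_vector(sim$human, per_sample = TRUE)
  simres <- similarity_ranking(rat_fcs, human_fcs, ass, mapped)
  if (!is.null(out)) {
    utils::write.table(ass$assignments, file.path(out, "assignments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(simres$summary, file.path(out, "similarity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(assignment_accuracy = acc, winner = simres$winner,
       target = sim$truth$target,
       mean_rho = stats::setNames(simres$summary$mean_rho,
                                  simres$summary$subtype),
       n_mapped_genes = simres$n_genes)
}
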