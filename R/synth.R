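# Synthetic-data generators. Every input the pipeline consumes can be
# simulated here with planted ground truth recorded in a separate record,
# never embedded in the data tables themselves.

# default log-normal location/scale (natural-log units) for the fluorescence
# model: background (and isotype) events sit low, marker-positive events high,
# and CD45 gets distinct "low" and "high" components separated by a
# configurable gap so the low/high split is learnable from the data.
# the isotype control sits slightly above true-negative autofluorescence
# (non-specific antibody binding), the usual behaviour of isotype controls;
# stained marker-negative channels therefore use the lower autofluorescence
# location while isotype tables use the background location.
.FLUO <- list(
  background_meanlog = 1.0, background_sdlog = 0.5,
  autofluo_meanlog = 0.5, autofluo_sdlog = 0.5,
  positive_meanlog = 6.0, positive_sdlog = 0.35,
  cd45_low_meanlog = 4.0, split_gap = 2.0
)

#' Configure a flow-cytometry panel simulation
#'
#' Describes one stained panel as a log-normal mixture: each population has a
#' mixing fraction and, per channel, a log-mean and log-sd. Channels are
#' independent within a population. A matched isotype-control distribution
#' (background staining only) is part of the configuration.
#'
#' @param panel_name panel label, e.g. `"myeloid"`.
#' @param channels character vector of channel (marker) names.
#' @param populations list of population descriptions; each element is a list
#'   with `name`, `fraction`, `meanlog` (named per channel) and `sdlog`
#'   (named per channel). Fractions must sum to 1.
#' @param n_events number of stained events to draw (>= 1).
#' @param isotype_meanlog,isotype_sdlog per-channel background parameters for
#'   the isotype control (named numeric vectors).
#' @param n_isotype number of isotype-control events (>= 100 recommended).
#' @param condition,compartment,day panel metadata (see [event_table()]).
#' @param seed integer seed for this panel.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(panel_name, channels, populations, n_events,
                             isotype_meanlog, isotype_sdlog,
                             n_isotype = 10000L,
                             condition = "naive", compartment = "brain",
                             day = NA_integer_, seed = 1L) {
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    validation_error("population fractions must sum to 1 (got %.12f)", sum(fr))
  if (any(fr < 0 | fr > 1))
    validation_error("population fractions must lie in [0, 1]")
  if (n_events < 1L) validation_error("n_events must be >= 1")
  for (p in populations) {
    if (!all(channels %in% names(p$meanlog)) ||
        !all(channels %in% names(p$sdlog)))
      schema_error("population '%s' lacks parameters for some channels",
                   p$name)
    if (any(p$sdlog[channels] < 0))
      validation_error("population '%s' has negative log-sd", p$name)
  }
  if (!all(channels %in% names(isotype_meanlog)) ||
      !all(channels %in% names(isotype_sdlog)))
    schema_error("isotype parameters must cover every channel")
  structure(
    list(panel_name = panel_name, channels = channels,
         populations = populations, n_events = as.integer(n_events),
         isotype_meanlog = isotype_meanlog, isotype_sdlog = isotype_sdlog,
         n_isotype = as.integer(n_isotype), condition = condition,
         compartment = compartment, day = day, seed = as.integer(seed)),
    class = "panel_sim_config"
  )
}

.pop <- function(name, fraction, channels, meanlog, sdlog) {
  list(name = name, fraction = fraction,
       meanlog = stats::setNames(meanlog, channels),
       sdlog = stats::setNames(sdlog, channels))
}

#' Default myeloid (CD11b/CD45) panel configurations
#'
#' Planted population fractions follow the day-21 flow-cytometry
#' quantification of the rat C6 glioma model: sham-operated brains carry 13%
#' microglia (CD11b+CD45low) and essentially no macrophages or leukocytes;
#' tumor-bearing brains at day 21 carry 28% microglia, 4% blood-derived
#' macrophages (CD11b+CD45high) and 20% leukocytes (CD11b-CD45high).
#' Earlier-day glioma fractions interpolate the reported kinetics (microglia
#' unchanged at day 8, rising by day 14).
#'
#' @param condition `"glioma"`, `"sham"` or `"naive"`.
#' @param day day after implantation (8, 14 or 21).
#' @param n_events stained events to draw (default 5e4).
#' @param seed integer seed.
#' @return A `panel_sim_config`.
#' @export
myeloid_panel_config <- function(condition = "glioma", day = 21L,
                                 n_events = 50000L, seed = 1L) {
  condition <- match.arg(condition, c("glioma", "sham", "naive"))
  fr <- switch(condition,
    glioma = switch(as.character(day),
      "8"  = c(microglia = 0.13, macrophage = 0.005, leukocyte = 0.015),
      "14" = c(microglia = 0.22, macrophage = 0.025, leukocyte = 0.12),
      "21" = c(microglia = 0.28, macrophage = 0.04, leukocyte = 0.20),
      validation_error("day must be one of 8, 14, 21")),
    sham = c(microglia = 0.13, macrophage = 0.005, leukocyte = 0.01),
    naive = c(microglia = 0.13, macrophage = 0.001, leukocyte = 0.002)
  )
  ch <- c("CD11b", "CD45")
  f <- .FLUO
  cd45_high <- f$cd45_low_meanlog + f$split_gap
  pops <- list(
    .pop("microglia", fr[["microglia"]], ch,
         c(f$positive_meanlog, f$cd45_low_meanlog),
         rep(f$positive_sdlog, 2)),
    .pop("macrophage", fr[["macrophage"]], ch,
         c(f$positive_meanlog, cd45_high), rep(f$positive_sdlog, 2)),
    .pop("leukocyte", fr[["leukocyte"]], ch,
         c(f$autofluo_meanlog, cd45_high),
         c(f$autofluo_sdlog, f$positive_sdlog)),
    .pop("negative", 1 - sum(fr), ch,
         rep(f$autofluo_meanlog, 2), rep(f$autofluo_sdlog, 2))
  )
  panel_sim_config("myeloid", ch, pops, n_events,
                   isotype_meanlog = stats::setNames(rep(f$background_meanlog, 2), ch),
                   isotype_sdlog = stats::setNames(rep(f$background_sdlog, 2), ch),
                   condition = condition, compartment = "brain",
                   day = day, seed = seed)
}

#' Default single-marker T-cell panel configurations
#'
#' Planted positive fractions follow the day-21 quantification in tumor-bearing
#' versus sham brains: Treg (FOXP3+) 8.20% vs 2.0%, Th (CD4+) 2.80% vs 1.2%,
#' Tc (CD8a+) 0.8% vs 1.2% (the cytotoxic fraction is slightly *reduced* in
#' gliomas; sham values for all three panels are not printed in the source
#' quantification and are modelled choices).
#'
#' @param marker one of `"FOXP3"`, `"CD4"`, `"CD8a"`.
#' @param condition `"glioma"` or `"sham"`.
#' @param n_events stained events; the intracellular FOXP3 protocol analyses
#'   1e6 cells, surface panels 5e4.
#' @param seed integer seed.
#' @return A `panel_sim_config`.
#' @export
tcell_panel_config <- function(marker = c("FOXP3", "CD4", "CD8a"),
                               condition = "glioma",
                               n_events = if (marker[1] == "FOXP3") 1000000L else 50000L,
                               seed = 1L) {
  marker <- match.arg(marker)
  condition <- match.arg(condition, c("glioma", "sham"))
  fr <- switch(marker,
    FOXP3 = c(glioma = 0.0820, sham = 0.020),
    CD4   = c(glioma = 0.0280, sham = 0.012),
    CD8a  = c(glioma = 0.008, sham = 0.012)
  )[[condition]]
  f <- .FLUO
  pops <- list(
    .pop(paste0(marker, "_pos"), fr, marker, f$positive_meanlog,
         f$positive_sdlog),
    .pop("negative", 1 - fr, marker, f$autofluo_meanlog, f$autofluo_sdlog)
  )
  panel_sim_config(paste0("tcell_", marker), marker, pops, n_events,
                   isotype_meanlog = stats::setNames(f$background_meanlog, marker),
                   isotype_sdlog = stats::setNames(f$background_sdlog, marker),
                   condition = condition, compartment = "brain", day = 21L,
                   seed = seed)
}

#' Default MDSC (CD11b/Gr1) panel configurations
#'
#' Planted CD11b+Gr1+ (double-positive) fractions follow the day-21
#' quantification: 3.99% in glioma-bearing brains vs 1.05% in sham brains,
#' and 6.30% vs 2.11% in peripheral blood. A CD11b+Gr1- component is planted
#' alongside so the conditional Gr1+ fraction within CD11b+ cells is
#' informative.
#'
#' @param condition `"glioma"` or `"sham"`.
#' @param compartment `"brain"` or `"blood"`.
#' @param n_events stained events (default 5e4).
#' @param seed integer seed.
#' @return A `panel_sim_config`.
#' @export
mdsc_panel_config <- function(condition = "glioma", compartment = "brain",
                              n_events = 50000L, seed = 1L) {
  condition <- match.arg(condition, c("glioma", "sham"))
  compartment <- match.arg(compartment, c("brain", "blood"))
  dp <- if (compartment == "brain") c(glioma = 0.0399, sham = 0.0105)
        else c(glioma = 0.0630, sham = 0.0211)
  single <- if (compartment == "brain") c(glioma = 0.28, sham = 0.13)
            else c(glioma = 0.25, sham = 0.20)
  dp <- dp[[condition]]; single <- single[[condition]]
  ch <- c("CD11b", "Gr1")
  f <- .FLUO
  pops <- list(
    .pop("mdsc", dp, ch, rep(f$positive_meanlog, 2),
         rep(f$positive_sdlog, 2)),
    .pop("cd11b_single", single, ch,
         c(f$positive_meanlog, f$autofluo_meanlog),
         c(f$positive_sdlog, f$autofluo_sdlog)),
    .pop("negative", 1 - dp - single, ch, rep(f$autofluo_meanlog, 2),
         rep(f$autofluo_sdlog, 2))
  )
  panel_sim_config("mdsc", ch, pops, n_events,
                   isotype_meanlog = stats::setNames(rep(f$background_meanlog, 2), ch),
                   isotype_sdlog = stats::setNames(rep(f$background_sdlog, 2), ch),
                   condition = condition, compartment = compartment,
                   day = 21L, seed = seed)
}

#' Generate a stained/isotype event-table pair from a panel configuration
#'
#' Draws `n_events` events from the configured log-normal mixture (stained
#' table) and `n_isotype` events from the background-only isotype
#' distribution. The planted population fractions are returned as a separate
#' ground-truth record, exactly as configured. Identical seed and
#' configuration give bit-identical output.
#'
#' @param config a [panel_sim_config()].
#' @return List with elements `stained` and `isotype` ([event_table()]s) and
#'   `truth` (list with `panel`, `condition`, `compartment`, `day` and the
#'   planted `fractions`).
#' @export
generate_event_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(child_seed(config$seed, paste0("panel:", config$panel_name, ":",
                                          config$condition, ":",
                                          config$compartment)))
  fr <- vapply(config$populations, function(p) p$fraction, numeric(1))
  idx <- sample.int(length(fr), config$n_events, replace = TRUE, prob = fr)
  mat <- matrix(NA_real_, config$n_events, length(config$channels),
                dimnames = list(NULL, config$channels))
  for (k in seq_along(config$populations)) {
    p <- config$populations[[k]]
    rows <- which(idx == k)
    if (!length(rows)) next
    for (ch in config$channels)
      mat[rows, ch] <- stats::rlnorm(length(rows), p$meanlog[[ch]],
                                     p$sdlog[[ch]])
  }
  iso <- matrix(NA_real_, config$n_isotype, length(config$channels),
                dimnames = list(NULL, config$channels))
  for (ch in config$channels)
    iso[, ch] <- stats::rlnorm(config$n_isotype,
                               config$isotype_meanlog[[ch]],
                               config$isotype_sdlog[[ch]])
  mk <- function(m, stain) {
    df <- as.data.frame(m)
    df <- cbind(event_id = seq_len(nrow(df)), df)
    event_table(df[-1], panel = config$panel_name,
                condition = config$condition,
                compartment = config$compartment, day = config$day,
                stain = stain)
  }
  names(fr) <- vapply(config$populations, function(p) p$name, character(1))
  list(
    stained = mk(mat, "antibody"),
    isotype = mk(iso, "isotype"),
    truth = list(panel = config$panel_name, condition = config$condition,
                 compartment = config$compartment, day = config$day,
                 fractions = as.list(fr))
  )
}

#' Configure an expression-study simulation
#'
#' Two-group (control vs tumor) log2 expression with planted per-gene effects
#' and, optionally, planted GO terms whose member genes share an effect
#' direction. Gene-level baselines are drawn once per gene; samples add
#' independent Gaussian noise; tumor samples add the planted log2 effects.
#'
#' @param n_genes gene universe size.
#' @param n_control,n_tumor samples per group (both >= 2; the downstream
#'   Welch test needs within-group variance). Defaults 4 and 3 follow the
#'   whole-hemisphere study design.
#' @param baseline_log2_mean,baseline_log2_sd gene baseline distribution
#'   (log2 units).
#' @param de_genes data frame with columns `gene` and `effect` (log2 units);
#'   may be empty for a null simulation.
#' @param noise_sd per-sample Gaussian noise sd (log2 units).
#' @param planted_go_terms named list term -> list(genes=, effect=) recording
#'   which gene sets were shifted together (genes must appear in `de_genes`).
#' @param genes optional explicit gene universe (character, length
#'   `n_genes`); defaults to generated identifiers.
#' @param seed integer seed.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 2000L, n_control = 4L, n_tumor = 3L,
                            baseline_log2_mean = 8, baseline_log2_sd = 2,
                            de_genes = NULL, noise_sd = 0.5,
                            planted_go_terms = list(), genes = NULL,
                            seed = 1L) {
  if (n_control < 2L || n_tumor < 2L)
    validation_error("both groups need >= 2 samples for Welch testing")
  genes <- genes %||% sprintf("g%05d", seq_len(n_genes))
  if (length(genes) != n_genes)
    validation_error("gene universe must contain exactly n_genes symbols")
  if (anyDuplicated(genes))
    validation_error("duplicate gene identifiers in the gene universe")
  if (is.null(de_genes))
    de_genes <- data.frame(gene = character(), effect = numeric())
  de_genes <- as.data.frame(de_genes)
  if (nrow(de_genes)) {
    if (anyDuplicated(de_genes$gene))
      validation_error("duplicate gene in de_genes")
    outside <- setdiff(de_genes$gene, genes)
    if (length(outside))
      validation_error("de_genes outside the gene universe: %s",
                       paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(
    list(n_genes = as.integer(n_genes), genes = genes,
         n_control = as.integer(n_control), n_tumor = as.integer(n_tumor),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd, de_genes = de_genes,
         noise_sd = noise_sd, planted_go_terms = planted_go_terms,
         seed = as.integer(seed)),
    class = "expr_sim_config"
  )
}

#' Generate a two-group expression study with planted effects
#'
#' @param config an [expr_sim_config()].
#' @return List with `study` (an [expression_study()]), `de_truth` (data
#'   frame of planted gene effects) and `go_truth` (list of planted term
#'   records).
#' @export
generate_expression_study <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(child_seed(config$seed, "expr"))
  genes <- config$genes
  n <- config$n_control + config$n_tumor
  samples <- c(sprintf("ctrl_%02d", seq_len(config$n_control)),
               sprintf("tumor_%02d", seq_len(config$n_tumor)))
  groups <- stats::setNames(rep(c("control", "tumor"),
                                c(config$n_control, config$n_tumor)),
                            samples)
  baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  expr <- baseline + matrix(stats::rnorm(config$n_genes * n, 0,
                                         config$noise_sd),
                            config$n_genes, n)
  dimnames(expr) <- list(genes, samples)
  if (nrow(config$de_genes)) {
    rows <- match(config$de_genes$gene, genes)
    tum <- which(groups == "tumor")
    expr[rows, tum] <- expr[rows, tum] + config$de_genes$effect
  }
  list(
    study = expression_study(expr, groups),
    de_truth = config$de_genes,
    go_truth = config$planted_go_terms
  )
}

#' Generate a flat GO annotation over a gene universe
#'
#' Random terms draw genes uniformly from the universe; planted terms are
#' included verbatim so enrichment recovery can be scored against them.
#'
#' @param genes gene universe (character).
#' @param n_random number of random background terms.
#' @param size_range min/max genes per random term.
#' @param planted named list term -> character vector of genes to include
#'   verbatim.
#' @param seed integer seed.
#' @return A [go_annotation()].
#' @export
generate_go_annotation <- function(genes, n_random = 50L,
                                   size_range = c(5L, 40L),
                                   planted = list(), seed = 1L) {
  set.seed(child_seed(seed, "go_annotation"))
  terms <- planted
  for (i in seq_len(n_random)) {
    size <- sample(seq(size_range[1], size_range[2]), 1L)
    terms[[sprintf("GO:%07d", i)]] <- sample(genes, size)
  }
  go_annotation(terms)
}

#' Configure a cross-species cohort simulation
#'
#' Describes a human tumor/normal cohort with planted subtype centroids, a
#' subtype signature, a partially-retained rat-to-human ortholog map, and a
#' rat study whose tumor samples carry one target subtype's centroid shifts
#' (attenuated) through the mapped genes.
#'
#' @param subtypes subtype names (default the four-subtype GBM panel).
#' @param genes_per_subtype signature genes per subtype (default 210, giving
#'   an 840-gene signature for four subtypes).
#' @param centroid_shift log2 up-shift of a subtype's signature genes in its
#'   own tumors.
#' @param samples_per_subtype,n_normals human cohort sizes.
#' @param retention fraction of signature genes retained in the ortholog map
#'   (default 660/840).
#' @param target subtype whose profile the rat study mimics.
#' @param attenuation multiplier in (0, 1] on the target centroid in rat
#'   tumors.
#' @param n_rat_tumor,n_rat_control rat study sizes (3 tumor replicates
#'   matching the reported n = 3, plus controls).
#' @param n_background_genes non-signature genes shared by both species.
#' @param baseline_log2_mean,baseline_log2_sd,noise_sd expression model
#'   parameters (log2 units).
#' @param seed integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(subtypes = c("Proneural", "Neural", "Classical",
                                           "Mesenchymal"),
                              genes_per_subtype = 210L, centroid_shift = 2,
                              samples_per_subtype = 20L, n_normals = 10L,
                              retention = 660 / 840, target = "Mesenchymal",
                              attenuation = 0.7, n_rat_tumor = 3L,
                              n_rat_control = 4L, n_background_genes = 1160L,
                              baseline_log2_mean = 8, baseline_log2_sd = 2,
                              noise_sd = 1, seed = 1L) {
  if (retention <= 0 || retention > 1)
    validation_error("retention must lie in (0, 1]")
  if (!target %in% subtypes)
    validation_error("target '%s' is not among the subtypes", target)
  if (length(target) != 1L)
    validation_error("exactly one target subtype is required")
  if (attenuation <= 0 || attenuation > 1)
    validation_error("attenuation must lie in (0, 1]")
  if (floor(retention * genes_per_subtype) < 3L)
    validation_error(
      "retention %.3f leaves < 3 mapped genes per subtype", retention)
  structure(
    list(subtypes = subtypes, genes_per_subtype = as.integer(genes_per_subtype),
         centroid_shift = centroid_shift,
         samples_per_subtype = as.integer(samples_per_subtype),
         n_normals = as.integer(n_normals), retention = retention,
         target = target, attenuation = attenuation,
         n_rat_tumor = as.integer(n_rat_tumor),
         n_rat_control = as.integer(n_rat_control),
         n_background_genes = as.integer(n_background_genes),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Generate a human cohort, signature, ortholog map and matched rat study
#'
#' Human tumors are baseline plus their own subtype's centroid shift plus
#' noise; normals are baseline plus noise. The signature lists each subtype's
#' shifted genes. The ortholog map retains an exact `retention` fraction of
#' signature genes (sampled without replacement) plus all background genes.
#' Rat tumor replicates carry the target subtype's shifts, attenuated,
#' through mapped genes only.
#'
#' @param config a [cohort_sim_config()].
#' @return List with `human` and `rat` ([expression_study()]s), `signature`
#'   (a [signature_set()]), `orthologs` (an [ortholog_map()]) and `truth`
#'   (target subtype, per-sample subtype labels, retained-gene count).
#' @export
generate_human_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(child_seed(config$seed, "cohort"))
  ns <- length(config$subtypes)
  n_sig <- ns * config$genes_per_subtype
  sig_genes <- sprintf("SIG%04d", seq_len(n_sig))
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(sig_genes, bg_genes)
  sets <- split(sig_genes, rep(config$subtypes,
                               each = config$genes_per_subtype))
  sets <- sets[config$subtypes]
  sig <- signature_set(sets)

  n_tumor <- ns * config$samples_per_subtype
  tumor_subtype <- rep(config$subtypes, each = config$samples_per_subtype)
  samples <- c(sprintf("tumor_%03d", seq_len(n_tumor)),
               sprintf("normal_%02d", seq_len(config$n_normals)))
  groups <- stats::setNames(rep(c("tumor", "control"),
                                c(n_tumor, config$n_normals)), samples)
  baseline <- stats::rnorm(length(genes), config$baseline_log2_mean,
                           config$baseline_log2_sd)
  expr <- baseline + matrix(stats::rnorm(length(genes) * length(samples), 0,
                                         config$noise_sd),
                            length(genes), length(samples))
  dimnames(expr) <- list(genes, samples)
  for (j in seq_len(n_tumor))
    expr[sets[[tumor_subtype[j]]], j] <-
      expr[sets[[tumor_subtype[j]]], j] + config$centroid_shift
  human <- expression_study(expr, groups)

  n_keep <- round(config$retention * n_sig)
  kept_sig <- sort(sample(sig_genes, n_keep))
  mapped_human <- c(kept_sig, bg_genes)
  pairs <- data.frame(rat = paste0("r", mapped_human), human = mapped_human)
  map <- ortholog_map(pairs)

  rat_samples <- c(sprintf("rat_ctrl_%02d", seq_len(config$n_rat_control)),
                   sprintf("rat_tumor_%02d", seq_len(config$n_rat_tumor)))
  rat_groups <- stats::setNames(rep(c("control", "tumor"),
                                    c(config$n_rat_control,
                                      config$n_rat_tumor)), rat_samples)
  rat_baseline <- stats::rnorm(length(mapped_human),
                               config$baseline_log2_mean,
                               config$baseline_log2_sd)
  rat_expr <- rat_baseline +
    matrix(stats::rnorm(length(mapped_human) * length(rat_samples), 0,
                        config$noise_sd),
           length(mapped_human), length(rat_samples))
  dimnames(rat_expr) <- list(pairs$rat, rat_samples)
  target_mapped <- intersect(sets[[config$target]], mapped_human)
  tum_idx <- which(rat_groups == "tumor")
  rat_expr[match(target_mapped, mapped_human), tum_idx] <-
    rat_expr[match(target_mapped, mapped_human), tum_idx] +
    config$attenuation * config$centroid_shift
  rat <- expression_study(rat_expr, rat_groups)

  list(human = human, rat = rat, signature = sig, orthologs = map,
       truth = list(target = config$target,
                    subtype_of = stats::setNames(tumor_subtype,
                                                 samples[seq_len(n_tumor)]),
                    n_retained_signature_genes = n_keep))
}
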