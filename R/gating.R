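# Quadrant-gate analysis of immune-cell flow-cytometry panels: thresholds
# from isotype controls, population classification, fractions, kinetics
# ratios and two-group comparisons.

#' Derive gate thresholds from an isotype control
#'
#' The positivity cutoff per channel is a high quantile (default the 99th
#' percentile) of the isotype-control intensity distribution, following the
#' convention that the isotype control defines background staining. For the
#' CD45 channel (or any `split_channel`) an additional low/high separator is
#' placed at the minimum-density point between the two largest modes of the
#' log-intensity distribution of split-channel-positive stained events.
#' Events exactly equal to a threshold are classified negative downstream
#' (strict inequality).
#'
#' @param stained stained [event_table()].
#' @param isotype matched isotype-control [event_table()] (>= 100 events).
#' @param pos_quantile probability for the positivity cutoff (default 0.99).
#' @param split_channel channel needing a low/high separator, or `NULL` for
#'   none; default `"CD45"` when present in the panel.
#' @param manual_split optional numeric override for the separator (intensity
#'   units); required when the positive events are unimodal.
#' @return Object of class `gate_thresholds`: list with `theta_pos` (named
#'   per channel) and `theta_split` (or `NULL`).
#' @export
derive_thresholds <- function(stained, isotype, pos_quantile = 0.99,
                              split_channel = "CD45", manual_split = NULL) {
  stopifnot(inherits(stained, "event_table"), inherits(isotype, "event_table"))
  channels <- names(stained$intensities)
  if (!setequal(channels, names(isotype$intensities)))
    schema_error("stained and isotype tables must share the panel's channels")
  if (n_events(isotype) < 100L)
    validation_error("isotype control needs >= 100 events (has %d)",
                     n_events(isotype))
  theta_pos <- vapply(channels, function(ch)
    unname(stats::quantile(isotype$intensities[[ch]], pos_quantile)),
    numeric(1))
  names(theta_pos) <- channels
  theta_split <- NULL
  if (!is.null(split_channel) && split_channel %in% channels) {
    if (!is.null(manual_split)) {
      theta_split <- manual_split
    } else {
      pos <- stained$intensities[[split_channel]]
      pos <- pos[pos > theta_pos[[split_channel]]]
      theta_split <- .density_valley(log(pos), split_channel)
    }
    if (theta_split <= theta_pos[[split_channel]])
      validation_error("theta_split must exceed theta_pos on %s",
                       split_channel)
  }
  structure(list(theta_pos = theta_pos, theta_split = theta_split,
                 pos_quantile = pos_quantile, split_channel = split_channel),
            class = "gate_thresholds")
}

# minimum-density point (on the intensity scale) between the two largest
# modes of a log-intensity sample; errors when fewer than two modes exist
.density_valley <- function(logx, channel) {
  if (length(logx) < 10L)
    tme_stop("gliomaTME_split_error",
             "too few %s-positive events to place a low/high split", channel)
  d <- stats::density(logx, n = 512)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  # ignore minor wiggles: a genuine second mode must reach 5% of the main one
  peaks <- peaks[d$y[peaks] >= 0.05 * max(d$y[peaks])]
  if (length(peaks) < 2L)
    tme_stop("gliomaTME_split_error",
             paste0("%s-positive events look unimodal; supply manual_split ",
                    "to place the low/high separator"), channel)
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1L
  exp(d$x[valley])
}

.pop_fractions <- function(counts, n_total, extra = list()) {
  structure(c(list(counts = counts, fractions = counts / n_total,
                   n_total = n_total), extra),
            class = "population_fractions")
}

#' @export
print.population_fractions <- function(x, ...) {
  cat(sprintf("<population_fractions> n = %d\n", x$n_total))
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %8d  %6.2f%%\n", nm, x$counts[[nm]],
                100 * x$fractions[[nm]]))
  invisible(x)
}

.require_channels <- function(events, needed) {
  missing <- setdiff(needed, names(events$intensities))
  if (length(missing))
    schema_error("panel lacks required channel(s): %s",
                 paste(missing, collapse = ", "))
}

#' Classify myeloid-panel events into quadrant populations
#'
#' Each event is assigned exactly one label: microglia (CD11b+, CD45 low:
#' `CD11b > theta_pos` and `theta_pos < CD45 <= theta_split`), blood-derived
#' macrophage (CD11b+, CD45 high), leukocyte (CD11b-, CD45 high), or
#' unclassified. Fractions are over all gated events.
#'
#' @param events stained myeloid [event_table()] with CD11b and CD45 channels.
#' @param th [derive_thresholds()] output including `theta_split`.
#' @return A `population_fractions` object with populations `microglia`,
#'   `macrophage`, `leukocyte`, `unclassified`.
#' @export
classify_myeloid <- function(events, th) {
  .require_channels(events, c("CD11b", "CD45"))
  if (is.null(th$theta_split))
    validation_error("myeloid classification needs a CD45 low/high split")
  cd11b <- events$intensities$CD11b
  cd45 <- events$intensities$CD45
  pos11b <- cd11b > th$theta_pos[["CD11b"]]
  pos45 <- cd45 > th$theta_pos[["CD45"]]
  high45 <- cd45 > th$theta_split
  label <- rep("unclassified", length(cd11b))
  label[pos11b & pos45 & !high45] <- "microglia"
  label[pos11b & high45] <- "macrophage"
  label[!pos11b & high45] <- "leukocyte"
  counts <- vapply(c("microglia", "macrophage", "leukocyte", "unclassified"),
                   function(l) sum(label == l), integer(1))
  .pop_fractions(counts, length(label))
}

#' Single-marker positive fraction for a T-cell panel
#'
#' Fraction of events whose marker intensity exceeds the isotype-derived
#' positivity cutoff; the denominator is all gated events.
#'
#' @param events stained [event_table()] containing the marker channel.
#' @param th [derive_thresholds()] output.
#' @param marker one of `"CD4"`, `"CD8a"`, `"FOXP3"`.
#' @return A `population_fractions` object with populations
#'   `<marker>_pos` and `unclassified`.
#' @export
classify_tcell_panel <- function(events, th, marker) {
  supported <- c("CD4", "CD8a", "FOXP3")
  if (!marker %in% supported)
    validation_error("unknown marker '%s'; supported markers: %s", marker,
                     paste(supported, collapse = ", "))
  .require_channels(events, marker)
  pos <- events$intensities[[marker]] > th$theta_pos[[marker]]
  counts <- stats::setNames(c(sum(pos), sum(!pos)),
                            c(paste0(marker, "_pos"), "unclassified"))
  .pop_fractions(counts, length(pos))
}

#' Double-positive MDSC fraction (CD11b+Gr1+)
#'
#' Reports the CD11b+Gr1+ fraction over all gated events and, additionally,
#' the conditional Gr1+ fraction within CD11b+ events (flagged undefined when
#' there are no CD11b+ events).
#'
#' @param events stained [event_table()] with CD11b and Gr1 channels.
#' @param th [derive_thresholds()] output.
#' @return A `population_fractions` object with populations `mdsc` and
#'   `unclassified` plus fields `conditional_fraction` and
#'   `conditional_defined`.
#' @export
classify_mdsc <- function(events, th) {
  .require_channels(events, c("CD11b", "Gr1"))
  pos11b <- events$intensities$CD11b > th$theta_pos[["CD11b"]]
  posgr1 <- events$intensities$Gr1 > th$theta_pos[["Gr1"]]
  dp <- pos11b & posgr1
  counts <- stats::setNames(c(sum(dp), sum(!dp)), c("mdsc", "unclassified"))
  cond_def <- any(pos11b)
  .pop_fractions(counts, length(dp), extra = list(
    conditional_fraction = if (cond_def) sum(dp) / sum(pos11b) else NA_real_,
    conditional_defined = cond_def
  ))
}

#' Glioma-to-sham kinetics ratios
#'
#' Per shared population, the ratio of the glioma fraction to the sham
#' fraction. A zero sham fraction flags the ratio undefined (`NA`) rather
#' than returning infinity.
#'
#' @param glioma,sham `population_fractions` with the same populations.
#' @return Data frame with columns `population`, `ratio`, `defined`.
#' @export
kinetics_ratio <- function(glioma, sham) {
  pops <- names(glioma$fractions)
  if (!setequal(pops, names(sham$fractions)))
    schema_error("glioma and sham fractions must cover the same populations")
  ratio <- vapply(pops, function(p) {
    s <- sham$fractions[[p]]
    if (s == 0) NA_real_ else glioma$fractions[[p]] / s
  }, numeric(1))
  data.frame(population = pops, ratio = unname(ratio),
             defined = !is.na(ratio), row.names = NULL)
}

#' Two-group comparison: Welch t followed by Mann-Whitney U
#'
#' Group summaries (mean, SEM, n), a two-sided Welch t-test, and a two-sided
#' Mann-Whitney U test (exact by enumeration for combined n <= 20, normal
#' approximation with tie correction above). The significance flag uses the
#' Mann-Whitney p at the 0.05 level.
#'
#' @param a,b numeric vectors of per-animal fractions (each n >= 2 for the
#'   Welch test).
#' @return List with group summaries, `t`, `t_p`, `U`, `mw_p`, `significant`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    validation_error("both groups need >= 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    d <- mean(b) - mean(a)
    t <- if (d == 0) 0 else sign(d) * Inf
    t_p <- if (d == 0) 1 else 0
  } else {
    ht <- stats::t.test(b, a)
    t <- unname(ht$statistic); t_p <- ht$p.value
  }
  mw <- mann_whitney(a, b)
  list(mean_a = mean(a), mean_b = mean(b),
       sem_a = stats::sd(a) / sqrt(length(a)),
       sem_b = stats::sd(b) / sqrt(length(b)),
       n_a = length(a), n_b = length(b),
       t = t, t_p = t_p, U = mw$U, mw_p = mw$p,
       significant = mw$p < 0.05)
}
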