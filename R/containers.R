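#' Construct an event table
#'
#' An event table holds per-event fluorescence intensities for one staining of
#' one flow-cytometry panel, together with the metadata needed to interpret it
#' (panel, experimental condition, tissue compartment, day after implantation,
#' and whether the stain is the specific antibody or its isotype control).
#'
#' @param intensities data frame or matrix of positive fluorescence
#'   intensities, one row per event, one column per channel (arbitrary units).
#' @param panel panel name, e.g. `"myeloid"`.
#' @param condition experimental condition: `"naive"`, `"sham"` or `"glioma"`.
#' @param compartment `"brain"` or `"blood"`.
#' @param day day after implantation (8, 14, 15 or 21), or `NA`.
#' @param stain `"antibody"` or `"isotype"`.
#' @return An object of class `event_table`.
#' @export
event_table <- function(intensities, panel, condition = "naive",
                        compartment = "brain", day = NA_integer_,
                        stain = "antibody") {
  intensities <- as.data.frame(intensities)
  if (nrow(intensities) < 1L)
    validation_error("event table must contain at least one event")
  if (ncol(intensities) < 1L)
    schema_error("event table must have at least one channel column")
  if (!all(vapply(intensities, is.numeric, logical(1))))
    schema_error("all channel columns must be numeric")
  if (any(vapply(intensities, function(x) any(!is.finite(x) | x <= 0),
                 logical(1))))
    validation_error("all fluorescence intensities must be finite and > 0")
  condition <- match.arg(condition, c("naive", "sham", "glioma"))
  compartment <- match.arg(compartment, c("brain", "blood"))
  stain <- match.arg(stain, c("antibody", "isotype"))
  structure(
    list(intensities = intensities, panel = panel, condition = condition,
         compartment = compartment, day = day, stain = stain),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> panel=%s stain=%s condition=%s %s day=%s\n",
              x$panel, x$stain, x$condition, x$compartment,
              as.character(x$day)))
  cat(sprintf("  %d events x %d channels: %s\n", nrow(x$intensities),
              ncol(x$intensities), paste(names(x$intensities),
                                         collapse = ", ")))
  invisible(x)
}

#' Number of events in an event table
#' @param x an `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$intensities)
}

#' Construct an expression study
#'
#' Container for a log2 expression matrix (genes in rows, samples in columns)
#' with a group label (`control` or `tumor`) per sample. This is the unit of
#' the differential-expression, GO-enrichment and subtype analyses.
#'
#' @param expr numeric matrix of log2 expression, genes x samples, with
#'   rownames (gene identifiers) and colnames (sample identifiers).
#' @param groups named character vector mapping every sample to `"control"`
#'   or `"tumor"`, in any order.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(expr, groups) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    schema_error("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup))
    validation_error("duplicate gene identifier(s): %s",
                     paste(unique(dup), collapse = ", "))
  missing <- setdiff(colnames(expr), names(groups))
  if (length(missing))
    validation_error("sample(s) without a group label: %s",
                     paste(missing, collapse = ", "))
  groups <- groups[colnames(expr)]
  bad <- setdiff(unique(groups), c("control", "tumor"))
  if (length(bad))
    validation_error("unknown group label(s): %s", paste(bad, collapse = ", "))
  structure(list(expr = expr, groups = groups), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%d control, %d tumor)\n",
              nrow(x$expr), ncol(x$expr), sum(x$groups == "control"),
              sum(x$groups == "tumor")))
  invisible(x)
}

#' Construct a subtype signature set
#'
#' A signature set maps each molecular subtype to its marker gene list. The
#' default human glioblastoma use case is a four-subtype signature (Proneural,
#' Neural, Classical, Mesenchymal) of 210 genes each; any disjoint gene lists
#' with at least three genes per subtype are accepted.
#'
#' @param sets named list, subtype -> character vector of gene symbols.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    schema_error("signature sets must be a named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  sizes <- lengths(sets)
  if (any(sizes < 3L))
    validation_error("every subtype needs >= 3 genes (violated by: %s)",
                     paste(names(sets)[sizes < 3L], collapse = ", "))
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes))
    validation_error("subtype gene lists must be pairwise disjoint")
  structure(list(sets = sets), class = "signature_set")
}

#' Construct a rat-to-human ortholog map
#'
#' @param pairs data frame with columns `rat` and `human` (gene symbols).
#'   Symbols are treated as case-sensitive opaque identifiers.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("rat", "human") %in% names(pairs)))
    schema_error("ortholog map needs columns 'rat' and 'human'")
  pairs$rat <- as.character(pairs$rat)
  pairs$human <- as.character(pairs$human)
  structure(list(pairs = unique(pairs[c("rat", "human")])),
            class = "ortholog_map")
}

#' Construct a GO annotation
#'
#' Flat term-to-gene annotation (no ontology-graph propagation; annotations
#' are consumed as given).
#'
#' @param terms named list, term id -> character vector of annotated genes.
#' @param names optional named character vector of human-readable term names.
#' @param namespace single namespace string recorded for all terms
#'   (default `"biological_process"`).
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(terms, names = NULL,
                          namespace = "biological_process") {
  if (is.null(base::names(terms)) || anyDuplicated(base::names(terms)))
    schema_error("term ids must be unique and named")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0L))
    validation_error("every term needs a non-empty gene set")
  nm <- base::names(terms)
  full <- if (is.null(names)) stats::setNames(nm, nm) else {
    out <- stats::setNames(nm, nm)
    out[base::names(names)] <- names
    out
  }
  structure(list(terms = terms, term_names = full, namespace = namespace),
            class = "go_annotation")
}
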