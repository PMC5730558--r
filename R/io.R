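# Readers and writers for the plain-text interchange formats: event CSV with
# a metadata JSON sidecar, expression and group TSVs, GMT gene sets, the
# two-column ortholog TSV, and JSON reports. Gene and sample identifiers are
# case-sensitive opaque symbols; no aliasing or normalization is applied.

#' Write an event table as CSV plus a metadata JSON sidecar
#'
#' @param x an [event_table()].
#' @param path CSV path; the sidecar is written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  df <- cbind(event_id = seq_len(nrow(x$intensities)), x$intensities)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(panel = x$panel, condition = x$condition,
               compartment = x$compartment, day = x$day, stain = x$stain,
               channels = names(x$intensities))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an event table written by [write_event_csv()]
#'
#' @param path CSV path with a `<path>.meta.json` sidecar.
#' @return An [event_table()].
#' @export
read_event_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "event_id")
    schema_error("%s: first column must be 'event_id'", path)
  missing <- setdiff(meta$channels, names(df))
  if (length(missing))
    schema_error("%s: channel column(s) missing: %s", path,
                 paste(missing, collapse = ", "))
  event_table(df[meta$channels], panel = meta$panel,
              condition = meta$condition, compartment = meta$compartment,
              day = meta$day, stain = meta$stain)
}

#' Write an expression study as a genes-by-samples TSV plus a groups TSV
#'
#' @param study an [expression_study()].
#' @param expr_path TSV path for the matrix (first column `gene`).
#' @param groups_path TSV path for the two-column sample/group table.
#' @return `expr_path`, invisibly.
#' @export
write_expression_tsv <- function(study, expr_path, groups_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$expr), study$expr,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gdf <- data.frame(sample = names(study$groups),
                    group = unname(study$groups))
  utils::write.table(gdf, groups_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(expr_path)
}

#' Read an expression study from a matrix TSV and a groups TSV
#'
#' @param expr_path genes-by-samples TSV, first column `gene`. A duplicated
#'   gene row is an error naming the gene.
#' @param groups_path two-column TSV (`sample`, `group`).
#' @return An [expression_study()].
#' @export
read_expression_tsv <- function(expr_path, groups_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE)
  if (names(df)[1] != "gene")
    schema_error("%s: first column must be 'gene'", expr_path)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup))
    validation_error("%s: duplicated gene row(s): %s", expr_path,
                     paste(unique(dup), collapse = ", "))
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$gene
  gdf <- utils::read.delim(groups_path)
  if (!all(c("sample", "group") %in% names(gdf)))
    schema_error("%s: needs columns 'sample' and 'group'", groups_path)
  expression_study(mat, stats::setNames(gdf$group, gdf$sample))
}

#' Write gene sets in GMT format
#'
#' One line per set: `name TAB description TAB gene...`.
#'
#' @param sets named list, set name -> character vector of genes.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return List with `sets` (named list of gene vectors) and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      schema_error("%s line %d: GMT rows need name, description, >=1 gene",
                   path, i)
    if (f[1] %in% names(sets))
      validation_error("%s line %d: duplicate set '%s'", path, i, f[1])
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  list(sets = sets, descriptions = desc)
}

#' Write an ortholog map as a two-column TSV
#'
#' @param map an [ortholog_map()].
#' @param path output path (columns `rat`, `human`).
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  utils::write.table(map$pairs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ortholog map from a two-column TSV
#'
#' @param path TSV with columns `rat` and `human`.
#' @return An [ortholog_map()].
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path)
  ortholog_map(df)
}

#' Read a GO annotation from a GMT file
#'
#' @param path GMT path (term id, term name, genes...).
#' @param namespace namespace recorded for the terms.
#' @return A [go_annotation()].
#' @export
read_go_gmt <- function(path, namespace = "biological_process") {
  g <- read_gmt(path)
  go_annotation(g$sets, names = g$descriptions, namespace = namespace)
}

#' Write a named list as pretty JSON
#'
#' @param x list to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
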