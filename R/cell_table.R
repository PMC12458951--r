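#' Per-cell feature tables
#'
#' A cell table is a `data.frame` (class `cell_table`) with one row per
#' segmented cell. Mandatory columns are `cell_id` (unique), `x_um` and
#' `y_um` (centroid coordinates in micrometres, image convention: origin at
#' the top-left, y increasing downward). Marker mean intensities are plain
#' numeric columns named after the marker; binary positivity calls produced
#' by [apply_gates()] are logical columns suffixed `_call`; [assign_phenotypes()]
#' adds a `phenotype` column and [classify_compartment()] a `compartment`
#' column (`"tumor:<domain_id>"`, `"non_tumor"` or `"excluded"`).
#'
#' @param df data.frame with at least `cell_id`, `x_um`, `y_um`.
#' @return A validated `cell_table`.
#' @export
cell_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cell table schema error: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("cell table integrity error: duplicate cell_id values")
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("cell table integrity error: non-finite coordinates")
  df <- as.data.frame(df)
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Read a cell table from CSV
#'
#' @param path CSV file with a header row.
#' @param column_map optional named character vector mapping file column
#'   names to the canonical names `cell_id`, `x_um`, `y_um` (e.g.
#'   `c(cell_id = "CellID", x_um = "X_centroid", y_um = "Y_centroid")`).
#'   Unlisted columns are kept under their file names; columns suffixed
#'   `_call` are coerced to logical.
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cell table file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop("cell table schema error: mapped column '", src, "' not in file")
      names(df)[names(df) == src] <- canon
    }
  }
  for (cc in grep("_call$", names(df), value = TRUE)) df[[cc]] <- as.logical(df[[cc]])
  cell_table(df)
}

#' Write a cell table to CSV
#'
#' Coordinates are in micrometres (image convention, y down); a comment
#' header line records this. Round-trips through [read_cell_table()].
#'
#' @param table a `cell_table`
#' @param path output CSV path
#' @export
write_cell_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: micrometres, image convention (origin top-left, y down)", con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gating configuration
#'
#' One intensity threshold per gated marker. A cell is called positive when
#' its intensity is strictly greater than the threshold (cells exactly at
#' the threshold are negative). A marker may optionally be restricted to
#' regions of interest: its threshold is then only applied to cells inside
#' the given polygons and the call is `FALSE` elsewhere, mirroring gating of
#' markers that are only reliable inside dense immune aggregates (e.g.
#' Ki67, TCF1, PD-1).
#'
#' @param thresholds named numeric vector, marker -> nonnegative threshold.
#' @param regions optional named list, marker -> list of polygons (each a
#'   list with numeric `x`, `y` ring vectors) restricting where that
#'   marker's gate applies.
#' @export
gating_config <- function(thresholds, regions = NULL) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  if (any(thresholds < 0)) stop("gating thresholds must be nonnegative")
  if (anyDuplicated(names(thresholds)))
    stop("each gated marker must have exactly one threshold")
  structure(list(thresholds = thresholds, regions = regions),
            class = "gating_config")
}

#' Apply marker gates
#'
#' Adds a logical `<marker>_call` column per gated marker:
#' `intensity > threshold` (strict). Intensities are left untouched, so
#' gating is idempotent.
#'
#' @param table a `cell_table` carrying intensity columns
#' @param gating a [gating_config()]
#' @return The table with call columns added/overwritten.
#' @export
apply_gates <- function(table, gating) {
  stopifnot(inherits(gating, "gating_config"))
  for (m in names(gating$thresholds)) {
    if (!m %in% names(table))
      stop("gating configuration error: marker '", m, "' not in table")
    call <- table[[m]] > gating$thresholds[[m]]
    regs <- gating$regions[[m]]
    if (!is.null(regs)) {
      inside <- rep(FALSE, nrow(table))
      for (rg in regs)
        inside <- inside | points_in_polygon(table$x_um, table$y_um, rg$x, rg$y)
      call <- call & inside
    }
    table[[paste0(m, "_call")]] <- call
  }
  table
}

#' Phenotype rule set
#'
#' An ordered list of gating rules; the first (highest-priority) matching
#' rule labels the cell, cells matching no rule are `"unclassified"`. Each
#' rule requires a set of positive and (optionally) negative marker calls.
#' Lineage conflicts (e.g. CD20+CD3d+ doublets) are resolved purely by rule
#' order, so place the preferred lineage first.
#'
#' @param rules list of lists with elements `label`, `positive` (character
#'   vector of markers required positive) and optional `negative`.
#' @export
phenotype_rules <- function(rules) {
  stopifnot(is.list(rules), length(rules) > 0)
  for (r in rules) {
    if (is.null(r$label) || is.null(r$positive))
      stop("each phenotype rule needs a label and required-positive markers")
  }
  structure(rules, class = "phenotype_rules")
}

#' Default phenotype hierarchy
#'
#' A compact rule set covering the populations used throughout the
#' analyses: cytotoxic/exhausted CD8 T-cell states first (most specific),
#' then T lineages ahead of B (T > B on doublets), then B-cell states.
#' Labels: `Tpex` (TCF1+PD-1+CD8+), `CTL` (GZB+CD8+), `Tex` (PD-1+CD8+),
#' `CD8 T` (CD3d+CD8a+), `CD4 T` (CD3d+CD4+), `T` (CD3d+), `Ki67+ B`
#' (CD20+Ki67+), `B` (CD20+), `tumor` (AMACR+).
#'
#' @export
default_phenotype_rules <- function() {
  phenotype_rules(list(
    list(label = "Tpex",    positive = c("TCF1", "PD1", "CD8a", "CD3d")),
    list(label = "CTL",     positive = c("GZB", "CD8a", "CD3d")),
    list(label = "Tex",     positive = c("PD1", "CD8a", "CD3d")),
    list(label = "CD8 T",   positive = c("CD3d", "CD8a")),
    list(label = "CD4 T",   positive = c("CD3d", "CD4")),
    list(label = "T",       positive = "CD3d"),
    list(label = "Ki67+ B", positive = c("CD20", "Ki67")),
    list(label = "B",       positive = "CD20"),
    list(label = "tumor",   positive = "AMACR")
  ))
}

#' Assign phenotypes from binary marker calls
#'
#' @param table a `cell_table` with `_call` columns for all markers the
#'   rules reference
#' @param rules a [phenotype_rules()] object
#' @return The table with a `phenotype` column; every cell receives exactly
#'   one label.
#' @export
assign_phenotypes <- function(table, rules) {
  stopifnot(inherits(rules, "phenotype_rules"))
  markers <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  missing_calls <- setdiff(paste0(markers, "_call"), names(table))
  if (length(missing_calls) > 0)
    stop("phenotype configuration error: rules reference ungated marker(s): ",
         paste(sub("_call$", "", missing_calls), collapse = ", "))
  phen <- rep("unclassified", nrow(table))
  unset <- rep(TRUE, nrow(table))
  for (r in rules) {
    ok <- unset
    for (m in r$positive) ok <- ok & table[[paste0(m, "_call")]]
    for (m in r$negative %||% character(0)) ok <- ok & !table[[paste0(m, "_call")]]
    phen[ok] <- r$label
    unset <- unset & !ok
  }
  table$phenotype <- phen
  table
}

#' Exclude poor-quality regions
#'
#' Cells inside any excluded polygon are flagged `compartment = "excluded"`
#' and dropped from all downstream analyses (the returned table retains
#' them, flagged; use `drop = TRUE` to remove the rows).
#'
#' @param table a `cell_table`
#' @param excluded_polygons list of polygons (lists with `x`, `y` ring
#'   vectors) in the same micrometre frame
#' @param drop remove excluded rows instead of flagging them
#' @export
exclude_regions <- function(table, excluded_polygons, drop = FALSE) {
  if (length(excluded_polygons) == 0) return(table)
  excl <- rep(FALSE, nrow(table))
  for (pg in excluded_polygons) {
    if (!polygon_is_simple(pg$x, pg$y))
      stop("geometry error: excluded polygon is self-intersecting")
    excl <- excl | points_in_polygon(table$x_um, table$y_um, pg$x, pg$y)
  }
  if (!"compartment" %in% names(table)) table$compartment <- NA_character_
  table$compartment[excl] <- "excluded"
  if (drop) table <- table[!excl, , drop = FALSE]
  table
}

# Rows that take part in downstream analyses.
active_cells <- function(table) {
  if (!"compartment" %in% names(table)) return(table)
  table[is.na(table$compartment) | table$compartment != "excluded", , drop = FALSE]
}
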