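# Multi-panel composition: row-aligning track figures, count heatmaps and
# stacked bars against a shared sequence order — the order of a phylogeny's
# leaves when a tree is supplied, else the first panel's order.

panel_ids <- function(panel) UseMethod("panel_ids")
#' @export
panel_ids.track_figure <- function(panel) panel$rows$seq_id
#' @export
panel_ids.heatmap_panel <- function(panel) rownames(panel$counts)
#' @export
panel_ids.bar_panel <- function(panel) rownames(panel$counts)

panel_reorder <- function(panel, order) UseMethod("panel_reorder")

#' @export
panel_reorder.track_figure <- function(panel, order) {
  n <- length(order)
  new_y <- stats::setNames(seq(n, 1), order)
  old_y <- stats::setNames(panel$rows$y, panel$rows$seq_id)
  panel$rows <- data.frame(seq_id = order, y = unname(new_y[order]),
                           stringsAsFactors = FALSE)
  i <- match(order, panel$backbones$seq_id)
  panel$backbones <- panel$backbones[i, , drop = FALSE]
  panel$backbones$y <- unname(new_y[panel$backbones$seq_id])
  rownames(panel$backbones) <- NULL
  g <- panel$glyphs
  if (nrow(g) > 0L) {
    shift <- unname(new_y[g$seq_id] - old_y[g$seq_id])
    g$y0 <- g$y0 + shift
    g$y1 <- g$y1 + shift
    panel$glyphs <- g
  }
  panel
}

#' @export
panel_reorder.heatmap_panel <- function(panel, order) {
  panel$counts <- panel$counts[order, , drop = FALSE]
  panel
}

#' @export
panel_reorder.bar_panel <- function(panel, order) {
  panel$counts <- panel$counts[order, , drop = FALSE]
  panel$values <- panel$values[order, , drop = FALSE]
  panel
}

check_same_ids <- function(target, ids, what) {
  missing_ids <- setdiff(target, ids)
  extra <- setdiff(ids, target)
  if (length(missing_ids) > 0L || length(extra) > 0L) {
    stop(what, ": sequence sets differ",
         if (length(missing_ids)) paste0("; missing: ",
                                         paste(missing_ids, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
}

#' Compose row-aligned panels, optionally against a phylogeny
#'
#' All panels are re-ordered to one shared top-to-bottom sequence order —
#' the depth-first leaf order of `tree` when given, else the first panel's
#' row order — so that every sequence occupies the same y position in
#' every panel. A tree is drawn as the leftmost panel. Panels may be track
#' figures, count heatmaps or stacked-bar panels; each keeps its own
#' independent x axis (a protein panel and a gene panel have different
#' scales; only the rows are shared).
#'
#' @param panels list of panels ([build_track_figure()],
#'   [heatmap_panel()], [stacked_bar_panel()]).
#' @param tree optional Newick path/string or `phylo`; its leaf set must
#'   equal every panel's sequence set.
#' @param labels optional character vector of per-panel captions (the tree
#'   panel, when present, takes the first label).
#' @return an object of class `track_composite`.
#' @export
compose <- function(panels, tree = NULL, labels = NULL) {
  if (inherits(panels, c("track_figure", "heatmap_panel", "bar_panel"))) {
    panels <- list(panels)
  }
  stopifnot(is.list(panels), length(panels) >= 1L)
  phy <- if (!is.null(tree)) read_tree(tree) else NULL
  target <- if (!is.null(phy)) leaf_order(phy) else panel_ids(panels[[1]])
  for (i in seq_along(panels)) {
    check_same_ids(target, panel_ids(panels[[i]]), sprintf("panel %d", i))
    panels[[i]] <- panel_reorder(panels[[i]], target)
  }
  structure(list(tree = phy, panels = panels, labels = labels,
                 order = target),
            class = "track_composite")
}

#' @export
print.track_composite <- function(x, ...) {
  cat(sprintf("track_composite: %s%d panel(s), %d row(s)\n",
              if (!is.null(x$tree)) "tree + " else "", length(x$panels),
              length(x$order)))
  invisible(x)
}

# --- advance-plot panels ---------------------------------------------------

#' Count heatmap panel
#'
#' One grid cell per (sequence, column) of a [count_matrix()], colored on
#' a linear ramp from `low` (count 0) to `high` (the matrix maximum), with
#' the count printed in the cell. Zero cells stay blank unless
#' `show_zeros`. Rows follow the tree's leaf order when a tree is given.
#'
#' @param counts a [count_matrix()] (or any integer matrix with row and
#'   column names).
#' @param tree optional tree; leaves must equal the matrix row names.
#' @param low,high ramp endpoint colors.
#' @param show_zeros print `0` in empty cells.
#' @return an object of class `heatmap_panel`, composable with
#'   [compose()] and renderable with [render()].
#' @export
heatmap_panel <- function(counts, tree = NULL, low = "#F7FBFF",
                          high = "#CB181D", show_zeros = FALSE) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  panel <- structure(list(counts = counts, low = low, high = high,
                          show_zeros = isTRUE(show_zeros)),
                     class = "heatmap_panel")
  if (!is.null(tree)) {
    ord <- leaf_order(tree)
    check_same_ids(ord, rownames(counts), "heatmap_panel")
    panel <- panel_reorder(panel, ord)
  }
  panel
}

#' @export
print.heatmap_panel <- function(x, ...) {
  cat(sprintf("heatmap_panel: %d x %d, max count %d\n",
              nrow(x$counts), ncol(x$counts), max(x$counts, 0L)))
  invisible(x)
}

#' Stacked-bar panel of per-sequence totals
#'
#' One horizontal bar per sequence with one segment per matrix column. In
#' `"sum"` mode segment lengths are the counts, so each bar's length is
#' the row marginal; in `"percent"` mode they are `100 * count / row
#' total` and every non-empty bar totals exactly 100 (sequences with zero
#' records are drawn as empty bars, not dropped — tree alignment needs
#' their rows).
#'
#' @inheritParams heatmap_panel
#' @param mode `"sum"` or `"percent"` (per-sequence normalization).
#' @param palette_name,overrides segment colors, see [assign_palette()].
#' @return an object of class `bar_panel`.
#' @export
stacked_bar_panel <- function(counts, mode = c("sum", "percent"),
                              tree = NULL, palette_name = "default",
                              overrides = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  values <- if (mode == "sum") {
    matrix(as.numeric(counts), nrow(counts), ncol(counts),
           dimnames = dimnames(counts))
  } else {
    tot <- rowSums(counts)
    v <- 100 * counts / ifelse(tot == 0, 1, tot)
    v[tot == 0, ] <- 0
    v
  }
  panel <- structure(list(counts = counts, values = values, mode = mode,
                          palette = assign_palette(colnames(counts),
                                                   palette_name, overrides)),
                     class = "bar_panel")
  if (!is.null(tree)) {
    ord <- leaf_order(tree)
    check_same_ids(ord, rownames(counts), "stacked_bar_panel")
    panel <- panel_reorder(panel, ord)
  }
  panel
}

#' @export
print.bar_panel <- function(x, ...) {
  cat(sprintf("bar_panel (%s mode): %d bar(s), %d categor%s\n", x$mode,
              nrow(x$counts), ncol(x$counts),
              if (ncol(x$counts) == 1L) "y" else "ies"))
  invisible(x)
}

#' Cis-element distribution composite (tree + heatmap + stacked bars)
#'
#' Builds the full promoter-element overview in one call: the table is
#' classified into functional categories if needed, counted per sequence,
#' and laid out as a tree-aligned composite of a count heatmap and a
#' stacked-bar panel of category totals (sum or percent).
#'
#' @param table a [loc_table()] of cis-elements (classification is run
#'   with `cmap` if the table has no `category` column yet).
#' @param tree optional tree giving the row order.
#' @param mode bar mode, `"sum"` or `"percent"`.
#' @param by count `"category"` (default) or raw `"element"` names.
#' @param cmap a [category_map()] for classification (default map when
#'   omitted).
#' @param show_zeros print zeros in empty heatmap cells.
#' @return a `track_composite` with the heatmap and bar panels.
#' @export
advance_plot <- function(table, tree = NULL, mode = c("sum", "percent"),
                         by = c("category", "element"), cmap = NULL,
                         show_zeros = FALSE) {
  mode <- match.arg(mode)
  by <- match.arg(by)
  if (by == "category" && !("category" %in% names(table$records))) {
    table <- plantcare_classify(table, cmap = cmap)
  }
  m <- count_matrix(table, by = by)
  compose(list(heatmap_panel(m, show_zeros = show_zeros),
               stacked_bar_panel(m, mode = mode)),
          tree = tree)
}
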