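# Track figures: a deterministic, backend-agnostic layout (rows, backbone
# segments, glyph geometry, palette, legend) built from a loc_table.
# Rendering to SVG/PNG/PDF lives in render.R; the layout itself never
# touches a graphics device.

#' Build a per-sequence element track figure
#'
#' The basic plot of the package: one horizontal backbone line per
#' sequence (top to bottom, uniform spacing of 1 y-unit per row) with each
#' element record drawn as a rounded-rectangle glyph spanning
#' `[start - 1, end]` on a continuous axis. Colors are assigned
#' deterministically with [assign_palette()]; the legend lists the
#' distinct element names that received a glyph, in palette (sorted)
#' order.
#'
#' @param table a valid [loc_table()].
#' @param style glyph shape, `"rrect"` (rounded, default) or `"rect"`.
#' @param radius corner radius in row-height units (default 0.15); ignored
#'   for `style = "rect"`.
#' @param row_order optional character vector, a permutation of the
#'   table's seq_ids, giving the top-to-bottom row order (default: table
#'   order).
#' @param palette_name,overrides see [assign_palette()].
#' @param glyph_height default glyph height in row units.
#' @param heights named numeric vector of per-element height overrides.
#' @param skip_elements element names drawn as backbone only (no glyph,
#'   not in the legend) — the gff preset uses this for introns.
#' @param axis_label x-axis caption.
#' @return an object of class `track_figure` with components `rows`
#'   (seq_id, y), `backbones`, `glyphs`, `palette`, `legend` and `axis`.
#' @seealso [preset_plot()] for the fixed one-step style bundles,
#'   [render()] to write SVG/PNG/PDF, [compose()] for multi-panel figures.
#' @export
build_track_figure <- function(table, style = c("rrect", "rect"),
                               radius = 0.15, row_order = NULL,
                               palette_name = "default", overrides = NULL,
                               glyph_height = 0.6, heights = NULL,
                               skip_elements = character(),
                               axis_label = "Position") {
  style <- match.arg(style)
  stopifnot(inherits(table, "loc_table"))
  v <- validate_loc(table)
  if (length(v) > 0L) {
    stop("invalid loc_table:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  ids <- table$sequences$seq_id
  if (is.null(row_order)) {
    row_order <- ids
  } else {
    missing_ids <- setdiff(ids, row_order)
    extra <- setdiff(row_order, ids)
    if (length(missing_ids) > 0L || length(extra) > 0L) {
      stop("row_order is not a permutation of the table's sequences",
           if (length(missing_ids)) paste0("; missing: ",
                                           paste(missing_ids, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  n <- length(row_order)
  y <- stats::setNames(seq(n, 1), row_order)  # first row on top
  len <- stats::setNames(table$sequences$length, ids)
  rows <- data.frame(seq_id = row_order, y = unname(y[row_order]),
                     stringsAsFactors = FALSE)
  backbones <- data.frame(seq_id = rows$seq_id, y = rows$y, x0 = 0,
                          x1 = unname(len[rows$seq_id]),
                          stringsAsFactors = FALSE)
  r <- table$records
  drawn <- r[!(r$element %in% skip_elements), , drop = FALSE]
  h <- rep(glyph_height, nrow(drawn))
  if (!is.null(heights) && nrow(drawn) > 0L) {
    hit <- drawn$element %in% names(heights)
    h[hit] <- heights[drawn$element[hit]]
  }
  rad <- rep(if (style == "rect") 0 else radius, nrow(drawn))
  glyphs <- data.frame(
    seq_id = drawn$seq_id, element = drawn$element,
    x0 = drawn$start - 1, x1 = drawn$end,
    y0 = unname(y[drawn$seq_id]) - h / 2, y1 = unname(y[drawn$seq_id]) + h / 2,
    radius = rad, stringsAsFactors = FALSE)
  palette <- assign_palette(drawn$element, palette_name, overrides)
  structure(list(
    rows = rows,
    backbones = backbones,
    glyphs = glyphs,
    palette = palette,
    legend = names(palette),
    axis = list(xlim = c(0, max(c(1, len))), label = axis_label)
  ), class = "track_figure")
}

#' @export
print.track_figure <- function(x, ...) {
  cat(sprintf("track_figure: %d row(s), %d glyph(s), %d legend entr%s\n",
              nrow(x$rows), nrow(x$glyphs), length(x$legend),
              if (length(x$legend) == 1L) "y" else "ies"))
  invisible(x)
}

PRESET_STYLES <- list(
  gff = list(heights = c(CDS = 0.6, five_prime_UTR = 0.35,
                         three_prime_UTR = 0.35, exon = 0.6),
             skip_elements = "intron", axis_label = "Position (bp)"),
  meme = list(heights = NULL, skip_elements = character(),
              axis_label = "Position (bp)"),
  pfam = list(heights = NULL, skip_elements = character(),
              axis_label = "Position (aa)"),
  cdd = list(heights = NULL, skip_elements = character(),
             axis_label = "Position (aa)"),
  smart = list(heights = NULL, skip_elements = character(),
               axis_label = "Position (aa)"),
  plantcare = list(heights = NULL, skip_elements = character(),
                   axis_label = "Position (bp)")
)

#' One-step track figure with a fixed style bundle
#'
#' Equals [build_track_figure()] with the preset's style constants, so the
#' "one step" route (raw result file in, figure out) and the "step by
#' step" route (convert to a location table, then plot) produce identical
#' figures on identical inputs. The `gff` preset draws CDS as tall rounded
#' boxes, UTRs shorter, and introns as backbone only.
#'
#' @param table a valid [loc_table()].
#' @param preset one of `"gff"`, `"meme"`, `"pfam"`, `"cdd"`, `"smart"`,
#'   `"plantcare"`.
#' @param ... further arguments passed to [build_track_figure()]
#'   (e.g. `row_order`, `palette_name`, `overrides`).
#' @return a `track_figure`.
#' @export
preset_plot <- function(table, preset = names(PRESET_STYLES), ...) {
  preset <- match.arg(preset)
  st <- PRESET_STYLES[[preset]]
  build_track_figure(table, style = "rrect", heights = st$heights,
                     skip_elements = st$skip_elements,
                     axis_label = st$axis_label, ...)
}

#' Basic element plot from a location table
#'
#' Alias of [build_track_figure()]: draw any element map — protein, DNA or
#' RNA — from the canonical coordinate + length representation.
#'
#' @inheritParams build_track_figure
#' @param ... passed to [build_track_figure()].
#' @export
motif_plot <- function(table, ...) build_track_figure(table, ...)

# --- one-step wrappers: raw result file straight to a track figure --------

#' One-step plots from raw result files
#'
#' Each wrapper parses its format and applies the matching [preset_plot()]
#' style bundle in one call.
#'
#' @param path input file in the wrapper's format.
#' @param ... passed to the underlying parser (e.g. `transcript_policy`,
#'   `analysis_filter`, `fasta`) — except `row_order`, `palette_name` and
#'   `overrides`, which go to the figure builder.
#' @name one_step_plots
NULL

split_dots <- function(...) {
  dots <- list(...)
  fig_args <- intersect(names(dots), c("row_order", "palette_name", "overrides"))
  list(parser = dots[setdiff(names(dots), fig_args)], fig = dots[fig_args])
}

one_step <- function(parser, preset, path, ...) {
  a <- split_dots(...)
  tab <- do.call(parser, c(list(path), a$parser))
  do.call(preset_plot, c(list(tab, preset), a$fig))
}

#' @rdname one_step_plots
#' @export
gff_plot <- function(path, ...) one_step(gff_to_loc, "gff", path, ...)

#' @rdname one_step_plots
#' @export
meme_plot <- function(path, ...) one_step(meme_to_loc, "meme", path, ...)

#' @rdname one_step_plots
#' @export
pfam_plot <- function(path, ...) one_step(interpro_to_loc, "pfam", path, ...)

#' @rdname one_step_plots
#' @export
cdd_plot <- function(path, ...) one_step(cdd_to_loc, "cdd", path, ...)

#' @rdname one_step_plots
#' @export
smart_plot <- function(path, ...) one_step(smart_to_loc, "smart", path, ...)

#' @rdname one_step_plots
#' @export
plantcare_plot <- function(path, ...) one_step(plantcare_to_loc, "plantcare",
                                               path, ...)
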