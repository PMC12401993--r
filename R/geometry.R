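# Rounded-rectangle glyph geometry and deterministic color assignment.

#' Outline polygon of a rounded rectangle
#'
#' The workhorse glyph of every track figure. The corner radius is clamped
#' to `min(radius, (x1-x0)/2, (y1-y0)/2)`, which guarantees a simple
#' (non-self-intersecting) outline; with radius 0 the outline is exactly
#' the 4-corner rectangle. Corner arcs are approximated by `n_arc` segments
#' each, so the polygon area converges to the closed form
#' `w*h - (4-pi)*r^2` as `n_arc` grows.
#'
#' @param x0,x1,y0,y1 rectangle bounds, `x0 < x1`, `y0 < y1`.
#' @param radius corner radius in axis units, `>= 0`.
#' @param n_arc arc-approximation segments per corner, `>= 1`.
#' @return data frame of `x`, `y` polygon vertices, counter-clockwise,
#'   implicitly closed (the last vertex connects back to the first).
#' @examples
#' p <- rrect_outline(0, 1, 0, 1, radius = 0.25, n_arc = 64)
#' # area close to 1 - (4 - pi) * 0.25^2
#' @export
rrect_outline <- function(x0, x1, y0, y1, radius = 0, n_arc = 16L) {
  if (!(x1 > x0) || !(y1 > y0)) {
    stop(sprintf("degenerate rectangle: need x0 < x1 and y0 < y1 (got [%g,%g]x[%g,%g])",
                 x0, x1, y0, y1), call. = FALSE)
  }
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  n_arc <- max(1L, as.integer(n_arc))
  r <- min(radius, (x1 - x0) / 2, (y1 - y0) / 2)
  if (r == 0) {
    return(data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
  }
  corner <- function(cx, cy, from) {
    th <- seq(from, from + pi / 2, length.out = n_arc + 1L)
    list(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  cs <- list(corner(x1 - r, y0 + r, -pi / 2),  # bottom-right
             corner(x1 - r, y1 - r, 0),        # top-right
             corner(x0 + r, y1 - r, pi / 2),   # top-left
             corner(x0 + r, y0 + r, pi))       # bottom-left
  data.frame(x = unlist(lapply(cs, `[[`, "x")),
             y = unlist(lapply(cs, `[[`, "y")))
}

# shoelace area of an implicitly closed polygon
polygon_area <- function(p) {
  x <- p$x; y <- p$y
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

SEQTRACKS_PALETTES <- list(
  default = c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
              "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
              "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
              "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5"),
  okabe_ito = c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                "#D55E00", "#CC79A7", "#999999"),
  paired = c("#a6cee3", "#1f78b4", "#b2df8a", "#33a02c", "#fb9a99",
             "#e31a1c", "#fdbf6f", "#ff7f00", "#cab2d6", "#6a3d9a",
             "#ffff99", "#b15928")
)

#' Deterministic element-to-color assignment
#'
#' Element names are sorted, deduplicated, and mapped to the palette's
#' colors cycled in order, so that the same set of names always yields the
#' same mapping — across runs, and across the panels of a composite figure
#' regardless of per-panel element order. Overrides are applied last.
#'
#' @param element_names character vector (any order, duplicates allowed).
#' @param palette_name one of `"default"` (20 colors), `"okabe_ito"` (8),
#'   `"paired"` (12).
#' @param overrides named character vector of fixed `name = "#RRGGBB"`
#'   assignments.
#' @return named character vector, sorted unique names -> hex colors.
#' @export
assign_palette <- function(element_names, palette_name = "default",
                           overrides = NULL) {
  if (!palette_name %in% names(SEQTRACKS_PALETTES)) {
    stop("unknown palette '", palette_name, "'; available: ",
         paste(names(SEQTRACKS_PALETTES), collapse = ", "), call. = FALSE)
  }
  pal <- SEQTRACKS_PALETTES[[palette_name]]
  # radix sort: byte order, independent of the session locale
  nms <- sort(unique(as.character(element_names)), method = "radix")
  if (length(nms) == 0L) return(stats::setNames(character(), character()))
  cols <- pal[((seq_along(nms) - 1L) %% length(pal)) + 1L]
  out <- stats::setNames(cols, nms)
  if (!is.null(overrides)) {
    hit <- intersect(names(overrides), nms)
    out[hit] <- overrides[hit]
  }
  out
}
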