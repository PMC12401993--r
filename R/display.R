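# Display-list layout: every figure object is flattened into one list of
# pixel-space primitives (lines, polygons, rects, text). The SVG writer
# serializes that list verbatim (which is what makes SVG output
# byte-stable) and the base-graphics backend replays the same list, so
# every output format shares one geometry source.

DL <- list(rowh = 34, top = 30, axis_h = 52, bottom = 8, left = 8,
           right = 8, label_w = 112, tree_w = 150, panel_w = 380, gap = 26,
           legend_entry_h = 16)

prim_line <- function(x1, y1, x2, y2, stroke = "#555555", width = 1,
                      class = "") {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
       width = width, class = class)
}
prim_polygon <- function(x, y, fill, stroke = "none", class = "") {
  list(kind = "polygon", x = x, y = y, fill = fill, stroke = stroke,
       class = class)
}
prim_rect <- function(x, y, w, h, fill, stroke = "none", class = "") {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke, class = class)
}
prim_text <- function(x, y, text, size = 10, anchor = "start", angle = 0,
                      fill = "#222222", class = "") {
  list(kind = "text", x = x, y = y, text = as.character(text), size = size,
       anchor = anchor, angle = angle, fill = fill, class = class)
}

ramp_color <- function(frac, low, high) {
  m <- grDevices::colorRamp(c(low, high))(pmin(pmax(frac, 0), 1))
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

axis_prims <- function(x0, w, vmax, axis_y, caption) {
  ticks <- pretty(c(0, vmax), n = 5)
  ticks <- ticks[ticks >= 0 & ticks <= vmax]
  sx <- function(v) x0 + v / max(vmax, 1e-9) * w
  prims <- list(prim_line(x0, axis_y, x0 + w, axis_y, "#333333", 1))
  for (t in ticks) {
    prims <- c(prims, list(
      prim_line(sx(t), axis_y, sx(t), axis_y + 4, "#333333", 1),
      prim_text(sx(t), axis_y + 15, format(t, trim = TRUE,
                                           scientific = FALSE),
                size = 9, anchor = "middle")))
  }
  c(prims, list(prim_text(x0 + w / 2, axis_y + 32, caption, size = 10,
                          anchor = "middle")))
}

# --- per-panel primitive generators ---------------------------------------
# each returns list(prims = ..., legend = data.frame(label, color))

panel_prims <- function(panel, x0, w, ymap, yrow, axis_y) {
  UseMethod("panel_prims")
}

#' @export
panel_prims.track_figure <- function(panel, x0, w, ymap, yrow, axis_y) {
  xlim2 <- panel$axis$xlim[2]
  sx <- function(v) x0 + v / xlim2 * w
  prims <- list()
  b <- panel$backbones
  for (i in seq_len(nrow(b))) {
    prims <- c(prims, list(prim_line(sx(b$x0[i]), ymap[[b$seq_id[i]]],
                                     sx(b$x1[i]), ymap[[b$seq_id[i]]],
                                     "#666666", 1.2, class = "backbone")))
  }
  g <- panel$glyphs
  for (i in seq_len(nrow(g))) {
    pyc <- ymap[[g$seq_id[i]]] -
      ((g$y0[i] + g$y1[i]) / 2 - yrow[[g$seq_id[i]]]) * DL$rowh
    hpx <- (g$y1[i] - g$y0[i]) * DL$rowh
    out <- rrect_outline(sx(g$x0[i]), sx(g$x1[i]), pyc - hpx / 2,
                         pyc + hpx / 2, radius = g$radius[i] * DL$rowh,
                         n_arc = 16L)
    prims <- c(prims, list(prim_polygon(out$x, out$y,
                                        fill = panel$palette[[g$element[i]]],
                                        class = "glyph")))
  }
  prims <- c(prims, axis_prims(x0, w, xlim2, axis_y, panel$axis$label))
  legend <- data.frame(label = panel$legend,
                       color = unname(panel$palette[panel$legend]),
                       stringsAsFactors = FALSE)
  list(prims = prims, legend = legend)
}

#' @export
panel_prims.heatmap_panel <- function(panel, x0, w, ymap, yrow, axis_y) {
  m <- panel$counts
  nc <- ncol(m)
  maxc <- max(m, 0L)
  cw <- if (nc > 0L) w / nc else w
  prims <- list()
  for (i in seq_len(nrow(m))) {
    pyc <- ymap[[rownames(m)[i]]]
    for (j in seq_len(nc)) {
      fill <- if (maxc == 0L) panel$low else
        ramp_color(m[i, j] / maxc, panel$low, panel$high)
      prims <- c(prims, list(prim_rect(x0 + (j - 1) * cw + 1,
                                       pyc - DL$rowh / 2 + 2,
                                       cw - 2, DL$rowh - 4, fill,
                                       stroke = "#DDDDDD", class = "cell")))
      if (m[i, j] > 0L || panel$show_zeros) {
        dark <- maxc > 0L && m[i, j] / maxc > 0.6
        prims <- c(prims, list(prim_text(x0 + (j - 0.5) * cw, pyc + 3,
                                         m[i, j], size = 9,
                                         anchor = "middle",
                                         fill = if (dark) "#FFFFFF" else "#222222",
                                         class = "count")))
      }
    }
  }
  for (j in seq_len(nc)) {
    prims <- c(prims, list(prim_text(x0 + (j - 0.5) * cw, axis_y + 10,
                                     colnames(m)[j], size = 9,
                                     anchor = "start", angle = 45,
                                     class = "collab")))
  }
  legend <- data.frame(label = c("0", format(maxc)),
                       color = c(panel$low, panel$high),
                       stringsAsFactors = FALSE)
  list(prims = prims, legend = legend)
}

#' @export
panel_prims.bar_panel <- function(panel, x0, w, ymap, yrow, axis_y) {
  v <- panel$values
  vmax <- if (panel$mode == "percent") 100 else max(rowSums(v), 1e-9)
  sx <- function(val) x0 + val / vmax * w
  bh <- DL$rowh * 0.62
  prims <- list()
  for (i in seq_len(nrow(v))) {
    pyc <- ymap[[rownames(v)[i]]]
    cum <- 0
    for (j in seq_len(ncol(v))) {
      if (v[i, j] > 0) {
        prims <- c(prims, list(prim_rect(sx(cum), pyc - bh / 2,
                                         sx(cum + v[i, j]) - sx(cum), bh,
                                         panel$palette[[colnames(v)[j]]],
                                         class = "segment")))
        cum <- cum + v[i, j]
      }
    }
  }
  caption <- if (panel$mode == "percent") "Percent (%)" else "Count"
  prims <- c(prims, axis_prims(x0, w, vmax, axis_y, caption))
  legend <- data.frame(label = colnames(v),
                       color = unname(panel$palette[colnames(v)]),
                       stringsAsFactors = FALSE)
  list(prims = prims, legend = legend)
}

tree_prims <- function(phy, x0, w, ymap) {
  tip_y <- vapply(phy$tip.label, function(id) ymap[[id]], numeric(1))
  lay <- tree_layout(phy, tip_y)
  sx <- function(v) x0 + 6 + v * (w - 16)
  prims <- list()
  for (node in (lay$ntip + 1):(lay$ntip + length(lay$kids))) {
    kk <- lay$kids[[as.character(node)]]
    if (is.null(kk)) next
    prims <- c(prims, list(prim_line(sx(lay$x[node]), min(lay$y[kk]),
                                     sx(lay$x[node]), max(lay$y[kk]),
                                     "#444444", 1.2, class = "treeline")))
    for (k in kk) {
      prims <- c(prims, list(prim_line(sx(lay$x[node]), lay$y[k],
                                       sx(lay$x[k]), lay$y[k],
                                       "#444444", 1.2, class = "treeline")))
    }
  }
  prims
}

# --- the composite layout --------------------------------------------------

build_display <- function(x, ...) UseMethod("build_display")

#' @export
build_display.track_figure <- function(x, ...) {
  build_display(compose(list(x)), ...)
}
#' @export
build_display.heatmap_panel <- function(x, ...) {
  build_display(compose(list(x)), ...)
}
#' @export
build_display.bar_panel <- function(x, ...) {
  build_display(compose(list(x)), ...)
}

#' @export
build_display.track_composite <- function(x, ...) {
  order <- x$order
  n <- length(order)
  np <- length(x$panels)
  has_tree <- !is.null(x$tree)
  ymap <- stats::setNames(DL$top + (seq_len(n) - 1) * DL$rowh + DL$rowh / 2,
                          order)
  ymap <- as.list(ymap)
  yrow <- as.list(stats::setNames(seq(n, 1), order))  # figure row units
  content_bottom <- DL$top + n * DL$rowh
  axis_y <- content_bottom + 6

  # legends are collected per panel and drawn side by side under the axes
  x_tree <- DL$left
  x_label <- DL$left + (if (has_tree) DL$tree_w else 0)
  panel_x0 <- function(i) x_label + DL$label_w + (i - 1) * (DL$panel_w + DL$gap)
  width <- panel_x0(np) + DL$panel_w + DL$right

  prims <- list()
  legends <- list()
  if (has_tree) prims <- c(prims, tree_prims(x$tree, x_tree, DL$tree_w, ymap))
  for (id in order) {
    prims <- c(prims, list(prim_text(x_label + DL$label_w - 8, ymap[[id]] + 3,
                                     id, size = 10, anchor = "end",
                                     class = "rowlab")))
  }
  for (i in seq_len(np)) {
    pp <- panel_prims(x$panels[[i]], panel_x0(i), DL$panel_w, ymap, yrow,
                      axis_y)
    prims <- c(prims, pp$prims)
    legends[[i]] <- pp$legend
  }
  # panel captions
  if (!is.null(x$labels)) {
    lab <- x$labels
    k <- 1L
    if (has_tree && length(lab) >= 1L) {
      prims <- c(prims, list(prim_text(x_tree + DL$tree_w / 2, DL$top - 12,
                                       lab[1], size = 12, anchor = "middle",
                                       class = "caption")))
      k <- 2L
    }
    for (i in seq_len(np)) {
      if (k > length(lab)) break
      prims <- c(prims, list(prim_text(panel_x0(i) + DL$panel_w / 2,
                                       DL$top - 12, lab[k], size = 12,
                                       anchor = "middle", class = "caption")))
      k <- k + 1L
    }
  }
  # legends
  legend_top <- axis_y + DL$axis_h
  max_entries <- max(c(0L, vapply(legends, nrow, integer(1))))
  for (i in seq_len(np)) {
    lg <- legends[[i]]
    for (j in seq_len(nrow(lg))) {
      ly <- legend_top + (j - 1) * DL$legend_entry_h
      prims <- c(prims, list(
        prim_rect(panel_x0(i), ly, 12, 12, lg$color[j], stroke = "#999999",
                  class = "legend-swatch"),
        prim_text(panel_x0(i) + 18, ly + 10, lg$label[j], size = 9,
                  class = "legend-label")))
    }
  }
  height <- legend_top + max_entries * DL$legend_entry_h + DL$bottom
  list(width = width, height = height, prims = prims)
}
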