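# Output backends: a deterministic SVG writer (byte-identical output for
# identical figures — sequential element ids, no timestamps, fixed number
# formatting) and base-graphics replay for PNG/PDF devices.

px <- function(v) sprintf("%.2f", v)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_string <- function(disp) {
  w <- disp$width; h <- disp$height
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\"",
                   " height=\"%s\" viewBox=\"0 0 %s %s\">"),
            px(w), px(h), px(w), px(h)),
    sprintf("<rect id=\"e0\" x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#FFFFFF\"/>",
            px(w), px(h))
  )
  n <- 0L
  for (p in disp$prims) {
    n <- n + 1L
    id <- sprintf("e%d", n)
    cls <- if (nzchar(p$class)) sprintf(" class=\"%s\"", p$class) else ""
    tag <- switch(
      p$kind,
      line = sprintf(
        "<line id=\"%s\"%s x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
        id, cls, px(p$x1), px(p$y1), px(p$x2), px(p$y2), p$stroke,
        px(p$width)),
      polygon = sprintf(
        "<polygon id=\"%s\"%s points=\"%s\" fill=\"%s\" stroke=\"%s\"/>",
        id, cls, paste(paste0(px(p$x), ",", px(p$y)), collapse = " "),
        p$fill, p$stroke),
      rect = sprintf(
        "<rect id=\"%s\"%s x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"%s\"/>",
        id, cls, px(p$x), px(p$y), px(p$w), px(p$h), p$fill, p$stroke),
      text = {
        rot <- if (p$angle != 0)
          sprintf(" transform=\"rotate(%s %s %s)\"", px(p$angle), px(p$x),
                  px(p$y)) else ""
        sprintf(
          "<text id=\"%s\"%s x=\"%s\" y=\"%s\" font-family=\"Helvetica,Arial,sans-serif\" font-size=\"%s\" text-anchor=\"%s\" fill=\"%s\"%s>%s</text>",
          id, cls, px(p$x), px(p$y), px(p$size), p$anchor, p$fill, rot,
          xml_escape(p$text))
      },
      stop("unknown primitive kind: ", p$kind)
    )
    out <- c(out, tag)
  }
  c(out, "</svg>")
}

replay_display <- function(disp) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, disp$width), ylim = c(disp$height, 0))
  graphics::rect(0, disp$height, disp$width, 0, col = "#FFFFFF",
                 border = NA)
  for (p in disp$prims) {
    switch(
      p$kind,
      line = graphics::segments(p$x1, p$y1, p$x2, p$y2, col = p$stroke,
                                lwd = p$width),
      polygon = graphics::polygon(p$x, p$y, col = p$fill,
                                  border = if (identical(p$stroke, "none"))
                                    NA else p$stroke),
      rect = graphics::rect(p$x, p$y + p$h, p$x + p$w, p$y, col = p$fill,
                            border = if (identical(p$stroke, "none"))
                              NA else p$stroke),
      text = graphics::text(p$x, p$y, p$text, cex = p$size / 12,
                            col = p$fill, srt = -p$angle,
                            adj = switch(p$anchor, start = 0, middle = 0.5,
                                         end = 1))
    )
  }
  invisible(NULL)
}

#' Render a figure to SVG, PNG or PDF
#'
#' SVG output is produced by the package's own writer and is byte-stable:
#' rendering the same figure twice yields byte-identical files (sequential
#' element ids, fixed number formatting, no timestamps or creation
#' metadata). PNG and PDF go through the corresponding `grDevices` device,
#' replaying exactly the same display list.
#'
#' @param figure a `track_figure`, `track_composite`, `heatmap_panel` or
#'   `bar_panel`.
#' @param path output file; with `format = "auto"` the format is inferred
#'   from the extension.
#' @param format `"auto"`, `"svg"`, `"png"` or `"pdf"`.
#' @param dpi resolution for PNG output (the figure's natural size is
#'   defined at 96 px/inch).
#' @return invisibly, `path`.
#' @export
render <- function(figure, path, format = c("auto", "svg", "png", "pdf"),
                   dpi = 96) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("svg", "png", "pdf")) {
      stop("cannot infer output format from extension '.", ext,
           "'; pass format = \"svg\", \"png\" or \"pdf\"", call. = FALSE)
    }
    format <- ext
  }
  disp <- build_display(figure)
  if (format == "svg") {
    writeLines(svg_string(disp), path, sep = "\n", useBytes = TRUE)
  } else if (format == "png") {
    grDevices::png(path, width = disp$width / 96 * dpi,
                   height = disp$height / 96 * dpi, res = dpi)
    on.exit(grDevices::dev.off())
    replay_display(disp)
  } else {
    grDevices::pdf(path, width = disp$width / 96,
                   height = disp$height / 96)
    on.exit(grDevices::dev.off())
    replay_display(disp)
  }
  invisible(path)
}

#' @export
plot.track_figure <- function(x, ...) {
  replay_display(build_display(x))
  invisible(x)
}

#' @export
plot.track_composite <- function(x, ...) {
  replay_display(build_display(x))
  invisible(x)
}

#' @export
plot.heatmap_panel <- function(x, ...) {
  replay_display(build_display(x))
  invisible(x)
}

#' @export
plot.bar_panel <- function(x, ...) {
  replay_display(build_display(x))
  invisible(x)
}
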