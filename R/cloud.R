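#' Render a metabolite set name cloud
#'
#' Each set name is drawn with a font size linear in its representation score
#' (so the marker conventions at scores 50 and 75 fall mid-scale), and the
#' top sets — five by default, ties broken by name — are highlighted in red
#' (SVG) or marked with `*` (text). The layout is a deterministic row layout
#' sorted by score, so identical inputs give identical files.
#'
#' @param scores data.frame with columns `set_name` and `score` (as from
#'   [score_collection()]).
#' @param out_path output file path.
#' @param format `"svg"` or `"txt"`.
#' @param highlight_top how many top sets to highlight; default 5.
#' @param min_size,max_size font sizes (px) mapped linearly to scores 0 and
#'   100.
#' @return `out_path`, invisibly.
#' @export
render_cloud <- function(scores, out_path, format = c("svg", "txt"),
                         highlight_top = 5, min_size = 10, max_size = 36) {
  format <- match.arg(format)
  if (!nrow(scores)) stop("need at least one score to render a cloud")
  ord <- order(-scores$score, scores$set_name)
  scores <- scores[ord, , drop = FALSE]
  n_hl <- min(highlight_top, nrow(scores))
  highlighted <- seq_len(nrow(scores)) <= n_hl
  size <- min_size + (max_size - min_size) * pmin(pmax(scores$score, 0), 100) / 100

  if (format == "txt") {
    lines <- sprintf("%s%-50s score=%6.2f size=%4.1f",
                     ifelse(highlighted, "* ", "  "),
                     scores$set_name, scores$score, size)
    writeLines(lines, out_path)
  } else {
    width <- 760
    y <- cumsum(size + 6)
    body <- sprintf(
      paste0('  <text x="10" y="%.1f" font-size="%.1f" fill="%s" ',
             'font-family="sans-serif">%s</text>'),
      y, size, ifelse(highlighted, "#cc0000", "#333333"),
      xml_escape(scores$set_name))
    svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'width="%d" height="%.0f">'),
                     width, max(y) + 10),
             body, "</svg>")
    writeLines(svg, out_path)
  }
  invisible(out_path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
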