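# Scale-exact gene-map rendering and tabular export.
#
# Every track shares a single px-per-kb scale, so gene arrow widths are
# directly comparable across rows: a fusion gene's arrow is exactly as wide
# as its parts combined, which is what makes fusions visible by eye. Genes
# matching the query are stroked bold; uncolored genes are neutral grey.

# 24 maximally distinct fills; ids beyond 24 cycle with shade variation.
.palette24 <- c(
  "#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231", "#911eb4",
  "#46f0f0", "#f032e6", "#bcf60c", "#fabebe", "#008080", "#e6beff",
  "#9a6324", "#fffac8", "#800000", "#aaffc3", "#808000", "#ffd8b1",
  "#000075", "#a9a9a9", "#2f4f4f", "#ff1493", "#00ced1", "#7fff00")

NEUTRAL_FILL <- "#d3d3d3"

#' Fill color for a color id
#'
#' Deterministic palette: 24 distinct base colors, cycling with progressive
#' shade variation beyond 24 components. `NA` maps to neutral grey.
#'
#' @param id Integer color id (>= 1) or `NA`.
#' @return Hex color string.
#' @export
color_fill <- function(id) {
  vapply(id, function(i) {
    if (is.na(i)) return(NEUTRAL_FILL)
    base <- .palette24[(i - 1L) %% 24L + 1L]
    cycle <- (i - 1L) %/% 24L
    if (cycle == 0L) return(base)
    # mix toward white (odd cycles) or black (even cycles)
    towards <- if (cycle %% 2L) 255 else 0
    w <- min(0.25 * ceiling(cycle / 2), 0.75)
    rgb <- grDevices::col2rgb(base)[, 1]
    mixed <- round(rgb * (1 - w) + towards * w)
    grDevices::rgb(mixed[1], mixed[2], mixed[3], maxColorValue = 255)
  }, character(1))
}

# Is this gene the query anchor of its segment (contains the anchor center)?
.is_anchor_gene <- function(seg) {
  g <- seg$genes
  if (!nrow(g) || is.null(seg$anchor)) return(rep(FALSE, nrow(g)))
  ctr <- seg$anchor$center_bp[1]
  L_hint <- max(g$end, seg$window_end)
  hit <- g$start <= ctr & g$end > ctr
  if (seg$wrapped) hit <- hit | (g$start <= ctr + L_hint & g$end > ctr + L_hint)
  hit
}

.arrow_points <- function(x1, x2, y, h, strand, head = 8) {
  head <- min(head, x2 - x1)
  if (strand >= 0) {
    xs <- c(x1, x2 - head, x2 - head, x2, x2 - head, x2 - head, x1)
    ys <- c(y - h / 2, y - h / 2, y - h, y, y + h, y + h / 2, y + h / 2)
  } else {
    xs <- c(x2, x1 + head, x1 + head, x1, x1 + head, x1 + head, x2)
    ys <- c(y - h / 2, y - h / 2, y - h, y, y + h, y + h / 2, y + h / 2)
  }
  list(x = xs, y = ys)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Render a synteny report as SVG
#'
#' One horizontal track per segment, all sharing one global scale
#' (`px_per_kb`); genes are strand-oriented arrows whose width is exactly
#' `(end - start) * px_per_kb / 1000`. The gene hit by the query is stroked
#' bold. Per-gene metadata (locus tag, product, coordinates, normalized
#' score) is embedded as `<title>` elements and `data-` attributes. The
#' not-found genome list is appended below the tracks; a report with no rows
#' renders only that block.
#'
#' @param report A [run_synteny()] result.
#' @param px_per_kb Pixels per kilobase (default 40).
#' @param path Optional output file.
#' @return SVG text, invisibly when written to `path`.
#' @export
render_svg <- function(report, px_per_kb = 40, path = NULL) {
  rows <- report$rows
  margin_x <- 12; row_h <- 64; label_h <- 14; gene_h <- 10
  max_len <- if (length(rows))
    max(vapply(rows, function(s) s$window_len, numeric(1))) else 0
  width <- ceiling(max_len * px_per_kb / 1000 + 2 * margin_x)
  width <- max(width, 640)
  nf_h <- 20 + 14 * (nrow(report$not_found) + 1)
  height <- length(rows) * row_h + nf_h + 20
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
    width, height),
    '<defs></defs>',
    sprintf('<desc>query length %d aa; min normalized score %s; mode %s; window %d bp</desc>',
            report$query_length, format(report$params$min_norm_score),
            report$params$mode, report$params$width))
  for (r in seq_along(rows)) {
    seg <- rows[[r]]
    y0 <- (r - 1) * row_h + 10
    baseline <- y0 + label_h + 22
    clip_id <- sprintf("clip%d", r)
    out <- c(out, sprintf(
      '<clipPath id="%s"><rect x="%g" y="%g" width="%g" height="%g"/></clipPath>',
      clip_id, margin_x, y0, seg$window_len * px_per_kb / 1000, row_h))
    label <- sprintf("%d. %s (%s)%s", seg$rank, .xml_escape(seg$organism),
                     .xml_escape(seg$accession),
                     if (!is.null(seg$anchor))
                       sprintf(" - %.1f%%", seg$anchor$norm_score[1]) else "")
    out <- c(out, sprintf(
      '<text x="%g" y="%g" font-family="Helvetica" font-size="11">%s</text>',
      margin_x, y0 + label_h - 3, label))
    out <- c(out, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#888" stroke-width="1"/>',
      margin_x, baseline, margin_x + seg$window_len * px_per_kb / 1000,
      baseline))
    anchor <- .is_anchor_gene(seg)
    g <- seg$genes
    for (i in seq_len(nrow(g))) {
      x1 <- margin_x + g$display_start[i] * px_per_kb / 1000
      x2 <- margin_x + g$display_end[i] * px_per_kb / 1000
      pts <- .arrow_points(x1, x2, baseline, gene_h, g$strand[i])
      fill <- color_fill(g$color[i])
      stroke_w <- if (anchor[i]) 2.5 else 0.75
      meta <- sprintf("%s | %s | %d..%d (%s) | norm %s",
                      g$locus_tag[i], g$product[i], g$start[i], g$end[i],
                      if (g$strand[i] > 0) "+" else "-",
                      ifelse(is.na(g$norm_vs_ref[i]), "-",
                             sprintf("%.1f%%", g$norm_vs_ref[i])))
      out <- c(out, sprintf(
        paste0('<g clip-path="url(#%s)"><polygon points="%s" fill="%s" ',
               'stroke="black" stroke-width="%g" data-locus-tag="%s" ',
               'data-color="%s" data-start="%d" data-end="%d">',
               '<title>%s</title></polygon></g>'),
        clip_id,
        paste(sprintf("%.3f,%.3f", pts$x, pts$y), collapse = " "),
        fill, stroke_w, .xml_escape(g$locus_tag[i]),
        ifelse(is.na(g$color[i]), "none", g$color[i]),
        g$start[i], g$end[i], .xml_escape(meta)))
    }
  }
  ynf <- length(rows) * row_h + 24
  out <- c(out, sprintf(
    '<text x="%g" y="%g" font-family="Helvetica" font-size="11" font-weight="bold">Synteny not found in %d genome(s):</text>',
    margin_x, ynf, nrow(report$not_found)))
  for (i in seq_len(nrow(report$not_found)))
    out <- c(out, sprintf(
      '<text x="%g" y="%g" font-family="Helvetica" font-size="10">%s (%s)</text>',
      margin_x + 8, ynf + 14 * i,
      .xml_escape(report$not_found$organism[i]),
      .xml_escape(report$not_found$accession[i])))
  out <- c(out, "</svg>")
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
  text
}

# ---- CSV -------------------------------------------------------------------

#' Flatten a synteny report to one row per gene
#'
#' @param report A [run_synteny()] result.
#' @return Data frame with columns `rank`, `accession`, `organism`,
#'   `locus_tag`, `start`, `end`, `strand`, `color`, `norm_score`,
#'   `product`; not-found genomes appended as rows with empty gene fields.
#' @export
report_table <- function(report) {
  rows <- lapply(report$rows, function(seg) {
    g <- seg$genes
    if (!nrow(g))
      return(data.frame(rank = seg$rank, accession = seg$accession,
                        organism = seg$organism, locus_tag = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_integer_, color = NA_integer_,
                        norm_score = NA_real_, product = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(rank = seg$rank, accession = seg$accession,
               organism = seg$organism, locus_tag = g$locus_tag,
               start = g$start, end = g$end, strand = g$strand,
               color = g$color, norm_score = g$norm_vs_ref,
               product = g$product, stringsAsFactors = FALSE)
  })
  nf <- report$not_found
  if (nrow(nf))
    rows[[length(rows) + 1L]] <- data.frame(
      rank = NA_integer_, accession = nf$accession, organism = nf$organism,
      locus_tag = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_integer_, color = NA_integer_, norm_score = NA_real_,
      product = NA_character_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- report_table_empty()
  rownames(out) <- NULL
  out
}

report_table_empty <- function() {
  data.frame(rank = integer(), accession = character(), organism = character(),
             locus_tag = character(), start = integer(), end = integer(),
             strand = integer(), color = integer(), norm_score = numeric(),
             product = character(), stringsAsFactors = FALSE)
}

#' Export a synteny report as CSV
#'
#' Standard quoted CSV of [report_table()]; fields containing commas
#' (typically product strings) are quoted, and the table round-trips through
#' [read_report_csv()].
#'
#' @param report A [run_synteny()] result.
#' @param path Optional output file.
#' @return The CSV text, invisibly when written to `path`.
#' @export
export_csv <- function(report, path = NULL) {
  tab <- report_table(report)
  con <- textConnection("csvtext", "w", local = TRUE)
  utils::write.csv(tab, con, row.names = FALSE, na = "")
  close(con)
  text <- paste0(paste(csvtext, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(csvtext, path)
    return(invisible(text))
  }
  text
}

#' Read back a CSV synteny export
#'
#' @param path CSV file written by [export_csv()].
#' @return Data frame in the [report_table()] layout.
#' @export
read_report_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "",
                         colClasses = c(rank = "integer", start = "integer",
                                        end = "integer", strand = "integer",
                                        color = "integer",
                                        norm_score = "numeric"))
  tab
}

# ---- PDF -------------------------------------------------------------------

#' Render a synteny report as a printable PDF
#'
#' Same layout contract as [render_svg()] (single shared scale, bold query
#' gene, neutral grey for uncolored genes) plus a header carrying the full
#' query sequence and the run parameters. Long reports paginate. Document
#' metadata timestamps are normalized so identical reports are byte-identical.
#'
#' @param report A [run_synteny()] result.
#' @param path Output PDF path.
#' @param rows_per_page Segments per page (default 10).
#' @return `path`, invisibly.
#' @export
render_pdf <- function(report, path, rows_per_page = 10L) {
  rows <- report$rows
  page_w <- 8.27; page_h <- 11.69           # A4 inches
  grDevices::pdf(path, width = page_w, height = page_h, onefile = TRUE,
                 compress = FALSE, useDingbats = FALSE, title = "synteny map")
  on.exit(try(grDevices::dev.off(), silent = TRUE), add = TRUE)
  margin <- 0.6
  max_len <- if (length(rows))
    max(vapply(rows, function(s) s$window_len, numeric(1))) else 15000
  in_per_bp <- (page_w - 2 * margin) / max_len

  grid::grid.newpage()
  y <- page_h - margin
  put <- function(txt, size = 9, bold = FALSE, x = margin, yy = y) {
    grid::grid.text(txt, x = grid::unit(x, "in"), y = grid::unit(yy, "in"),
                    just = c("left", "top"),
                    gp = grid::gpar(fontsize = size,
                                    fontface = if (bold) "bold" else "plain",
                                    fontfamily = "mono"))
  }
  put("Synteny report", 14, bold = TRUE); y <- y - 0.3
  put(sprintf("min normalized score: %s%%   mode: %s   window: %d bp   gaps: %d/%d",
              format(report$params$min_norm_score), report$params$mode,
              report$params$width, report$params$gap_open,
              report$params$gap_extend)); y <- y - 0.25
  put(sprintf("query (%d aa):", report$query_length)); y <- y - 0.2
  qlines <- substring(report$query, seq(1, nchar(report$query), 60),
                      pmin(seq(1, nchar(report$query), 60) + 59,
                           nchar(report$query)))
  for (ql in qlines) { put(ql, 8); y <- y - 0.16 }
  y <- y - 0.2

  row_h <- 0.9
  draw_row <- function(seg, y_top) {
    put(sprintf("%d. %s (%s)", seg$rank, seg$organism, seg$accession),
        9, yy = y_top)
    baseline <- y_top - 0.45
    grid::grid.lines(x = grid::unit(c(margin, margin +
                                        seg$window_len * in_per_bp), "in"),
                     y = grid::unit(c(baseline, baseline), "in"),
                     gp = grid::gpar(col = "grey50"))
    anchor <- .is_anchor_gene(seg)
    g <- seg$genes
    for (i in seq_len(nrow(g))) {
      x1 <- margin + max(0, g$display_start[i]) * in_per_bp
      x2 <- margin + min(seg$window_len, g$display_end[i]) * in_per_bp
      if (x2 <= x1) next
      pts <- .arrow_points(x1, x2, baseline, 0.09, g$strand[i], head = 0.08)
      grid::grid.polygon(x = grid::unit(pts$x, "in"),
                         y = grid::unit(pts$y, "in"),
                         gp = grid::gpar(fill = color_fill(g$color[i]),
                                         col = "black",
                                         lwd = if (anchor[i]) 2.4 else 0.6))
    }
  }
  n_on_page <- 0L
  for (r in seq_along(rows)) {
    if (y - row_h < margin || n_on_page >= rows_per_page) {
      grid::grid.newpage(); y <- page_h - margin; n_on_page <- 0L
    }
    draw_row(rows[[r]], y)
    y <- y - row_h; n_on_page <- n_on_page + 1L
  }
  if (y - 0.3 * (nrow(report$not_found) + 2) < margin) {
    grid::grid.newpage(); y <- page_h - margin
  }
  put(sprintf("Synteny not found in %d genome(s):", nrow(report$not_found)),
      10, bold = TRUE); y <- y - 0.22
  for (i in seq_len(nrow(report$not_found))) {
    put(sprintf("  %s (%s)", report$not_found$organism[i],
                report$not_found$accession[i]), 9)
    y <- y - 0.18
    if (y < margin) { grid::grid.newpage(); y <- page_h - margin }
  }
  grDevices::dev.off()
  on.exit(NULL)
  .normalize_pdf_metadata(path)
  invisible(path)
}

# Fix the volatile /CreationDate and /ModDate entries so identical reports
# produce byte-identical files.
.normalize_pdf_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("/CreationDate \\(D:[^)]*\\)", "/CreationDate (D:20000101000000)",
               lines, useBytes = TRUE)
  lines <- sub("/ModDate \\(D:[^)]*\\)", "/ModDate (D:20000101000000)", lines,
               useBytes = TRUE)
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}
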