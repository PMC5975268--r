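#' Tab-separated export of an enumeration
#'
#' Serializes every enumerated triple (both labelings) with enough fields
#' to reconstruct it exactly. Columns: `direction`, `origin`, `labeling`,
#' `F` and `S` (comma-joined gene sets), `window` (comma-joined, in
#' origin-representative order), `window_size`, `conserved_pass`,
#' `intergenic_pass` (semicolon-joined per-constraint verdicts, `NA` when
#' no constraints were annotated), `is_min_dup`.
#'
#' @param x A `tdrl_enumeration`.
#' @param path Optional output file; when `NULL` the TSV is returned as a
#'   single string. Output is byte-deterministic for identical inputs.
#' @param direction Label written to the `direction` column (default
#'   `"source_to_target"`).
#' @return The TSV as one string, invisibly when written to `path`.
#' @export
format_tdrl_tsv <- function(x, path = NULL, direction = "source_to_target") {
  if (!inherits(x, "tdrl_enumeration")) {
    stop("`x` must be a tdrl_enumeration", call. = FALSE)
  }
  tab <- x$tdrls
  join <- function(col) vapply(col, paste, character(1), collapse = ",")
  cells <- cbind(
    direction = rep(direction, nrow(tab)),
    origin = tab$origin,
    labeling = tab$labeling,
    F = join(tab$first_copy),
    S = join(tab$second_copy),
    window = join(tab$window),
    window_size = as.character(tab$window_size),
    conserved_pass = if ("conserved_detail" %in% names(tab)) tab$conserved_detail else rep(NA_character_, nrow(tab)),
    intergenic_pass = if ("intergenic_detail" %in% names(tab)) tab$intergenic_detail else rep(NA_character_, nrow(tab)),
    is_min_dup = as.character(tab$is_min_dup)
  )
  lines <- c(
    paste(colnames(cells), collapse = "\t"),
    apply(cells, 1L, paste, collapse = "\t")
  )
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

# rows shown in matrix renderings: the smaller-window labeling per origin,
# origins ordered along the reference rotation of the source
display_rows <- function(x, reference = NULL) {
  if (x$case != "single-tdrl") {
    stop("matrix rendering applies to the single-TDRL case only; ",
         "for equal orders use glance() for the identity-triple count",
         call. = FALSE)
  }
  genes <- if (is.null(reference)) x$source$genes else representative(x$source, reference)
  tab <- dplyr::filter(x$tdrls, .data$displayed)
  tab <- tab[order(match(tab$origin, genes)), , drop = FALSE]
  for (col in c("conserved_pass", "intergenic_pass")) {
    if (!col %in% names(tab)) tab[[col]] <- rep(NA, nrow(tab))
  }
  list(genes = genes, rows = tab)
}

#' Plain-text matrix of equivalent TDRLs
#'
#' One row per origin (its smaller-window labeling), one column per gene of
#' the source order: `o` marks a gene kept in the first copy (`F`), `x` a
#' gene kept in the second copy (`S`), and `[ ]` brackets the genes of the
#' minimal partial-duplication window. When constraints have been annotated
#' a marker column is appended: `*` for a TDRL that keeps every conserved
#' group intact, `i` for one that explains every intergenic pair, `d` for a
#' minimum-duplication TDRL.
#'
#' @param x A `tdrl_enumeration` (single-TDRL case).
#' @param reference Optional gene anchoring the column order (columns read
#'   from this gene along the source); defaults to the canonical rotation.
#' @param markers Show the marker column; the default `NA` (auto) shows it
#'   only when constraints have been annotated with
#'   [annotate_constraints()].
#' @return Character vector of lines; rendering is deterministic.
#' @export
render_matrix_text <- function(x, reference = NULL, markers = NA) {
  d <- display_rows(x, reference)
  genes <- d$genes
  tab <- d$rows
  width <- max(nchar(genes))
  pad <- function(s) formatC(s, width = width + 2L, flag = "-")
  origin_w <- max(nchar("origin"), max(nchar(tab$origin)))
  header <- paste0(
    formatC("origin", width = origin_w, flag = "-"), " | ",
    paste(vapply(genes, pad, character(1)), collapse = "")
  )
  has_markers <- if (is.na(markers)) {
    any(c("conserved_pass", "intergenic_pass") %in% names(x$tdrls))
  } else {
    isTRUE(markers)
  }
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    f <- tab$first_copy[[i]]
    w <- tab$window[[i]]
    cell <- vapply(genes, function(g) {
      glyph <- if (g %in% f) "o" else "x"
      if (g %in% w) paste0("[", glyph, "]") else paste0(" ", glyph, " ")
    }, character(1))
    cell <- vapply(cell, function(s) formatC(s, width = width + 2L, flag = "-"),
                   character(1))
    marks <- if (has_markers) c(
      if (isTRUE(tab$conserved_pass[i])) "*",
      if (isTRUE(tab$intergenic_pass[i])) "i",
      if (isTRUE(tab$is_min_dup[i])) "d"
    ) else character(0)
    paste0(
      formatC(tab$origin[i], width = origin_w, flag = "-"), " | ",
      paste(cell, collapse = ""),
      if (has_markers) paste0(" ", paste(marks, collapse = ""))
    )
  }, character(1))
  c(header, lines)
}

#' SVG matrix of equivalent TDRLs
#'
#' Renders the enumeration in the classic matrix style: one row per origin,
#' one column per gene; a white circle marks a gene kept in the first copy
#' (`F`), a black circle one kept in the second copy (`S`), and a square
#' outlines each gene belonging to the minimal partial-duplication window.
#' Star / diamond / small-circle glyphs to the right of a row mark
#' conserved-group passing, minimum duplication, and intergenic-pair
#' passing TDRLs. The SVG markup is assembled as plain text so identical
#' inputs yield byte-identical documents.
#'
#' @inheritParams render_matrix_text
#' @param path Optional file to write the SVG document to.
#' @param cell Cell size in pixels (default 24).
#' @return The SVG document as a single string (invisibly when written).
#' @export
render_matrix_svg <- function(x, path = NULL, reference = NULL, cell = 24,
                              markers = NA) {
  d <- display_rows(x, reference)
  genes <- d$genes
  tab <- d$rows
  n <- length(genes)
  m <- nrow(tab)
  left <- 12 * max(nchar(tab$origin)) + 16
  top <- 12 * max(nchar(genes)) + 16
  width <- left + n * cell + 3 * cell
  height <- top + m * cell + cell
  el <- character(0)
  add <- function(...) el[[length(el) + 1L]] <<- paste0(...)
  num <- function(v) formatC(v, format = "fg", digits = 10)
  for (j in seq_len(n)) {
    add('<text x="', num(left + (j - 0.5) * cell), '" y="', num(top - 8),
        '" text-anchor="start" font-size="11" font-family="monospace" ',
        'transform="rotate(-60 ', num(left + (j - 0.5) * cell), " ",
        num(top - 8), ')">', genes[j], "</text>")
  }
  for (i in seq_len(m)) {
    cy <- top + (i - 0.5) * cell
    add('<text x="', num(left - 8), '" y="', num(cy + 4),
        '" text-anchor="end" font-size="11" font-family="monospace">',
        tab$origin[i], "</text>")
    f <- tab$first_copy[[i]]
    w <- tab$window[[i]]
    for (j in seq_len(n)) {
      cx <- left + (j - 0.5) * cell
      if (genes[j] %in% w) {
        add('<rect x="', num(cx - cell * 0.42), '" y="', num(cy - cell * 0.42),
            '" width="', num(cell * 0.84), '" height="', num(cell * 0.84),
            '" fill="none" stroke="black" stroke-width="1"/>')
      }
      fill <- if (genes[j] %in% f) "white" else "black"
      add('<circle cx="', num(cx), '" cy="', num(cy), '" r="', num(cell * 0.3),
          '" fill="', fill, '" stroke="black" stroke-width="1"/>')
    }
    show_marks <- if (is.na(markers)) {
      any(c("conserved_pass", "intergenic_pass") %in% names(x$tdrls))
    } else {
      isTRUE(markers)
    }
    marks <- if (show_marks) c(
      if (isTRUE(tab$conserved_pass[i])) "★",
      if (isTRUE(tab$is_min_dup[i])) "◆",
      if (isTRUE(tab$intergenic_pass[i])) "○"
    ) else character(0)
    if (length(marks) > 0L) {
      add('<text x="', num(left + n * cell + 0.5 * cell), '" y="', num(cy + 4),
          '" text-anchor="start" font-size="12">',
          paste(marks, collapse = " "), "</text>")
    }
  }
  doc <- paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="', num(width),
    '" height="', num(height), '" viewBox="0 0 ', num(width), " ",
    num(height), '">\n<rect width="100%" height="100%" fill="white"/>\n',
    paste(el, collapse = "\n"),
    "\n</svg>\n"
  )
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

#' ggplot2 matrix of equivalent TDRLs
#'
#' The same matrix as [render_matrix_svg()] as a ggplot: white/black points
#' for first-/second-copy membership and an outlined tile over the minimal
#' duplication window of each displayed labeling.
#'
#' @param object A `tdrl_enumeration` (single-TDRL case).
#' @param reference Optional gene anchoring the column order.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tdrl_enumeration
#' @export
autoplot.tdrl_enumeration <- function(object, reference = NULL, ...) {
  d <- display_rows(object, reference)
  genes <- d$genes
  tab <- d$rows
  cells <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    tibble::tibble(
      origin = tab$origin[i],
      gene = genes,
      copy = ifelse(genes %in% tab$first_copy[[i]], "first (F)", "second (S)"),
      in_window = genes %in% tab$window[[i]]
    )
  })
  cells$gene <- factor(cells$gene, levels = genes)
  cells$origin <- factor(cells$origin, levels = rev(tab$origin))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$gene, y = .data$origin)) +
    ggplot2::geom_tile(
      data = dplyr::filter(cells, .data$in_window),
      fill = NA, colour = "black", linewidth = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$copy),
                        shape = 21, size = 3, colour = "black") +
    ggplot2::scale_fill_manual(values = c("first (F)" = "white",
                                          "second (S)" = "black")) +
    ggplot2::labs(x = "gene", y = "origin p", fill = "kept in copy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
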