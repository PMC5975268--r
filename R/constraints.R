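#' Conserved-group condition on a TDRL
#'
#' A conserved gene group `G` models a run of genes (for example a shared
#' transcript) that must not be broken by the rearrangement: the TDRL must
#' lose all genes of `G` from the same copy of the duplicated intermediate,
#' i.e. `G` must be entirely contained in `F` or entirely in `S`. A
#' singleton group always passes.
#'
#' @param t A [tdrl()] triple.
#' @param groups List of character vectors (gene sets); element names, if
#'   any, label the groups in the returned detail.
#' @return Logical: `TRUE` iff every group is contained in one copy set.
#'   Attribute `"violating"` lists the labels of failing groups.
#' @examples
#' passes_conserved_groups(
#'   tdrl(c(1, 3, 5, 7, 8), c(2, 4, 6), 2),
#'   list(c("1", "2"), c("7", "8"))
#' )
#' @export
passes_conserved_groups <- function(t, groups) {
  if (!is_tdrl(t)) stop("`t` must be a tdrl object", call. = FALSE)
  groups <- normalize_groups(groups, tdrl_genes(t))
  ok <- vapply(
    groups,
    function(g) all(g %in% t$first) || all(g %in% t$second),
    logical(1)
  )
  structure(all(ok), violating = names(groups)[!ok])
}

normalize_groups <- function(groups, universe) {
  if (is.character(groups)) groups <- list(groups)
  groups <- lapply(groups, as.character)
  unknown <- setdiff(unique(unlist(groups)), universe)
  if (length(unknown) > 0L) {
    stop("unknown gene in conserved group: ",
         paste(sort_labels(unknown), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    lab <- vapply(groups, function(g) paste(g, collapse = "+"), character(1))
    nm <- names(groups)
    if (is.null(nm)) nm <- rep("", length(groups))
    names(groups) <- ifelse(nm == "", lab, nm)
  }
  groups
}

#' Intergenic-region condition on a TDRL
#'
#' Tests whether a TDRL can explain an intergenic region observed between
#' genes `x` and `y` in the rearranged genome as the remnant of an
#' incompletely deleted gene. Positions are taken in the source
#' representative starting at the TDRL's origin. If `x` and `y` survive in
#' different copies (one in `F`, one in `S`), any gene lying strictly
#' between their positions has a lost copy between them, so the condition
#' holds iff the positional interval is non-empty. If both survive in the
#' same copy, a gene of the opposite set must lie strictly between them.
#' The unordered positional interval is used throughout, consistent with
#' treating the origin representative as the reading frame of the
#' duplication.
#'
#' @param t A [tdrl()] triple.
#' @param source The `circular_order` the TDRL is applied to.
#' @param x,y Distinct gene labels framing the intergenic region (in the
#'   target genome).
#' @return Logical; attribute `"witness"` carries a gene whose lost copy
#'   can explain the region (`NA` if none).
#' @examples
#' passes_intergenic_pair(
#'   tdrl(c(1, 3, 5, 7, 8), c(2, 4, 6), 2),
#'   circular_order(1:8), "1", "2"
#' )
#' @export
passes_intergenic_pair <- function(t, source, x, y) {
  if (!is_tdrl(t)) stop("`t` must be a tdrl object", call. = FALSE)
  stopifnot_order(source, "source")
  x <- as.character(x)
  y <- as.character(y)
  unknown <- setdiff(c(x, y), source$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene in intergenic pair: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (identical(x, y)) stop("`x` and `y` must be distinct genes", call. = FALSE)
  rep_p <- representative(source, t$origin)
  px <- match(x, rep_p)
  py <- match(y, rep_p)
  lo <- min(px, py)
  hi <- max(px, py)
  between <- if (hi - lo >= 2L) rep_p[(lo + 1L):(hi - 1L)] else character(0)
  same_first <- all(c(x, y) %in% t$first)
  same_second <- all(c(x, y) %in% t$second)
  if (same_first || same_second) {
    opposite <- if (same_first) t$second else t$first
    z <- between[between %in% opposite]
  } else {
    # x and y survive in different copies: every in-between gene has a lost
    # copy between them in the duplicated intermediate
    z <- between
  }
  structure(length(z) > 0L,
            witness = if (length(z) > 0L) z[[1L]] else NA_character_)
}

#' Annotate an enumeration with constraint verdicts
#'
#' Adds per-triple pass/fail columns for conserved gene groups and
#' intergenic gene pairs to the tibble of a `tdrl_enumeration`. Both
#' verdicts are stable under F/S relabeling, so the two rows of each origin
#' always agree.
#'
#' @param x A `tdrl_enumeration` (single-TDRL case).
#' @param conserved Optional list of character vectors: gene groups that
#'   must survive in one copy (see [passes_conserved_groups()]).
#' @param intergenic Optional intergenic pairs: a two-column data frame /
#'   matrix or a list of length-2 vectors `c(x, y)`, each framing an
#'   intergenic region in the target. A warning is emitted when `x` and `y`
#'   are not adjacent in the target (the region they frame would then
#'   contain genes, not just a remnant), but the condition is still
#'   evaluated.
#' @return `x` with columns added to `tidy(x)`: `conserved_pass`,
#'   `conserved_detail` (semicolon-joined per-group verdicts),
#'   `intergenic_pass`, `intergenic_detail` (per-pair verdicts with witness
#'   gene), `passes_all`.
#' @export
annotate_constraints <- function(x, conserved = NULL, intergenic = NULL) {
  if (!inherits(x, "tdrl_enumeration")) {
    stop("`x` must be a tdrl_enumeration", call. = FALSE)
  }
  tab <- x$tdrls
  triples <- purrr::pmap(
    list(tab$first_copy, tab$second_copy, tab$origin),
    function(f, s, p) tdrl(f, s, p)
  )
  if (!is.null(conserved)) {
    conserved <- normalize_groups(conserved, x$source$genes)
    verdicts <- lapply(triples, passes_conserved_groups, groups = conserved)
    tab$conserved_pass <- vapply(verdicts, isTRUE, logical(1))
    tab$conserved_detail <- vapply(verdicts, function(v) {
      bad <- attr(v, "violating")
      paste(vapply(names(conserved), function(g) {
        paste0(g, ":", if (g %in% bad) "fail" else "pass")
      }, character(1)), collapse = ";")
    }, character(1))
  }
  if (!is.null(intergenic)) {
    pairs <- normalize_pairs(intergenic, x$source$genes)
    succ_t <- stats::setNames(rotate_genes(x$target$genes, 1L), x$target$genes)
    for (i in seq_len(nrow(pairs))) {
      xg <- pairs$x[[i]]; yg <- pairs$y[[i]]
      if (!identical(succ_t[[xg]], yg) && !identical(succ_t[[yg]], xg)) {
        warning("genes ", xg, " and ", yg,
                " are not adjacent in the target order; they do not frame ",
                "a single intergenic region", call. = FALSE)
      }
    }
    verdicts <- lapply(triples, function(t) {
      lapply(seq_len(nrow(pairs)), function(i) {
        passes_intergenic_pair(t, x$source, pairs$x[[i]], pairs$y[[i]])
      })
    })
    tab$intergenic_pass <- vapply(verdicts, function(v) all(vapply(v, isTRUE, logical(1))), logical(1))
    tab$intergenic_detail <- vapply(verdicts, function(v) {
      paste(vapply(seq_len(nrow(pairs)), function(i) {
        w <- attr(v[[i]], "witness")
        paste0(pairs$x[[i]], "-", pairs$y[[i]], ":",
               if (isTRUE(v[[i]])) paste0("pass(z=", w, ")") else "fail")
      }, character(1)), collapse = ";")
    }, character(1))
  }
  tab$passes_all <-
    (if (is.null(conserved)) TRUE else tab$conserved_pass) &
    (if (is.null(intergenic)) TRUE else tab$intergenic_pass)
  x$tdrls <- tab
  x$conserved <- conserved
  x$intergenic <- if (is.null(intergenic)) NULL else normalize_pairs(intergenic, x$source$genes)
  x
}

normalize_pairs <- function(pairs, universe) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- tibble::tibble(x = as.character(pairs[[1L]]),
                            y = as.character(pairs[[2L]]))
  } else {
    if (is.character(pairs)) pairs <- list(pairs)
    stopifnot(all(lengths(pairs) == 2L))
    pairs <- tibble::tibble(
      x = vapply(pairs, function(p) as.character(p)[[1L]], character(1)),
      y = vapply(pairs, function(p) as.character(p)[[2L]], character(1))
    )
  }
  unknown <- setdiff(c(pairs$x, pairs$y), universe)
  if (length(unknown) > 0L) {
    stop("unknown gene in intergenic pair: ",
         paste(sort_labels(unique(unknown)), collapse = ", "), call. = FALSE)
  }
  pairs
}

#' Read conserved gene groups from a text file
#'
#' One group per line: whitespace-separated gene names; `#` starts a
#' comment; blank lines are ignored.
#'
#' @param path File path.
#' @return List of character vectors.
#' @export
read_conserved_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  lapply(strsplit(lines, "\\s+"), as.character)
}

#' Read intergenic gene pairs from a text file
#'
#' Two gene names per line (whitespace-separated), ordered in the reading
#' direction of the target genome; `#` comments and blank lines allowed.
#'
#' @param path File path.
#' @return Tibble with columns `x`, `y`.
#' @export
read_intergenic_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 2L)) {
    stop("each line must contain exactly two gene names", call. = FALSE)
  }
  tibble::tibble(
    x = vapply(fields, `[[`, character(1), 1L),
    y = vapply(fields, `[[`, character(1), 2L)
  )
}
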