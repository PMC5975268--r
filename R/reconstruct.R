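#' Single-TDRL images of an order with prescribed conserved segments
#'
#' Searches for every circular order that (i) lies exactly one TDRL away
#' from `source` and (ii) whose maximal conserved segments with `source`
#' are exactly the given multi-gene segments (all other genes being
#' singletons). Useful to reconstruct a derived gene order when only the
#' ancestral order and the shared conserved blocks are known.
#'
#' The search is exhaustive over block-respecting TDRLs: the source is
#' decomposed into the given segments plus singleton blocks, and every
#' block rotation combined with every bipartition of the blocks into the
#' two copies is applied. This covers all candidate targets, because any
#' single TDRL whose image keeps every segment contiguous must cut between
#' blocks: within a block the copy assignment cannot change without
#' separating the block's genes in the image.
#'
#' @param source A `circular_order`.
#' @param segments List of character vectors: the prescribed maximal
#'   conserved runs (each must be contiguous in `source`, in reading
#'   direction, and they must not overlap).
#' @param max_blocks Guard on the number of blocks (default 16; the search
#'   scales as `blocks * 2^blocks`).
#' @return List of `circular_order` objects, one per matching rotation
#'   class (possibly empty; length one means the derived order is uniquely
#'   determined).
#' @export
reconstruct_targets <- function(source, segments, max_blocks = 16L) {
  stopifnot_order(source, "source")
  segments <- lapply(segments, as.character)
  unknown <- setdiff(unlist(segments), source$genes)
  if (length(unknown) > 0L) {
    stop("unknown gene in segment: ",
         paste(sort_labels(unknown), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(unlist(segments))) {
    stop("segments must not overlap", call. = FALSE)
  }
  n <- source$n
  # decompose the source into blocks, starting at a segment boundary
  anchor <- if (length(segments) > 0L) segments[[1L]][1L] else source$genes[1L]
  rep0 <- representative(source, anchor)
  blocks <- list()
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (s in segments) {
      if (length(s) <= n - i + 1L &&
          identical(rep0[i:(i + length(s) - 1L)], s)) {
        hit <- s
        break
      }
    }
    if (is.null(hit)) hit <- rep0[i]
    blocks[[length(blocks) + 1L]] <- hit
    i <- i + length(hit)
  }
  placed <- vapply(segments, function(s) {
    any(vapply(blocks, identical, logical(1), s))
  }, logical(1))
  if (!all(placed)) {
    stop("segment not contiguous in the source order: ",
         paste(vapply(segments[!placed], paste, character(1), collapse = " "),
               collapse = "; "), call. = FALSE)
  }
  nb <- length(blocks)
  if (nb > max_blocks) {
    stop(nb, " blocks exceed max_blocks = ", max_blocks, call. = FALSE)
  }
  # expected shared-adjacency pattern: exactly the within-segment adjacencies
  succ_src <- stats::setNames(rotate_genes(rep0, 1L), rep0)
  expected <- stats::setNames(logical(n), rep0)
  for (s in segments) {
    if (length(s) > 1L) expected[s[-length(s)]] <- TRUE
  }
  masks <- subset_mask_matrix(nb)
  hits <- character(0)
  found <- list()
  doubled <- c(blocks, blocks)
  for (r in seq_len(nb) - 1L) {
    rot <- doubled[(r + 1L):(r + nb)]
    for (m in seq_len(nrow(masks))) {
      f <- masks[m, ]
      tgt <- c(unlist(rot[f], use.names = FALSE),
               unlist(rot[!f], use.names = FALSE))
      succ_tgt <- stats::setNames(rotate_genes(tgt, 1L), tgt)
      if (identical(unname(succ_src == succ_tgt[rep0]), unname(expected))) {
        ord <- circular_order(tgt)
        key <- paste(ord$genes, collapse = "\r")
        if (!key %in% hits) {
          hits <- c(hits, key)
          found[[length(found) + 1L]] <- ord
        }
      }
    }
  }
  found
}
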