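#' Tandem duplication random loss (TDRL) rearrangements
#'
#' A TDRL tandem-duplicates the genome starting at an origin gene `p` and
#' then loses exactly one copy of every duplicated gene. It is written as a
#' triple `(F, S, p)`: `F` is the set of genes kept in the first copy of the
#' duplicated intermediate, `S` the set kept in the second copy, and
#' `(F, S)` is a bipartition of the gene set. Applying the triple to a
#' circular order moves the `F`-genes (in their current relative order) in
#' front of the `S`-genes (in their current relative order), read from the
#' linearization that starts at `p`. Interchanging `F` and `S` yields the
#' same resulting circular order.
#'
#' `F` or `S` may be empty: such triples are identity maps and are needed to
#' represent the full equivalence class of a no-op rearrangement.
#'
#' @param first_copy Character vector: genes kept in the first copy (`F`).
#' @param second_copy Character vector: genes kept in the second copy (`S`).
#' @param origin Gene label at which the duplication starts (`p`); must be a
#'   member of `first_copy` or `second_copy`.
#' @return An object of class `tdrl` with fields `first`, `second` (each
#'   sorted by label for deterministic display) and `origin`.
#' @examples
#' tdrl(c("4", "5"), c("1", "2", "3"), "1")
#' @export
tdrl <- function(first_copy, second_copy, origin) {
  first_copy <- as.character(first_copy)
  second_copy <- as.character(second_copy)
  origin <- as.character(origin)
  if (length(origin) != 1L || is.na(origin)) {
    stop("`origin` must be a single gene label", call. = FALSE)
  }
  overlap <- intersect(first_copy, second_copy)
  if (length(overlap) > 0L) {
    stop("F and S must be disjoint; shared: ",
         paste(sort_labels(overlap), collapse = ", "), call. = FALSE)
  }
  universe <- c(first_copy, second_copy)
  if (anyDuplicated(universe)) {
    stop("duplicate genes within F or S", call. = FALSE)
  }
  if (!origin %in% universe) {
    stop("origin ", origin, " is not a member of F or S", call. = FALSE)
  }
  structure(
    list(
      first = sort_labels(first_copy),
      second = sort_labels(second_copy),
      origin = origin
    ),
    class = "tdrl"
  )
}

#' @export
print.tdrl <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.tdrl <- function(x, ...) {
  paste0(
    "({", paste(x$first, collapse = ","), "},{",
    paste(x$second, collapse = ","), "},", x$origin, ")"
  )
}

is_tdrl <- function(x) inherits(x, "tdrl")

tdrl_genes <- function(t) c(t$first, t$second)

# canonical key identifying a labeled triple (F, S, p)
tdrl_key <- function(t) {
  paste0(t$origin, "|", paste(t$first, collapse = ","), "|",
         paste(t$second, collapse = ","))
}

check_tdrl_order <- function(t, order) {
  if (!is_tdrl(t)) stop("`t` must be a tdrl object", call. = FALSE)
  stopifnot_order(order)
  check_same_gene_set(tdrl_genes(t), order$genes)
  invisible(TRUE)
}

#' Apply a TDRL to a circular gene order
#'
#' @param t A [tdrl()] triple over the same gene set as `order`.
#' @param order A [circular_order()].
#' @return The resulting `circular_order`: reading the representative that
#'   starts at the origin, all `F`-genes (relative order preserved) followed
#'   by all `S`-genes (relative order preserved).
#' @examples
#' apply_tdrl(tdrl(c(4, 5), c(1, 2, 3), 1), circular_order(c(1, 4, 2, 5, 3)))
#' @export
apply_tdrl <- function(t, order) {
  check_tdrl_order(t, order)
  rep_p <- representative(order, t$origin)
  circular_order(c(rep_p[rep_p %in% t$first], rep_p[rep_p %in% t$second]))
}

#' Interchange the F and S labeling of a TDRL
#'
#' `(F, S, p)` and `(S, F, p)` act identically on every circular order; the
#' swap only changes which copy of the duplicated intermediate each gene is
#' said to survive in.
#'
#' @param t A [tdrl()] triple.
#' @return The triple `(S, F, p)`.
#' @export
swap_labeling <- function(t) {
  if (!is_tdrl(t)) stop("`t` must be a tdrl object", call. = FALSE)
  tdrl(t$second, t$first, t$origin)
}

#' Is a TDRL an identity map on a given order?
#'
#' @inheritParams apply_tdrl
#' @return `TRUE` iff applying `t` to `order` returns the same circular
#'   order.
#' @export
is_identity_tdrl <- function(t, order) {
  circular_equal(apply_tdrl(t, order), order)
}

#' The tandem-duplicated intermediate of a TDRL
#'
#' Materializes the `2n`-occurrence intermediate state: two tandem copies of
#' the representative starting at the origin, with each occurrence marked as
#' kept (it survives the loss phase) or lost. A gene is kept in copy 1 iff
#' it belongs to `F`, in copy 2 iff it belongs to `S`; every gene is kept
#' exactly once and lost exactly once. Reading the kept occurrences in order
#' spells a representative of the rearranged circular order.
#'
#' @inheritParams apply_tdrl
#' @return A tibble with `2n` rows: `position` (1..2n), `gene`, `copy`
#'   (1 or 2), `kept` (logical).
#' @export
duplicated_intermediate <- function(t, order) {
  check_tdrl_order(t, order)
  rep_p <- representative(order, t$origin)
  n <- order$n
  tibble::tibble(
    position = seq_len(2L * n),
    gene = c(rep_p, rep_p),
    copy = rep(1:2, each = n),
    kept = c(rep_p %in% t$first, rep_p %in% t$second)
  )
}

#' Minimal partial-duplication form of a TDRL
#'
#' Every whole-genome TDRL is equivalent to a partial-duplication TDRL that
#' duplicates only a contiguous window `W` of the representative starting at
#' the origin: genes before the window are untouched members of `F`, genes
#' after it untouched members of `S`, and only the window genes are
#' duplicated (window genes of `F` survive in the first window copy, window
#' genes of `S` in the second). The minimal such window runs from the first
#' `S`-gene to the last `F`-gene of the representative; it is empty exactly
#' when the TDRL is an identity map.
#'
#' @inheritParams apply_tdrl
#' @return An object of class `partial_tdrl`: list with `window` (genes of
#'   `W` in representative order), `kept_first` (`F` within the window, in
#'   window order), `kept_second` (`S` within the window), `non_duplicated`
#'   (genes outside the window), `origin`, and `representative`.
#' @examples
#' minimal_partial(tdrl(c(4, 6), c(1, 2, 3, 5, 7, 8), 3), circular_order(1:8))
#' @export
minimal_partial <- function(t, order) {
  check_tdrl_order(t, order)
  rep_p <- representative(order, t$origin)
  in_first <- rep_p %in% t$first
  in_second <- rep_p %in% t$second
  first_s <- if (any(in_second)) min(which(in_second)) else NA_integer_
  last_f <- if (any(in_first)) max(which(in_first)) else NA_integer_
  if (is.na(first_s) || is.na(last_f) || last_f < first_s) {
    window_idx <- integer(0)
  } else {
    window_idx <- first_s:last_f
  }
  window <- rep_p[window_idx]
  structure(
    list(
      window = window,
      kept_first = window[window %in% t$first],
      kept_second = window[window %in% t$second],
      non_duplicated = rep_p[setdiff(seq_along(rep_p), window_idx)],
      origin = t$origin,
      representative = rep_p
    ),
    class = "partial_tdrl"
  )
}

#' @export
print.partial_tdrl <- function(x, ...) {
  cat("<partial TDRL, origin ", x$origin, ">\n", sep = "")
  cat("  window W  : (", paste(x$window, collapse = " "), ")  [",
      length(x$window), " of ", length(x$representative), " genes duplicated]\n",
      sep = "")
  cat("  F' (copy1): {", paste(x$kept_first, collapse = ","), "}\n", sep = "")
  cat("  S' (copy2): {", paste(x$kept_second, collapse = ","), "}\n", sep = "")
  cat("  N (not duplicated): {", paste(x$non_duplicated, collapse = ","), "}\n",
      sep = "")
  invisible(x)
}

#' Whole-genome TDRL corresponding to a partial duplication
#'
#' Converts a partial-duplication TDRL `(W, F', S', N)` into the equivalent
#' whole-genome triple `(F, S, p)` with `F = S'`, `S = N` together with
#' `F'`, and origin the gene immediately following the window in the
#' circular reading.
#'
#' @param partial A `partial_tdrl` (see [minimal_partial()]) with a
#'   non-empty window.
#' @return The equivalent whole-genome [tdrl()] triple.
#' @export
partial_to_whole <- function(partial) {
  if (!inherits(partial, "partial_tdrl")) {
    stop("`partial` must be a partial_tdrl object", call. = FALSE)
  }
  if (length(partial$window) == 0L) {
    stop("the partial TDRL has an empty window (identity map); ",
         "no rearranging whole-genome counterpart exists", call. = FALSE)
  }
  rep_p <- partial$representative
  last_w <- match(partial$window[length(partial$window)], rep_p)
  origin <- rep_p[(last_w %% length(rep_p)) + 1L]
  tdrl(
    first_copy = partial$kept_second,
    second_copy = c(partial$non_duplicated, partial$kept_first),
    origin = origin
  )
}

# Exhaustive oracle for the minimal-window property: smallest contiguous
# (non-wrapping) window of the origin representative whose partial
# duplication under t's own F/S split reproduces apply_tdrl(t, order).
# Quadratic in n with an O(n) check per window; intended for small n.
window_size_oracle <- function(t, order) {
  check_tdrl_order(t, order)
  target <- apply_tdrl(t, order)
  rep_p <- representative(order, t$origin)
  n <- order$n
  if (circular_equal(order, target)) {
    return(0L)
  }
  for (size in seq_len(n)) {
    for (i in seq_len(n - size + 1L)) {
      idx <- i:(i + size - 1L)
      w <- rep_p[idx]
      out <- c(
        rep_p[seq_len(n) < i],
        w[w %in% t$first], w[w %in% t$second],
        rep_p[seq_len(n) > i + size - 1L]
      )
      if (circular_equal(circular_order(out), target)) {
        return(size)
      }
    }
  }
  stop("internal error: no window reproduces the TDRL") # unreachable
}
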