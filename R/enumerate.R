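#' Enumerate all equivalent TDRLs between two circular gene orders
#'
#' For two circular orders at TDRL distance one there are exactly `2n`
#' triples `(F, S, p)` that transform the source into the target: one
#' labeled pair per origin, the two members of a pair being F/S swaps of
#' each other. For equal orders (distance zero) there are `2n^2` identity
#' triples. This function returns the complete set, annotated with each
#' triple's minimal partial-duplication window.
#'
#' The search is quadratic: for each origin `p` the `n` target
#' linearizations are relabeled into the position space of the source
#' representative starting at `p`; a linearization contributes a triple iff
#' the relabeled permutation has exactly one descent, which fixes the cut
#' between `F` (before the descent) and `S` (after it).
#'
#' @param source,target `circular_order` objects over the same gene set
#'   with `circular_tdrl_distance(source, target) <= 1`.
#' @return An object of class `tdrl_enumeration`: a list with `source`,
#'   `target`, `case` (`"single-tdrl"` or `"identity"`), and `tdrls`, a
#'   tibble with one row per triple ordered by origin along the source's
#'   canonical representative, direct labeling (origin in `S`) before swap:
#'   columns `origin`, `labeling`, `first_copy` and `second_copy`
#'   (list-columns of gene sets), `window` (list-column, the minimal window
#'   in representative order), `window_size`, `origin_window_size` (the
#'   smaller of the two labelings' windows), `displayed` (marks the
#'   smaller-window labeling used in matrix renderings), `is_min_dup`
#'   (window attains the global minimum duplication size).
#' @examples
#' enumerate_tdrls(circular_order(1:8), circular_order(c(1, 2, 4, 6, 3, 5, 7, 8)))
#' @export
enumerate_tdrls <- function(source, target) {
  stopifnot_order(source, "source")
  stopifnot_order(target, "target")
  check_same_gene_set(source$genes, target$genes)
  if (circular_equal(source, target)) {
    return(new_enumeration(source, target, "identity", identity_triples(source)))
  }
  d_fwd <- circular_tdrl_distance(source, target)
  if (d_fwd > 1L) {
    d_bwd <- circular_tdrl_distance(target, source)
    stop("orders differ by more than one TDRL (distance ", d_fwd,
         " forward, ", d_bwd, " backward)", call. = FALSE)
  }
  n <- source$n
  rows <- list()
  seen <- character(0)
  for (p in source$genes) {
    rep_p <- representative(source, p)
    for (q in target$genes) {
      t_rep <- representative(target, q)
      u <- match(t_rep, rep_p)
      desc <- which(diff(u) < 0L)
      if (length(desc) == 1L) {
        t <- tdrl(t_rep[seq_len(desc)], t_rep[(desc + 1L):n], p)
        key <- tdrl_key(t)
        if (!key %in% seen) {
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- t
        }
      }
    }
  }
  new_enumeration(source, target, "single-tdrl", rows)
}

# all 2n^2 identity triples: per origin the n+1 prefix cuts of the
# representative and their swaps, deduplicated (the empty-F and empty-S
# triples coincide across the two families)
identity_triples <- function(source) {
  n <- source$n
  rows <- list()
  seen <- character(0)
  for (p in source$genes) {
    rep_p <- representative(source, p)
    for (cut in 0:n) {
      pre <- rep_p[seq_len(cut)]
      suf <- rep_p[setdiff(seq_len(n), seq_len(cut))]
      for (t in list(tdrl(pre, suf, p), tdrl(suf, pre, p))) {
        key <- tdrl_key(t)
        if (!key %in% seen) {
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- t
        }
      }
    }
  }
  rows
}

new_enumeration <- function(source, target, case, triples) {
  tab <- tibble::tibble(
    origin = vapply(triples, function(t) t$origin, character(1)),
    first_copy = lapply(triples, function(t) t$first),
    second_copy = lapply(triples, function(t) t$second),
    direct = vapply(triples, function(t) t$origin %in% t$second, logical(1))
  )
  # deterministic order: origin along the source's canonical representative,
  # direct labeling (origin kept in the second copy) before its swap
  tab <- tab[order(match(tab$origin, source$genes), !tab$direct,
                   lengths(tab$first_copy)), , drop = FALSE]
  tab$labeling <- ifelse(tab$direct, "direct", "swap")
  tab$direct <- NULL
  if (case == "single-tdrl") {
    partials <- purrr::pmap(
      list(tab$first_copy, tab$second_copy, tab$origin),
      function(f, s, p) minimal_partial(tdrl(f, s, p), source)
    )
    tab$window <- purrr::map(partials, "window")
    tab$window_size <- lengths(tab$window)
    per_origin <- tapply(tab$window_size, tab$origin, min)
    tab$origin_window_size <- as.integer(per_origin[tab$origin])
    tab <- tab |>
      dplyr::group_by(.data$origin) |>
      dplyr::mutate(
        displayed = pick_displayed(.data$window_size, .data$first_copy)
      ) |>
      dplyr::ungroup()
    global_min <- min(tab$origin_window_size)
    tab$is_min_dup <- tab$origin_window_size == global_min
  } else {
    tab$window <- purrr::map(seq_len(nrow(tab)), function(i) character(0))
    tab$window_size <- 0L
    tab$origin_window_size <- 0L
    tab$displayed <- tab$labeling == "direct"
    tab$is_min_dup <- NA
  }
  tab <- tab[, c("origin", "labeling", "first_copy", "second_copy", "window",
                 "window_size", "origin_window_size", "displayed", "is_min_dup")]
  structure(
    list(source = source, target = target, case = case, tdrls = tab),
    class = "tdrl_enumeration"
  )
}

# within one origin, mark the labeling shown in matrix renderings: the
# smaller window; ties broken by smaller |F|, then lexicographically
# smaller F
pick_displayed <- function(window_size, first_copy) {
  key_f <- vapply(first_copy, function(f) paste(f, collapse = ","), character(1))
  rank <- order(window_size, lengths(first_copy), key_f)
  out <- rep(FALSE, length(window_size))
  out[rank[1L]] <- TRUE
  out
}

#' @export
print.tdrl_enumeration <- function(x, ...) {
  cat("<tdrl_enumeration: ", x$case, " case, n = ", x$source$n, ", ",
      nrow(x$tdrls), " equivalent TDRLs>\n", sep = "")
  cat("  source: ", format(x$source), "\n", sep = "")
  cat("  target: ", format(x$target), "\n", sep = "")
  print(x$tdrls, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the enumerated TDRLs into a tibble
#'
#' @param x A `tdrl_enumeration`.
#' @param ... Unused.
#' @return The annotation tibble with one row per enumerated triple (see
#'   [enumerate_tdrls()]).
#' @method tidy tdrl_enumeration
#' @export
tidy.tdrl_enumeration <- function(x, ...) {
  x$tdrls
}

#' One-row summary of an enumeration
#'
#' @param x A `tdrl_enumeration`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `case`, `n_tdrls`, `n_origins`,
#'   `min_window_size`.
#' @method glance tdrl_enumeration
#' @export
glance.tdrl_enumeration <- function(x, ...) {
  tibble::tibble(
    n = x$source$n,
    case = x$case,
    n_tdrls = nrow(x$tdrls),
    n_origins = length(unique(x$tdrls$origin)),
    min_window_size = if (x$case == "single-tdrl") min(x$tdrls$window_size) else 0L
  )
}

#' Extract one enumerated triple as a tdrl object
#'
#' @param x A `tdrl_enumeration`.
#' @param i Row index into `tidy(x)`.
#' @return A [tdrl()] object.
#' @export
enumerated_tdrl <- function(x, i) {
  row <- x$tdrls[i, ]
  tdrl(row$first_copy[[1L]], row$second_copy[[1L]], row$origin)
}

#' Exhaustive enumeration oracle
#'
#' Tests all `n * 2^n` TDRL triples by direct application and returns every
#' triple that transforms `source` into `target`. Exponential; guarded to
#' `n <= 10`. Intended as ground truth for [enumerate_tdrls()].
#'
#' @inheritParams enumerate_tdrls
#' @return List of [tdrl()] objects (unordered).
#' @export
brute_force_enumerate <- function(source, target) {
  stopifnot_order(source, "source")
  stopifnot_order(target, "target")
  check_same_gene_set(source$genes, target$genes)
  n <- source$n
  if (n > 10L) {
    stop("brute-force enumeration is limited to n <= 10", call. = FALSE)
  }
  masks <- subset_mask_matrix(n)
  out <- list()
  for (p in source$genes) {
    rep_p <- representative(source, p)
    for (m in seq_len(nrow(masks))) {
      f <- masks[m, ]
      res <- circular_order(c(rep_p[f], rep_p[!f]))
      if (circular_equal(res, target)) {
        out[[length(out) + 1L]] <- tdrl(rep_p[f], rep_p[!f], p)
      }
    }
  }
  out
}

#' TDRLs duplicating the minimum number of genes
#'
#' Restricts an enumeration to the triples whose minimal
#' partial-duplication window attains the global minimum window size, i.e.
#' the most parsimonious rearrangements in terms of duplicated genes.
#'
#' @param x A `tdrl_enumeration` in the single-TDRL case.
#' @return Tibble of the flagged rows of `tidy(x)`.
#' @export
minimum_duplication_set <- function(x) {
  if (!inherits(x, "tdrl_enumeration")) {
    stop("`x` must be a tdrl_enumeration", call. = FALSE)
  }
  if (x$case != "single-tdrl") {
    stop("minimum-duplication selection is meaningful only for the ",
         "single-TDRL case (identity maps duplicate nothing)", call. = FALSE)
  }
  dplyr::filter(x$tdrls, .data$is_min_dup)
}
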