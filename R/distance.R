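#' Number of maximal increasing substrings of a permutation
#'
#' Partition the values `1..n` into maximal runs of consecutive values
#' `v, v+1, ...` whose positions in `w` increase. The run count `k` governs
#' the TDRL sorting cost under the unit-cost model: sorting `w` to the
#' identity needs exactly `ceiling(log2(k))` whole-genome TDRLs, because one
#' TDRL can halve the number of runs. `k = 1` iff `w` is the identity.
#'
#' @param w Integer permutation of `1:n` (positions of source genes in the
#'   target, see [relabel_by_target()]).
#' @return The run count `k`, a positive integer.
#' @examples
#' increasing_substring_count(c(1, 2, 5, 3, 6, 4, 7, 8)) # 2
#' @export
increasing_substring_count <- function(w) {
  w <- as.integer(w)
  n <- length(w)
  if (n == 0L || anyNA(w) || !setequal(w, seq_len(n))) {
    stop("`w` must be a permutation of 1:n", call. = FALSE)
  }
  pos <- integer(n)
  pos[w] <- seq_len(n)
  1L + sum(diff(pos) < 0L)
}

ceil_log2 <- function(k) {
  d <- 0L
  while (bitwShiftL(1L, d) < k) d <- d + 1L
  d
}

#' TDRL distance between two linear gene orders
#'
#' The minimum number of whole-genome TDRLs transforming the fixed
#' linearization `source_rep` into the fixed linearization `target_rep`:
#' `ceiling(log2(k))` where `k` is the increasing-substring count of the
#' relabeled permutation. The distance is directed; it need not equal the
#' distance of the reversed problem.
#'
#' @inheritParams relabel_by_target
#' @return Non-negative integer distance.
#' @examples
#' linear_tdrl_distance(as.character(1:8),
#'                      as.character(c(1, 2, 4, 6, 3, 5, 7, 8))) # 1
#' @export
linear_tdrl_distance <- function(source_rep, target_rep) {
  ceil_log2(increasing_substring_count(relabel_by_target(source_rep, target_rep)))
}

#' Directed TDRL distance between two circular gene orders
#'
#' The smallest number of TDRLs transforming circular order `a` into
#' circular order `b`. Working with a fixed pair of linearizations can
#' overestimate this number, so the distance is minimized over all `n x n`
#' pairs of representatives (one rotation of each order). The result is 0
#' iff the orders are circularly equal; the distance is directed and may
#' differ from `circular_tdrl_distance(b, a)`.
#'
#' @param a,b `circular_order` objects over the same gene set.
#' @return Non-negative integer distance.
#' @examples
#' circular_tdrl_distance(circular_order(1:8),
#'                        circular_order(c(1, 2, 4, 6, 3, 5, 7, 8))) # 1
#' @export
circular_tdrl_distance <- function(a, b) {
  stopifnot_order(a, "a")
  stopifnot_order(b, "b")
  check_same_gene_set(a$genes, b$genes)
  if (circular_equal(a, b)) {
    return(0L)
  }
  n <- a$n
  best <- Inf
  for (i in seq_len(n) - 1L) {
    src <- rotate_genes(a$genes, i)
    for (j in seq_len(n) - 1L) {
      d <- linear_tdrl_distance(src, rotate_genes(b$genes, j))
      if (d < best) {
        best <- d
        if (best == 1L) return(1L) # cannot be 0: classes differ
      }
    }
  }
  as.integer(best)
}

#' Both directed TDRL distances of a pair of circular orders
#'
#' @param a,b `circular_order` objects over the same gene set.
#' @return A tibble with columns `direction` (`"a_to_b"`, `"b_to_a"`) and
#'   `distance`.
#' @export
tdrl_distances <- function(a, b) {
  tibble::tibble(
    direction = c("a_to_b", "b_to_a"),
    distance = c(circular_tdrl_distance(a, b), circular_tdrl_distance(b, a))
  )
}

# ---- breadth-first search oracle ------------------------------------------

# integer encoding of an order's genes relative to a fixed label universe
encode_order <- function(order, universe) {
  match(order$genes, universe)
}

canonical_key <- function(perm) {
  i <- match(1L, perm)
  paste(rotate_genes(perm, i - 1L), collapse = ",")
}

# all canonical keys reachable from integer permutation `perm` by one TDRL
neighbor_keys <- function(perm, mask_matrix) {
  n <- length(perm)
  keys <- character(0)
  for (r in seq_len(n) - 1L) {
    rep_p <- rotate_genes(perm, r)
    for (m in seq_len(nrow(mask_matrix))) {
      f <- mask_matrix[m, ]
      keys[[length(keys) + 1L]] <- canonical_key(c(rep_p[f], rep_p[!f]))
    }
  }
  unique(keys)
}

subset_mask_matrix <- function(n) {
  m <- matrix(FALSE, nrow = 2L^n, ncol = n)
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(seq_len(2L^n) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  m
}

# full BFS table: canonical key -> exact TDRL distance from `a`, for every
# rotation class reachable within max_depth (all of them, since any class is
# reachable in <= ceil(log2 n) TDRLs); internal engine behind the small-n
# oracle tests
bfs_distance_table <- function(a, max_depth = 8L) {
  stopifnot_order(a, "a")
  if (a$n > 8L) stop("BFS table is limited to n <= 8", call. = FALSE)
  universe <- sort_labels(a$genes)
  start <- canonical_key(encode_order(a, universe))
  masks <- subset_mask_matrix(a$n)
  dist <- stats::setNames(0L, start)
  frontier <- start
  depth <- 0L
  while (depth < max_depth && length(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- character(0)
    for (key in frontier) {
      perm <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      for (nb in neighbor_keys(perm, masks)) {
        if (is.na(dist[nb])) {
          dist[[nb]] <- depth
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  dist
}

order_key <- function(order) {
  canonical_key(encode_order(order, sort_labels(order$genes)))
}

#' Exact TDRL distance by breadth-first search (small-n oracle)
#'
#' Ground-truth distance computation that explores the space of circular
#' orders by applying every possible TDRL triple, level by level, starting
#' from `a`. Exponential in `n` and therefore guarded to `n <= 8`; for
#' larger orders use [circular_tdrl_distance()].
#'
#' @param a,b `circular_order` objects over the same gene set, `n <= 8`.
#' @param max_depth Search horizon (default 8).
#' @return The exact minimum number of TDRLs transforming `a` into `b`, or
#'   an error if it exceeds `max_depth`.
#' @export
bfs_distance_oracle <- function(a, b, max_depth = 8L) {
  stopifnot_order(a, "a")
  stopifnot_order(b, "b")
  check_same_gene_set(a$genes, b$genes)
  if (a$n > 8L) {
    stop("BFS oracle is limited to n <= 8; use circular_tdrl_distance()",
         call. = FALSE)
  }
  if (max_depth < 0L) stop("`max_depth` must be >= 0", call. = FALSE)
  universe <- sort_labels(a$genes)
  start <- canonical_key(encode_order(a, universe))
  goal <- canonical_key(encode_order(b, universe))
  if (identical(start, goal)) {
    return(0L)
  }
  masks <- subset_mask_matrix(a$n)
  visited <- new.env(parent = emptyenv())
  assign(start, TRUE, envir = visited)
  frontier <- start
  depth <- 0L
  while (depth < max_depth && length(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- character(0)
    for (key in frontier) {
      perm <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      for (nb in neighbor_keys(perm, masks)) {
        if (identical(nb, goal)) {
          return(depth)
        }
        if (!exists(nb, envir = visited, inherits = FALSE)) {
          assign(nb, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  stop("TDRL distance exceeds max_depth = ", max_depth, call. = FALSE)
}
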