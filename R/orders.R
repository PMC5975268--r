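#' Circular gene orders
#'
#' A circular gene order models a unichromosomal circular genome (such as an
#' animal mitochondrial genome) as the rotation-equivalence class of a
#' permutation of distinct gene labels. Two linearizations that differ only by
#' where the circle was cut describe the same genome, so equality is
#' rotation-invariant. Internally one canonical representative is stored: the
#' rotation that starts at the smallest gene label (numeric order when every
#' label is an unsigned integer string, C-locale lexicographic order
#' otherwise).
#'
#' @param genes Character vector of distinct gene labels, length >= 1.
#'   Integer vectors are accepted and converted to character.
#' @return An object of class `circular_order` with fields `genes` (the
#'   canonical representative) and `n`.
#' @examples
#' circular_order(c(1, 4, 2, 5, 3))
#' circular_order(c("cox1", "trnL2", "cox2"))
#' @export
circular_order <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) < 1L) {
    stop("a circular gene order needs at least one gene", call. = FALSE)
  }
  if (anyNA(genes) || any(genes == "")) {
    stop("gene labels must be non-missing, non-empty strings", call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("duplicate gene ", paste(dup, collapse = ", "),
         " in circular gene order", call. = FALSE)
  }
  structure(
    list(genes = canonical_rotation(genes), n = length(genes)),
    class = "circular_order"
  )
}

#' @export
print.circular_order <- function(x, ...) {
  cat("<circular gene order, n = ", x$n, ">\n", sep = "")
  cat("(", paste(x$genes, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.circular_order <- function(x, ...) {
  paste0("(", paste(x$genes, collapse = " "), ")")
}

#' @export
length.circular_order <- function(x) x$n

is_circular_order <- function(x) inherits(x, "circular_order")

stopifnot_order <- function(x, arg = "order") {
  if (!is_circular_order(x)) {
    stop("`", arg, "` must be a circular_order object", call. = FALSE)
  }
  invisible(x)
}

# order() of labels: numeric when all labels are unsigned integer strings,
# C-locale lexicographic otherwise.  Used for the canonical rotation and for
# deterministic display of gene sets.
label_order <- function(labels) {
  if (all(grepl("^[0-9]+$", labels))) {
    order(as.numeric(labels))
  } else {
    order(labels, method = "radix")
  }
}

sort_labels <- function(labels) labels[label_order(labels)]

canonical_rotation <- function(genes) {
  rotate_genes(genes, label_order(genes)[1L] - 1L)
}

#' Rotate a linear gene sequence
#'
#' Applies the shift operation `k` times: the first `k` genes are moved,
#' in order, to the end of the sequence. A full rotation (`k = n`) is the
#' identity.
#'
#' @param genes Character vector (a linearization of a circular order).
#' @param k Non-negative integer number of single-gene shifts.
#' @return The rotated character vector.
#' @examples
#' rotate_genes(c("1", "4", "2", "5", "3"), 2) # (2 5 3 1 4)
#' @export
rotate_genes <- function(genes, k) {
  n <- length(genes)
  k <- as.integer(k) %% n
  if (k == 0L) return(genes)
  c(genes[(k + 1L):n], genes[1:k])
}

#' Representative of a circular order starting at a given gene
#'
#' Every circular order of length `n` has exactly `n` linear representatives,
#' one per start gene. This returns the unique representative beginning
#' with `p`.
#'
#' @param order A `circular_order`.
#' @param p A gene label occurring in `order`.
#' @return Character vector of length `n` starting with `p`.
#' @examples
#' representative(circular_order(c(1, 4, 2, 5, 3)), "4") # (4 2 5 3 1)
#' @export
representative <- function(order, p) {
  stopifnot_order(order)
  p <- as.character(p)
  i <- match(p, order$genes)
  if (is.na(i)) {
    stop("gene ", p, " does not occur in the circular order", call. = FALSE)
  }
  rotate_genes(order$genes, i - 1L)
}

#' Rotation-invariant equality of circular orders
#'
#' @param a,b `circular_order` objects.
#' @return `TRUE` iff some rotation of one representative equals the other,
#'   i.e. the two objects denote the same circular genome. Orders over
#'   different gene sets (or of different length) are unequal, not an error.
#' @examples
#' circular_equal(circular_order(c(1, 4, 2, 5, 3)),
#'                circular_order(c(3, 1, 4, 2, 5)))
#' @export
circular_equal <- function(a, b) {
  stopifnot_order(a, "a")
  stopifnot_order(b, "b")
  # canonical representatives are unique per rotation class
  a$n == b$n && identical(a$genes, b$genes)
}

#' Relabel a source linearization in target position space
#'
#' Maps each gene of `source_rep` to its 1-based position in `target_rep`,
#' reducing "transform source into target" to "sort the resulting
#' permutation to the identity". The result is the identity permutation iff
#' the two linearizations are equal.
#'
#' @param source_rep,target_rep Character vectors that are permutations of
#'   the same gene set.
#' @return Integer permutation `w` of `1:n` with `w[i]` the position of
#'   `source_rep[i]` in `target_rep`.
#' @examples
#' relabel_by_target(as.character(1:8), as.character(c(1, 2, 4, 6, 3, 5, 7, 8)))
#' @export
relabel_by_target <- function(source_rep, target_rep) {
  source_rep <- as.character(source_rep)
  target_rep <- as.character(target_rep)
  check_same_gene_set(source_rep, target_rep)
  match(source_rep, target_rep)
}

check_same_gene_set <- function(a, b) {
  extra_a <- setdiff(a, b)
  extra_b <- setdiff(b, a)
  if (length(extra_a) > 0L || length(extra_b) > 0L) {
    stop(
      "gene sets differ: ",
      if (length(extra_a)) paste0("only in first: {", paste(sort_labels(extra_a), collapse = ", "), "} "),
      if (length(extra_b)) paste0("only in second: {", paste(sort_labels(extra_b), collapse = ", "), "}"),
      call. = FALSE
    )
  }
  if (length(a) != length(b) || anyDuplicated(a) || anyDuplicated(b)) {
    stop("both sequences must be permutations of the same gene set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximal conserved gene segments of two circular orders
#'
#' Computes the maximal contiguous gene runs (read in the same direction)
#' common to both circular orders. Because no gene is duplicated, these are
#' exactly the maximal chains of shared gene adjacencies; the segments
#' partition the gene set, with genes that share no adjacency reported as
#' singletons. Reversed matches are not considered: a TDRL never inverts
#' gene order, so conserved runs must read identically in both genomes.
#'
#' @param a,b `circular_order` objects over the same gene set.
#' @return A tibble with one row per segment, ordered by position of the
#'   segment start along `a`'s canonical representative: `genes`
#'   (list-column, genes in reading order), `length`.
#' @examples
#' conserved_segments(circular_order(1:6), circular_order(c(1, 2, 3, 5, 4, 6)))
#' @export
conserved_segments <- function(a, b) {
  stopifnot_order(a, "a")
  stopifnot_order(b, "b")
  check_same_gene_set(a$genes, b$genes)
  n <- a$n
  succ_a <- stats::setNames(rotate_genes(a$genes, 1L), a$genes)
  succ_b <- stats::setNames(rotate_genes(b$genes, 1L), b$genes)
  shared <- succ_a == succ_b[names(succ_a)] # adjacency g -> succ_a[g] in both
  if (all(shared)) {
    return(tibble::tibble(genes = list(a$genes), length = n))
  }
  pred_shared <- stats::setNames(shared, succ_a) # gene g: adjacency pred -> g shared?
  starts <- a$genes[!pred_shared[a$genes]]
  segs <- lapply(starts, function(g) {
    run <- g
    while (shared[[g]]) {
      g <- succ_a[[g]]
      run <- c(run, g)
    }
    run
  })
  ord <- order(match(starts, a$genes))
  segs <- segs[ord]
  tibble::tibble(genes = segs, length = lengths(segs))
}

#' Read gene orders from a FASTA-like file
#'
#' Parses the plain-text dialect used by common gene-order tools: a line
#' starting with `>` opens a record and names it; the following non-empty
#' lines hold whitespace-separated gene names. A leading `+` or `-` strand
#' sign on a gene name is stripped (with a one-time message), since a TDRL
#' never changes gene orientation and the analysis is unsigned.
#'
#' @param path Path to the file.
#' @return Named list of `circular_order` objects, in file order.
#' @export
read_gene_orders <- function(path) {
  if (!file.exists(path)) {
    stop("gene order file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L || !startsWith(lines[1L], ">")) {
    stop("no gene order records found in ", path,
         " (expected a '>' header line)", call. = FALSE)
  }
  rec_idx <- cumsum(startsWith(lines, ">"))
  records <- split(lines, rec_idx)
  signs_seen <- FALSE
  out <- lapply(records, function(rec) {
    name <- sub("^>\\s*", "", rec[1L])
    genes <- unlist(strsplit(rec[-1L], "\\s+"), use.names = FALSE)
    genes <- genes[genes != ""]
    if (length(genes) == 0L) {
      stop("empty gene order record: ", name, call. = FALSE)
    }
    if (any(grepl("^[+-]", genes))) signs_seen <<- TRUE
    genes <- sub("^[+-]", "", genes)
    dup <- unique(genes[duplicated(genes)])
    if (length(dup) > 0L) {
      stop("duplicate gene ", paste(dup, collapse = ", "),
           " in record ", name, call. = FALSE)
    }
    circular_order(genes)
  })
  if (signs_seen) {
    message("strand signs present in ", basename(path),
            " were stripped (TDRLs do not change gene orientation)")
  }
  names(out) <- vapply(records, function(rec) sub("^>\\s*", "", rec[1L]), character(1))
  out
}

#' Restrict two circular orders to their shared gene set
#'
#' Drops, with a warning, all genes that occur in only one of the two
#' orders, keeping the relative circular order of the remaining genes.
#' Useful when two annotations disagree on a few markers.
#'
#' @param a,b `circular_order` objects.
#' @return List with elements `a` and `b`, both over the common gene set.
#' @export
project_shared <- function(a, b) {
  stopifnot_order(a, "a")
  stopifnot_order(b, "b")
  common <- intersect(a$genes, b$genes)
  if (length(common) == 0L) {
    stop("the two gene orders share no genes", call. = FALSE)
  }
  dropped <- c(setdiff(a$genes, common), setdiff(b$genes, common))
  if (length(dropped) > 0L) {
    warning("dropping genes absent from one order: ",
            paste(sort_labels(unique(dropped)), collapse = ", "),
            call. = FALSE)
  }
  list(
    a = circular_order(a$genes[a$genes %in% common]),
    b = circular_order(b$genes[b$genes %in% common])
  )
}
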