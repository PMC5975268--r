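#' Seeded random circular gene order
#'
#' Draws a uniform random rotation class over the gene labels
#' `"1" .. "n"` (a uniform random permutation induces a uniform rotation
#' class). Pure function of `(n, seed)`: the global RNG state is left
#' untouched.
#'
#' @param n Number of genes, `n >= 3`.
#' @param seed Integer seed.
#' @return A `circular_order`.
#' @export
random_circular_order <- function(n, seed) {
  if (n < 3L) stop("`n` must be at least 3", call. = FALSE)
  withr::with_seed(seed, circular_order(as.character(sample.int(n))))
}

#' Seeded random TDRL triple on a gene universe
#'
#' Each gene is assigned to `F` or `S` independently with probability 1/2
#' and the origin is uniform over the genes.
#'
#' @param genes Character vector of gene labels.
#' @param seed Integer seed.
#' @return A [tdrl()] triple (possibly an identity map).
#' @export
random_tdrl <- function(genes, seed) {
  genes <- as.character(genes)
  withr::with_seed(seed, {
    in_first <- sample(c(TRUE, FALSE), length(genes), replace = TRUE)
    tdrl(genes[in_first], genes[!in_first], sample(genes, 1L))
  })
}

#' Seeded synthetic pair of circular orders at TDRL distance one
#'
#' Draws a random circular order and a random non-identity TDRL (identity
#' maps are rejected and redrawn) and applies it, yielding a pair whose
#' directed TDRL distance from source to target is exactly one — the
#' precondition of [enumerate_tdrls()]. With `identity = TRUE` the target
#' equals the source instead (distance zero, the `2n^2` identity case) and
#' the generating triple is an identity map.
#'
#' @param n Number of genes, `n >= 4`.
#' @param seed Integer seed; the pair is a pure function of
#'   `(n, seed, identity)`.
#' @param identity Generate an identity pair instead of a distance-one pair.
#' @return Object of class `synthetic_pair`: list with `source`, `target`,
#'   `tdrl` (the generating triple), `n`, `seed`.
#' @export
random_d1_pair <- function(n, seed, identity = FALSE) {
  if (n < 4L) stop("`n` must be at least 4", call. = FALSE)
  source <- random_circular_order(n, seed)
  if (identity) {
    t <- tdrl(character(0), source$genes, source$genes[[1L]])
    return(structure(
      list(source = source, target = source, tdrl = t, n = n, seed = seed),
      class = "synthetic_pair"
    ))
  }
  for (attempt in seq_len(1000L)) {
    t <- random_tdrl(source$genes, seed + 20000L * attempt)
    target <- apply_tdrl(t, source)
    if (!circular_equal(target, source)) {
      return(structure(
        list(source = source, target = target, tdrl = t, n = n, seed = seed),
        class = "synthetic_pair"
      ))
    }
  }
  stop("failed to draw a non-identity TDRL") # astronomically unlikely
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat("<synthetic pair, n = ", x$n, ", seed = ", x$seed, ">\n", sep = "")
  cat("  source: ", format(x$source), "\n", sep = "")
  cat("  target: ", format(x$target), "\n", sep = "")
  cat("  TDRL  : ", format(x$tdrl), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic pair to disk
#'
#' Writes `<prefix>.fa` (FASTA-like gene-order file holding the source and
#' target records, readable by [read_gene_orders()]) and
#' `<prefix>_tdrl.tsv` (the generating triple, for regression tests).
#'
#' @param pair A `synthetic_pair`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_pair <- function(pair, prefix) {
  if (!inherits(pair, "synthetic_pair")) {
    stop("`pair` must be a synthetic_pair", call. = FALSE)
  }
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, "_tdrl.tsv")
  writeLines(c(
    ">source",
    paste(pair$source$genes, collapse = " "),
    ">target",
    paste(pair$target$genes, collapse = " ")
  ), fa)
  writeLines(c(
    "origin\tF\tS\tn\tseed",
    paste(pair$tdrl$origin,
          paste(pair$tdrl$first, collapse = ","),
          paste(pair$tdrl$second, collapse = ","),
          pair$n, pair$seed, sep = "\t")
  ), tsv)
  invisible(c(fa, tsv))
}
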