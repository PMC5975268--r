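# shared fixtures: the length-8 worked example and the mitochondrial case
# study bundled under extdata

toy_source <- circular_order(1:8)
toy_target <- circular_order(c(1, 2, 4, 6, 3, 5, 7, 8))

# the eight direct-labeled triples transforming toy_source into toy_target
# (one per origin); the complete set adds their F/S swaps
toy_triples <- list(
  tdrl(c(3, 5, 7, 8), c(1, 2, 4, 6), 1),
  tdrl(c(1, 3, 5, 7, 8), c(2, 4, 6), 2),
  tdrl(c(4, 6), c(1, 2, 3, 5, 7, 8), 3),
  tdrl(c(1, 2, 5, 7, 8), c(3, 4, 6), 4),
  tdrl(c(3, 6), c(1, 2, 4, 5, 7, 8), 5),
  tdrl(c(1, 2, 4, 7, 8), c(3, 5, 6), 6),
  tdrl(c(3, 5), c(1, 2, 4, 6, 7, 8), 7),
  tdrl(c(3, 5, 7), c(1, 2, 4, 6, 8), 8)
)

triple_keys <- function(triples) {
  sort(vapply(triples, tdrlkit:::tdrl_key, character(1)))
}

enumeration_keys <- function(enum) {
  td <- tidy(enum)
  sort(vapply(seq_len(nrow(td)), function(i) {
    tdrlkit:::tdrl_key(enumerated_tdrl(enum, i))
  }, character(1)))
}

extdata <- function(...) {
  path <- system.file("extdata", ..., package = "tdrlkit")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", ...)
  path
}

case_study_orders <- function() {
  read_gene_orders(extdata("psocoptera_pair.fa"))
}

# all (n-1)! rotation classes on n genes, as circular_order objects
all_circular_orders <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  lapply(perms(seq_len(n - 1L) + 1L), function(p) {
    circular_order(as.character(c(1L, p)))
  })
}
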