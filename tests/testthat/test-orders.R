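test_that("gene order files parse, strip strand signs, and reject bad records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", "1 2 3 4 5 6 7 8"), f)
  orders <- read_gene_orders(f)
  expect_named(orders, "toy")
  expect_equal(length(orders$toy), 8L)
  expect_equal(orders$toy$genes, as.character(1:8))

  writeLines(c(">g", "cox1 -trnL2 cox2"), f)
  expect_message(orders <- read_gene_orders(f), "strand signs")
  expect_equal(orders$g$genes, c("cox1", "trnL2", "cox2"))

  writeLines(c(">g", "a b a"), f)
  expect_error(read_gene_orders(f), "duplicate gene a")
  writeLines(c(">empty", ">other", "a b"), f)
  expect_error(read_gene_orders(f), "empty gene order record: empty")
  writeLines("no header here", f)
  expect_error(read_gene_orders(f), "no gene order records")
  expect_error(read_gene_orders(file.path(tempdir(), "absent.fa")), "not found")
})

test_that("multi-record files preserve record order", {
  orders <- read_gene_orders(extdata("toy_pair.fa"))
  expect_named(orders, c("toy_source", "toy_target"))
  expect_true(circular_equal(orders$toy_source, toy_source))
  expect_true(circular_equal(orders$toy_target, toy_target))
})

test_that("shift and representatives follow the worked length-5 example", {
  pi1 <- as.character(c(1, 4, 2, 5, 3))
  expect_equal(rotate_genes(pi1, 2), as.character(c(2, 5, 3, 1, 4)))
  expect_equal(rotate_genes(c("1", "2", "3"), 1), c("2", "3", "1"))
  expect_equal(rotate_genes(pi1, 5), pi1) # full rotation

  o <- circular_order(pi1)
  expect_equal(representative(o, "4"), as.character(c(4, 2, 5, 3, 1)))
  expect_equal(representative(o, "2"), as.character(c(2, 5, 3, 1, 4)))
  expect_equal(representative(o, o$genes[1]), o$genes)
  expect_error(representative(o, "9"), "does not occur")
})

test_that("circular equality is rotation-invariant and gene-set aware", {
  a <- circular_order(c(1, 4, 2, 5, 3))
  expect_true(circular_equal(a, circular_order(c(3, 1, 4, 2, 5))))
  expect_true(circular_equal(a, a))
  expect_false(circular_equal(circular_order(1:5), circular_order(c(1, 2, 3, 5, 4))))
  expect_false(circular_equal(circular_order(1:5), circular_order(1:6)))
  # rotation closure: every k-shift stays in the class
  for (k in 1:5) {
    expect_true(circular_equal(a, circular_order(rotate_genes(a$genes, k))))
  }
})

test_that("relabeling into target position space sorts to identity iff equal", {
  w <- relabel_by_target(as.character(1:8),
                         as.character(c(1, 2, 4, 6, 3, 5, 7, 8)))
  expect_equal(w, c(1L, 2L, 5L, 3L, 6L, 4L, 7L, 8L))
  expect_equal(
    relabel_by_target(as.character(c(1, 4, 2, 5, 3)),
                      as.character(c(4, 5, 1, 2, 3))),
    c(3L, 1L, 4L, 2L, 5L)
  )
  r <- as.character(c(2, 7, 1, 5))
  expect_equal(relabel_by_target(r, r), 1:4)
  expect_error(relabel_by_target(c("a", "b"), c("a", "c")), "gene sets differ")
  # inverse property: indexing the target by w reconstructs the source
  for (seed in 1:5) {
    src <- random_circular_order(7, seed)$genes
    tgt <- random_circular_order(7, seed + 100)$genes
    w <- relabel_by_target(src, tgt)
    expect_equal(tgt[w], src)
  }
})

test_that("conserved segments are maximal, same-direction, and partition the genes", {
  a <- circular_order(1:6)
  expect_equal(conserved_segments(a, a)$genes, list(as.character(1:6)))

  b <- circular_order(c(1, 2, 3, 5, 4, 6))
  segs <- conserved_segments(a, b)
  expect_setequal(
    vapply(segs$genes, paste, character(1), collapse = " "),
    c("6 1 2 3", "4", "5")
  )
  expect_equal(segs$length, lengths(segs$genes))
  # partition: concatenated segments cover each gene exactly once
  expect_setequal(unlist(segs$genes), a$genes)
  expect_equal(sum(segs$length), 6L)
  expect_error(conserved_segments(a, circular_order(1:5)), "gene sets differ")
})

test_that("projection to the shared gene set warns and preserves order", {
  a <- circular_order(c("u", "a", "b", "c"))
  b <- circular_order(c("a", "c", "b", "v"))
  expect_warning(shared <- project_shared(a, b), "u, v")
  expect_equal(shared$a$genes, c("a", "b", "c"))
  expect_true(circular_equal(shared$b, circular_order(c("a", "c", "b"))))
})
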