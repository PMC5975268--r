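test_that("applying a TDRL moves F-genes in front of S-genes from the origin", {
  o <- circular_order(c(1, 4, 2, 5, 3))
  res <- apply_tdrl(tdrl(c(4, 5), c(1, 2, 3), 1), o)
  expect_true(circular_equal(res, circular_order(c(4, 5, 1, 2, 3))))

  res2 <- apply_tdrl(tdrl(c(3, 5), c(1, 2, 4, 6, 7, 8), 7), toy_source)
  expect_true(circular_equal(res2, toy_target))

  # empty F: every gene kept in the second copy, nothing moves
  expect_true(circular_equal(apply_tdrl(tdrl(character(0), o$genes, "1"), o), o))
  expect_error(apply_tdrl(tdrl(c(1, 2), c(3, 4), 1), o), "gene sets differ")
})

test_that("triple construction enforces the bipartition invariants", {
  expect_error(tdrl(c(1, 2), c(2, 3), 1), "disjoint")
  expect_error(tdrl(c(1, 2), c(3, 4), 9), "not a member")
  t <- tdrl(c(4, 5), c(1, 2, 3), 1)
  expect_s3_class(t, "tdrl")
  expect_equal(format(t), "({4,5},{1,2,3},1)")
})

test_that("F/S swap leaves the action unchanged and is an involution", {
  o <- circular_order(c(1, 4, 2, 5, 3))
  t <- tdrl(c(4, 5), c(1, 2, 3), 1)
  s <- swap_labeling(t)
  expect_equal(s$first, t$second)
  expect_equal(tdrlkit:::tdrl_key(swap_labeling(s)), tdrlkit:::tdrl_key(t))
  expect_true(circular_equal(apply_tdrl(t, o), apply_tdrl(s, o)))
  # the two printed equivalent triples of the length-5 example
  expect_true(circular_equal(
    apply_tdrl(tdrl(c(3, 4), c(1, 2, 5), 5), o),
    apply_tdrl(tdrl(c(4, 5), c(1, 2, 3), 1), o)
  ))
  # quantified swap invariance on seeded instances
  for (seed in 1:20) {
    ord <- random_circular_order(4 + seed %% 5, seed)
    t <- random_tdrl(ord$genes, seed + 500)
    expect_true(circular_equal(apply_tdrl(t, ord),
                               apply_tdrl(swap_labeling(t), ord)))
  }
})

test_that("the duplicated intermediate keeps each gene exactly once", {
  o <- circular_order(c(1, 4, 2, 5, 3))
  t <- tdrl(c(4, 5), c(1, 2, 3), 1)
  di <- duplicated_intermediate(t, o)
  expect_equal(nrow(di), 10L)
  expect_equal(di$gene[di$kept], as.character(c(4, 5, 1, 2, 3)))
  counts <- table(di$gene)
  expect_true(all(counts == 2L))
  expect_true(all(table(di$gene[di$kept]) == 1L))
  # first n occurrences are the origin representative, repeated verbatim
  expect_equal(di$gene[di$copy == 1], representative(o, "1"))
  expect_equal(di$gene[di$copy == 1], di$gene[di$copy == 2])

  # F = full gene set: copy 1 kept entirely, copy 2 lost entirely
  t_all <- tdrl(o$genes, character(0), "1")
  di_all <- duplicated_intermediate(t_all, o)
  expect_true(all(di_all$kept[di_all$copy == 1]))
  expect_false(any(di_all$kept[di_all$copy == 2]))
})

test_that("the minimal window spans first S-gene to last F-gene", {
  p1 <- minimal_partial(tdrl(c(4, 6), c(1, 2, 3, 5, 7, 8), 3), toy_source)
  expect_equal(p1$window, as.character(3:6))
  expect_equal(p1$kept_first, c("4", "6"))
  expect_equal(p1$kept_second, c("3", "5"))

  p2 <- minimal_partial(tdrl(c(1, 2, 4, 6, 7, 8), c(3, 5), 7), toy_source)
  expect_equal(p2$window, as.character(3:6))
  expect_equal(p2$kept_first, c("4", "6"))
  expect_equal(p2$kept_second, c("3", "5"))
  expect_setequal(p2$non_duplicated, as.character(c(1, 2, 7, 8)))

  # identity triple: F is a prefix of the origin representative
  p3 <- minimal_partial(tdrl(c(3, 4), c(5, 6, 7, 8, 1, 2), 3), toy_source)
  expect_length(p3$window, 0L)
})

test_that("a partial duplication corresponds to a whole-genome TDRL", {
  t <- tdrl(c(4, 6), c(1, 2, 3, 5, 7, 8), 3)
  whole <- partial_to_whole(minimal_partial(t, toy_source))
  expect_equal(tdrlkit:::tdrl_key(whole),
               tdrlkit:::tdrl_key(tdrl(c(3, 5), c(1, 2, 4, 6, 7, 8), 7)))
  # and in general the corresponding whole TDRL acts identically
  for (seed in 1:15) {
    ord <- random_circular_order(5 + seed %% 4, seed + 40)
    t <- random_tdrl(ord$genes, seed + 900)
    if (is_identity_tdrl(t, ord)) next
    w <- partial_to_whole(minimal_partial(t, ord))
    expect_true(circular_equal(apply_tdrl(w, ord), apply_tdrl(t, ord)))
  }
  expect_error(
    partial_to_whole(minimal_partial(tdrl(character(0), toy_source$genes, "1"),
                                     toy_source)),
    "empty window"
  )
})

test_that("minimal windows match the exhaustive window oracle", {
  checked <- 0L
  for (seed in 1:30) {
    n <- 4 + seed %% 5
    ord <- random_circular_order(n, seed + 300)
    t <- random_tdrl(ord$genes, seed + 1300)
    # the window rule applies to proper rearrangements only: an identity map
    # (F a circular prefix or suffix) rearranges nothing
    if (is_identity_tdrl(t, ord)) next
    checked <- checked + 1L
    expect_equal(length(minimal_partial(t, ord)$window),
                 tdrlkit:::window_size_oracle(t, ord),
                 info = paste("seed", seed))
  }
  expect_gt(checked, 20L)
})

test_that("identity TDRLs are exactly the prefix-cut triples", {
  o <- circular_order(c(1, 4, 2, 5, 3))
  expect_true(is_identity_tdrl(tdrl(character(0), o$genes, "1"), o))
  for (cut in 0:5) {
    rep_p <- representative(o, "2")
    t <- tdrl(rep_p[seq_len(cut)], rep_p[setdiff(1:5, seq_len(cut))], "2")
    expect_true(is_identity_tdrl(t, o))
  }
  expect_false(is_identity_tdrl(tdrl(c(4, 5), c(1, 2, 3), 1), o))
})
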