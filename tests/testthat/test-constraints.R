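test_that("conserved groups exclude exactly origins 2 and 8 on the toy pair", {
  e <- enumerate_tdrls(toy_source, toy_target)
  groups <- list(c("1", "2"), c("7", "8"))
  e <- annotate_constraints(e, conserved = groups)
  td <- tidy(e)
  failing <- unique(td$origin[!td$conserved_pass])
  expect_setequal(failing, c("2", "8"))
  passing <- unique(td$origin[td$conserved_pass])
  expect_setequal(passing, as.character(c(1, 3, 4, 5, 6, 7)))
  # per-triple form with violation detail
  # origin 2 splits {1,2} across the copies ({7,8} stays within F)
  v <- passes_conserved_groups(tdrl(c(1, 3, 5, 7, 8), c(2, 4, 6), 2), groups)
  expect_false(isTRUE(v))
  expect_equal(attr(v, "violating"), "1+2")
  # origin 8 splits {7,8}
  v8 <- passes_conserved_groups(tdrl(c(3, 5, 7), c(1, 2, 4, 6, 8), 8), groups)
  expect_equal(attr(v8, "violating"), "7+8")
})

test_that("singleton and degenerate conserved groups behave as containment", {
  t <- tdrl(c(4, 6), c(1, 2, 3, 5, 7, 8), 3)
  expect_true(passes_conserved_groups(t, list("5")))
  # the full gene set can only survive jointly under an identity-style triple
  full <- list(as.character(1:8))
  expect_false(isTRUE(passes_conserved_groups(t, full)))
  expect_true(passes_conserved_groups(tdrl(character(0), as.character(1:8), 1),
                                      full))
  expect_error(passes_conserved_groups(t, list(c("1", "99"))), "unknown gene")
})

test_that("intergenic pair (3,5) passes all toy origins; (1,2) only origin 2", {
  e <- enumerate_tdrls(toy_source, toy_target)
  e35 <- annotate_constraints(e, intergenic = list(c("3", "5")))
  expect_true(all(tidy(e35)$intergenic_pass))

  e12 <- suppressWarnings(annotate_constraints(e, intergenic = list(c("1", "2"))))
  td <- tidy(e12)
  expect_setequal(unique(td$origin[td$intergenic_pass]), "2")
  # the printed witness: gene 3 lies between 1 and 2 in the origin-2 frame
  v <- passes_intergenic_pair(tdrl(c(1, 3, 5, 7, 8), c(2, 4, 6), 2),
                              toy_source, "1", "2")
  expect_true(isTRUE(v))
  expect_equal(attr(v, "witness"), "3")
})

test_that("adjacent same-set genes leave no room for a lost witness", {
  t <- tdrl(c(3, 5, 7, 8), c(1, 2, 4, 6), 1) # 1, 2 adjacent in the origin frame
  v <- passes_intergenic_pair(t, toy_source, "1", "2")
  expect_false(isTRUE(v))
  expect_true(is.na(attr(v, "witness")))
  expect_error(passes_intergenic_pair(t, toy_source, "1", "1"), "distinct")
  expect_error(passes_intergenic_pair(t, toy_source, "1", "42"), "unknown gene")
})

test_that("both filters are stable under F/S relabeling", {
  for (seed in 1:12) {
    n <- 5 + seed %% 4
    pair <- random_d1_pair(n, seed + 200)
    t <- pair$tdrl
    genes <- pair$source$genes
    grp <- list(genes[1:2], genes[c(3, 4)])
    expect_equal(isTRUE(passes_conserved_groups(t, grp)),
                 isTRUE(passes_conserved_groups(swap_labeling(t), grp)))
    v1 <- passes_intergenic_pair(t, pair$source, genes[1], genes[3])
    v2 <- passes_intergenic_pair(swap_labeling(t), pair$source,
                                 genes[1], genes[3])
    expect_equal(isTRUE(v1), isTRUE(v2), info = paste("seed", seed))
  }
})

test_that("adding conserved groups never grows the passing set", {
  e <- enumerate_tdrls(toy_source, toy_target)
  g1 <- list(c("1", "2"))
  g2 <- list(c("1", "2"), c("7", "8"), c("3", "4"))
  pass1 <- tidy(annotate_constraints(e, conserved = g1))$conserved_pass
  pass2 <- tidy(annotate_constraints(e, conserved = g2))$conserved_pass
  expect_true(all(pass1 | !pass2)) # pass2 subset of pass1
})

test_that("constraint files parse with comments and report unknown genes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# groups", "1 2", "", "7 8 # trailing"), f)
  groups <- read_conserved_groups(f)
  expect_equal(groups, list(c("1", "2"), c("7", "8")))

  writeLines(c("3 5", "1 2"), f)
  pairs <- read_intergenic_pairs(f)
  expect_equal(pairs$x, c("3", "1"))
  expect_equal(pairs$y, c("5", "2"))
  writeLines("only_one", f)
  expect_error(read_intergenic_pairs(f), "exactly two")

  e <- enumerate_tdrls(toy_source, toy_target)
  expect_error(annotate_constraints(e, conserved = list(c("1", "zz"))),
               "unknown gene")
})

test_that("non-adjacent intergenic pairs trigger a warning but still evaluate", {
  e <- enumerate_tdrls(toy_source, toy_target)
  expect_warning(annotate_constraints(e, intergenic = list(c("1", "7"))),
                 "not adjacent")
  # (3,5) is adjacent in the target (1 2 4 6 3 5 7 8): no warning
  expect_silent(annotate_constraints(e, intergenic = list(c("3", "5"))))
})
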