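test_that("expand_state implements the IUPAC table", {
  expect_equal(expand_state("A"), "A")
  expect_equal(expand_state("u"), "T")
  expect_equal(expand_state("N"), c("A", "C", "G", "T"))
  expect_equal(expand_state("-"), c("A", "C", "G", "T"))
  expect_equal(expand_state("R"), c("A", "G"))
  expect_equal(expand_state("y"), c("C", "T"))
  expect_equal(expand_state("S"), c("C", "G"))
  expect_equal(expand_state("W"), c("A", "T"))
  expect_equal(expand_state("K"), c("G", "T"))
  expect_equal(expand_state("M"), c("A", "C"))
  expect_equal(expand_state("B"), c("C", "G", "T"))
  expect_equal(expand_state("D"), c("A", "G", "T"))
  expect_equal(expand_state("H"), c("A", "C", "T"))
  expect_equal(expand_state("V"), c("A", "C", "G"))
  expect_error(expand_state("X"), "unrecognised")
  expect_error(expand_state("AC"), "single character")
})

test_that("unrecognised alignment characters name sequence, site and character", {
  aln <- rbind(A = c("A", "A"), B = c("A", "?"), C = c("T", "T"), D = c("T", "T"))
  expect_error(fitch_site_lengths(quartet_tree(), aln),
               "'\\?' in sequence 'B' at site 2")
})

test_that("downpass reproduces the worked quartet tree lengths", {
  tr <- quartet_tree()
  lens <- fitch_site_lengths(
    tr, rbind(A = c("A", "A", "A", "A"),
              B = c("A", "T", "A", "N"),
              C = c("T", "A", "A", "T"),
              D = c("T", "T", "A", "T")))
  # clade-defining / homoplasious / invariant / ambiguous-rescued patterns
  expect_identical(lens, c(1L, 2L, 0L, 1L))
})

test_that("oracle enumeration matches its frozen small cases", {
  tr <- quartet_tree()
  expect_equal(oracle_min_changes(tr, c(A = "A", B = "A", C = "T", D = "T")), 1L)
  expect_equal(oracle_min_changes(tr, c(A = "A", B = "T", C = "A", D = "T")), 2L)
  expect_equal(oracle_min_changes(tr, c(A = "A", B = "N", C = "T", D = "T")), 1L)
  expect_equal(oracle_min_changes(parse_newick("(A,B,C);"), c("A", "C", "G")), 2L)
  expect_error(oracle_min_changes(ape::rtree(13), rep("A", 13)), "12 tips")
})

test_that("downpass equals the exhaustive oracle on random binary instances", {
  set.seed(405)
  for (i in 1:200) {
    inst <- random_site_instance()
    expect_identical(
      fitch_site_lengths(inst$tree, one_site_alignment(inst$chars)),
      oracle_min_changes(inst$tree, inst$chars))
  }
})

# On a multifurcation the left-to-right fold scores the caterpillar
# resolution of the node, and refining a polytomy can only lower the
# parsimony length; so the fold is bounded by the exact multifurcation
# minimum above and by the n_states - 1 floor below (keeping CI <= 1).
test_that("on polytomies the fold is sandwiched between the state floor and the oracle", {
  set.seed(406)
  for (i in 1:100) {
    tree <- random_polytomy_tree()
    chars <- stats::setNames(sample(c("A", "C", "G", "T", "N"),
                                    length(tree$tip.label), replace = TRUE),
                             tree$tip.label)
    tl <- fitch_site_lengths(tree, one_site_alignment(chars))
    expect_lte(tl, oracle_min_changes(tree, chars))
    n_states <- sum(vapply(c("A", "C", "G", "T"),
                           function(b) any(chars == b), logical(1)))
    expect_gte(tl, max(0L, n_states - 1L))
  }
})

test_that("tree length respects the parsimony lower bound and child-order invariance", {
  set.seed(407)
  for (i in 1:50) {
    inst <- random_site_instance(p_ambig = 0.2)
    tl <- fitch_site_lengths(inst$tree, one_site_alignment(inst$chars))
    n_states <- sum(vapply(c("A", "C", "G", "T"),
                           function(b) any(inst$chars == b), logical(1)))
    expect_gte(tl, max(0L, n_states - 1L))

    ntip <- length(inst$tree$tip.label)
    rotated <- ape::rotate(inst$tree, ntip + sample(inst$tree$Nnode, 1))
    expect_identical(fitch_site_lengths(rotated, one_site_alignment(inst$chars)), tl)
  }
})

test_that("replacing a tip call by N never increases the tree length", {
  set.seed(408)
  for (i in 1:50) {
    inst <- random_site_instance(p_ambig = 0.2)
    tl <- fitch_site_lengths(inst$tree, one_site_alignment(inst$chars))
    chars_n <- inst$chars
    chars_n[sample(length(chars_n), 1)] <- "N"
    expect_lte(fitch_site_lengths(inst$tree, one_site_alignment(chars_n)), tl)
  }
})

test_that("consistency index has the documented orientation and guards", {
  expect_equal(consistency_index(1L, 2L), 1)
  expect_equal(consistency_index(2L, 2L), 0.5)
  expect_equal(consistency_index(0L, 1L), 1)
  expect_equal(consistency_index(0L, 0L), 1)
  expect_equal(consistency_index(c(3L, 4L), c(3L, 2L)), c(2 / 3, 0.25))
  expect_error(consistency_index(0L, 2L), "internal error")
  expect_error(consistency_index(-1L, 1L), "non-negative")
})
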