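# Shared small outbreak + tree for insertion tests
insertion_fixture <- function(seed = 417) {
  set.seed(seed)
  ob <- simulate_outbreak(simulation_config(n_individuals = 80L,
                                            stop_after_sampled = 40L))
  list(ob = ob, tree = build_nj_tree(ob$alignment))
}

test_that("inserting zero homoplasies is the identity", {
  fx <- insertion_fixture()
  out <- insert_homoplasies(fx$tree, fx$ob$alignment, 0)
  expect_identical(out$alignment[rownames(fx$ob$alignment), ], fx$ob$alignment)
  expect_equal(nrow(out$records), 0L)
})

test_that("each insertion creates a site flagged on the pre-insertion tree", {
  fx <- insertion_fixture(418)
  out <- insert_homoplasies(fx$tree, fx$ob$alignment, 5)
  expect_equal(nrow(out$records), 5L)
  expect_false(anyDuplicated(out$records$position) > 0)  # without replacement
  scan <- find_homoplasies(fx$tree, out$alignment)
  flagged <- scan$sites$position[scan$sites$is_inconsistent]
  expect_true(all(out$records$position %in% flagged))
})

test_that("donor and recipient are non-nested internal nodes, never the root", {
  fx <- insertion_fixture(419)
  out <- insert_homoplasies(fx$tree, fx$ob$alignment, 10)
  ntip <- length(fx$tree$tip.label)
  root <- ntip + 1L
  clades <- homoplasyscan:::clade_tip_sets(fx$tree)
  for (r in seq_len(nrow(out$records))) {
    i <- out$records$donor[r]; j <- out$records$recipient[r]
    expect_true(i > ntip && j > ntip)
    expect_true(i != root && j != root)
    expect_length(intersect(clades[[i - ntip]], clades[[j - ntip]]), 0L)
  }
})

test_that("insertion overwrites the recipient clade with the donor allele", {
  fx <- insertion_fixture(420)
  out <- insert_homoplasies(fx$tree, fx$ob$alignment, 3)
  ntip <- length(fx$tree$tip.label)
  clades <- homoplasyscan:::clade_tip_sets(fx$tree)
  for (r in seq_len(nrow(out$records))) {
    s <- out$records$position[r]
    donor_tips <- fx$tree$tip.label[clades[[out$records$donor[r] - ntip]]]
    recip_tips <- fx$tree$tip.label[clades[[out$records$recipient[r] - ntip]]]
    allele <- unique(out$alignment[donor_tips, s])
    expect_length(allele, 1L)
    expect_true(all(out$alignment[recip_tips, s] == allele))
  }
})

test_that("insertion fails loudly when eligibility is exhausted", {
  # two sequences per clade, almost no unique monomorphic sites
  aln <- rbind(a = c("A", "A"), b = c("A", "A"), c = c("A", "A"), d = c("A", "A"))
  tree <- parse_newick("((a,b),(c,d));")
  expect_error(insert_homoplasies(tree, aln, 2, max_tries = 50),
               "placed 0 of 2")
})

test_that("zero recombination events is the identity", {
  fx <- insertion_fixture(421)
  out <- insert_recombination(fx$tree, fx$ob$alignment, 0)
  expect_identical(out$alignment[rownames(fx$ob$alignment), ], fx$ob$alignment)
  expect_equal(nrow(out$events), 0L)
})

test_that("recombination copies the donor consensus into the recipient clade", {
  set.seed(422)
  fx <- insertion_fixture(422)
  out <- insert_recombination(fx$tree, fx$ob$alignment, 5, region_length = 50)
  ntip <- length(fx$tree$tip.label)
  clades <- homoplasyscan:::clade_tip_sets(fx$tree)
  last <- nrow(out$events)  # later events may overwrite earlier regions; check the last
  s <- out$events$start[last]
  cols <- s:(s + 49L)
  donor_tips <- fx$tree$tip.label[clades[[out$events$donor[last] - ntip]]]
  recip_tips <- fx$tree$tip.label[clades[[out$events$recipient[last] - ntip]]]
  cons <- apply(out$alignment[donor_tips, cols, drop = FALSE], 2, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(counts)[which.max(counts)]  # which.max takes the first = A<C<G<T
  })
  rec_rows <- out$alignment[recip_tips, cols, drop = FALSE]
  expect_true(all(t(rec_rows) == cons))
})

test_that("recombination requires the alignment to cover the region", {
  aln <- matrix("A", 4, 10, dimnames = list(c("a", "b", "c", "d"), NULL))
  tree <- parse_newick("((a,b),(c,d));")
  expect_error(insert_recombination(tree, aln, 1, region_length = 100),
               "shorter than")
})
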