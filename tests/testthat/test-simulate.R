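# Small outbreak configuration used where the full study scale is not needed
small_config <- function(...) {
  simulation_config(n_individuals = 60L, stop_after_sampled = 30L, ...)
}

test_that("configuration validation rejects out-of-range parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(infectiousness = 1.5))
  expect_error(simulation_config(sampling_prob = -0.1))
  expect_error(simulation_config(stop_after_sampled = 300))
  expect_error(simulation_config(n_homoplasies = -1))
})

test_that("without mutation all sampled sequences are identical", {
  set.seed(412)
  ob <- simulate_outbreak(small_config(mutation_rate = 0))
  expect_equal(nrow(ob$alignment), 30L)
  expect_equal(ob$n_sites, 0L)
  expect_equal(ncol(ob$alignment), 0L)
})

test_that("an epidemic that cannot reach the quota errors after bounded restarts", {
  set.seed(413)
  cfg <- simulation_config(n_individuals = 5L, infectiousness = 0,
                           sampling_prob = 1, stop_after_sampled = 2L,
                           max_restarts = 3L)
  expect_error(simulate_outbreak(cfg), "died out in all 3 attempts")
})

test_that("the realised mutation rate matches its Poisson mean", {
  set.seed(414)
  ob <- simulate_outbreak(simulation_config())
  rate <- ob$n_mutation_events / ob$n_infected_steps
  se <- sqrt(0.5 / ob$n_infected_steps)
  expect_lt(abs(rate - 0.5), 3 * se)
  expect_equal(ob$n_sites, ob$n_mutation_events)
})

test_that("outbreaks are reproducible from the seed", {
  set.seed(99); ob1 <- simulate_outbreak(small_config())
  set.seed(99); ob2 <- simulate_outbreak(small_config())
  expect_identical(ob1$alignment, ob2$alignment)
  expect_identical(ob1$transmissions, ob2$transmissions)
})

test_that("the true transmission genealogy is consistent with the samples", {
  set.seed(415)
  ob <- simulate_outbreak(small_config())
  expect_s3_class(ob$true_tree, "phylo")
  expect_setequal(ob$true_tree$tip.label, rownames(ob$alignment))
  # infinite-sites mutations on the true genealogy cannot be homoplasious
  scan <- find_homoplasies(ob$true_tree, ob$alignment)
  expect_equal(scan$n_inconsistent, 0L)
})

test_that("neighbour joining recovers additive trees exactly", {
  # perfect phylogenetic signal: one derived site per edge, so Hamming
  # distances are additive on the generating tree
  set.seed(416)
  gen <- ape::rtree(5)
  aln <- perfect_alignment(gen)
  rebuilt <- build_nj_tree(aln)
  expect_equal(ape::dist.topo(ape::unroot(rebuilt), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  # branch lengths equal the per-edge mutation counts (here, 1 per edge)
  d_in <- homoplasyscan:::hamming_distance_matrix(aln)
  d_out <- ape::cophenetic.phylo(rebuilt)[rownames(d_in), colnames(d_in)]
  expect_equal(d_out, d_in, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate distance inputs are handled", {
  aln <- matrix("A", 4, 5, dimnames = list(paste0("s", 1:4), NULL))
  tr <- build_nj_tree(aln)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length == 0))
  expect_error(build_nj_tree(aln[1:2, ]), "at least 3")
})

test_that("pairwise distances skip ambiguous characters", {
  aln <- rbind(a = c("A", "N", "G"), b = c("A", "C", "T"), c = c("T", "C", "T"))
  d <- homoplasyscan:::hamming_distance_matrix(aln)
  expect_equal(d["a", "b"], 1)  # site 2 skipped (N), site 3 differs
  expect_equal(d["b", "c"], 1)
  expect_equal(d["a", "c"], 2)
})
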