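# Fixtures are built in code; nothing is read from disk.

AMBIG_CODES <- c("N", "-", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# random rooted binary tree + one random site pattern (optionally with
# ambiguity codes), as used by the oracle-equivalence properties
random_site_instance <- function(ntip = sample(4:10, 1), p_ambig = 0.3) {
  tree <- ape::rtree(ntip)
  chars <- sample(c("A", "C", "G", "T"), ntip, replace = TRUE)
  amb <- stats::runif(ntip) < p_ambig
  if (any(amb)) chars[amb] <- sample(AMBIG_CODES, sum(amb), replace = TRUE)
  list(tree = tree, chars = stats::setNames(chars, tree$tip.label))
}

# collapse some internal edges of a random binary tree into polytomies
random_polytomy_tree <- function(ntip = sample(5:10, 1)) {
  tree <- ape::rtree(ntip)
  internal <- which(tree$edge[, 2] > ntip)
  drop <- internal[stats::runif(length(internal)) < 0.5]
  tree$edge.length[drop] <- 0
  ape::di2multi(tree, tol = 1e-8)
}

one_site_alignment <- function(chars) {
  matrix(chars, ncol = 1, dimnames = list(names(chars), NULL))
}

# an alignment with perfect phylogenetic signal on `tree`: one unique derived
# site per edge (infinite-sites on the tree itself)
perfect_alignment <- function(tree) {
  ntip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  kids <- homoplasyscan:::children_list(tree)
  tips_under <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[v]], tips_under))
  }
  aln <- matrix("A", ntip, n_edge, dimnames = list(tree$tip.label, NULL))
  for (e in seq_len(n_edge)) {
    aln[tips_under(tree$edge[e, 2]), e] <- "G"
  }
  aln
}

quartet_tree <- function() parse_newick("((A,B),(C,D));")

# the worked quartet: site 1 homoplasious (A/T/A/T), site 2 clean (A/A/T/T),
# site 3 invariant
quartet_alignment <- function() {
  rbind(A = c("A", "A", "C"),
        B = c("T", "A", "C"),
        C = c("A", "T", "C"),
        D = c("T", "T", "C"))
}

write_tmp_fasta <- function(aln, path = tempfile(fileext = ".fasta")) {
  write_fasta(aln, path)
  path
}
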