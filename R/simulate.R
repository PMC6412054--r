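#' Configuration for the outbreak validation simulations
#'
#' Bundles every parameter of the validation study. The defaults are the
#' study conditions: a closed population of 200 individuals, per-pair
#' infectiousness 0.001 per time-step, sequences gaining Poisson(0.5)
#' mutations per time-step (on average one every two steps) at previously
#' unused positions (infinite-sites), each infected individual sampled
#' (removed and recorded) with probability 0.05 per step, and the epidemic run
#' until 100 individuals have been sampled.
#'
#' @param n_individuals Population size.
#' @param infectiousness Per infected-susceptible pair transmission
#'   probability per time-step.
#' @param mutation_rate Poisson mean number of mutations per infected
#'   individual per time-step.
#' @param sampling_prob Probability an infected individual is sampled
#'   (removed, sequence recorded) per time-step.
#' @param stop_after_sampled Number of sampled sequences at which the
#'   simulation stops.
#' @param n_homoplasies Number of homoplasies to insert per replicate in
#'   [run_detection_experiment()]; `NULL` (the default) draws the number
#'   uniformly from 0 to 100 per replicate.
#' @param n_recombination Number of recombination events to apply per
#'   replicate (0 = none).
#' @param recombination_length Length in sites of each recombined region.
#' @param max_restarts Maximum number of fresh attempts when the epidemic dies
#'   out before the sampling quota is reached.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 200L,
                              infectiousness = 0.001,
                              mutation_rate = 0.5,
                              sampling_prob = 0.05,
                              stop_after_sampled = 100L,
                              n_homoplasies = NULL,
                              n_recombination = 0L,
                              recombination_length = 100L,
                              max_restarts = 100L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              infectiousness = infectiousness,
              mutation_rate = mutation_rate,
              sampling_prob = sampling_prob,
              stop_after_sampled = as.integer(stop_after_sampled),
              n_homoplasies = if (!is.null(n_homoplasies)) as.integer(n_homoplasies),
              n_recombination = as.integer(n_recombination),
              recombination_length = as.integer(recombination_length),
              max_restarts = as.integer(max_restarts))
  with(cfg, {
    stopifnot(n_individuals >= 1L,
              infectiousness >= 0, infectiousness <= 1,
              sampling_prob >= 0, sampling_prob <= 1,
              mutation_rate >= 0,
              stop_after_sampled >= 1L,
              stop_after_sampled <= n_individuals,
              n_recombination >= 0L,
              recombination_length >= 1L,
              max_restarts >= 1L)
    if (!is.null(n_homoplasies)) stopifnot(n_homoplasies >= 0L)
  })
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Outbreak simulation configuration:\n")
  cat(sprintf("  population %d, infectiousness %g/pair/step, mutations Poisson(%g)/step\n",
              x$n_individuals, x$infectiousness, x$mutation_rate))
  cat(sprintf("  sampling %g/step, stop after %d sampled\n",
              x$sampling_prob, x$stop_after_sampled))
  cat(sprintf("  insertions: %s homoplasies, %d recombination events (%d bp regions)\n",
              if (is.null(x$n_homoplasies)) "uniform 0-100" else x$n_homoplasies,
              x$n_recombination, x$recombination_length))
  invisible(x)
}

#' Simulate a sampled transmission chain of mutating sequences
#'
#' Discrete-time stochastic simulation: a single infected individual seeds a
#' closed susceptible population; each step, every infected individual infects
#' each susceptible with the configured per-pair probability (the recipient
#' copies the donor's current sequence), every infected sequence gains a
#' Poisson number of mutations at brand-new positions (infinite-sites: the
#' site registry grows as mutations occur), and every infected individual is
#' sampled with the configured probability, removing it and recording its
#' sequence. The run stops when the sampling quota is reached; if the epidemic
#' goes extinct first, the simulation restarts (same RNG stream) up to
#' `max_restarts` times.
#'
#' On return, sampled sequences are padded to the full site registry with the
#' ancestral allele (drawn uniformly per site; the mutant allele is drawn
#' uniformly from the other three nucleotides). The true genealogy of the
#' samples is reconstructed from the transmission events: lineages split where
#' transmission occurred, terminate where sampling occurred, and lineages that
#' lead to no sampled individual are pruned (unary nodes collapsed, branch
#' lengths in time-steps).
#'
#' @param config A [simulation_config()].
#' @return An object of class `sampled_outbreak` with elements `alignment`
#'   (character matrix, samples x sites), `true_tree` (`phylo`, `NULL` when
#'   fewer than 2 samples), `transmissions` (data frame: donor, recipient,
#'   time), `n_sites`, `n_mutation_events`, `n_infected_steps`, `duration`
#'   (time-steps of the successful run) and `restarts`.
#' @export
simulate_outbreak <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  for (attempt in seq_len(config$max_restarts)) {
    res <- run_epidemic_once(config)
    if (!is.null(res)) {
      res$restarts <- attempt - 1L
      return(res)
    }
  }
  stop("epidemic died out in all ", config$max_restarts,
       " attempts before ", config$stop_after_sampled,
       " individuals were sampled", call. = FALSE)
}

run_epidemic_once <- function(config) {
  n <- config$n_individuals
  quota <- config$stop_after_sampled
  status <- integer(n)          # 0 susceptible, 1 infected, 2 sampled
  status[1L] <- 1L
  muts <- vector("list", n)     # per-individual mutation (site id) sets
  muts[[1L]] <- integer(0)
  next_site <- 0L

  # genealogy bookkeeping: nodes are created at transmission (internal) and
  # sampling (leaf) events; lineage[i] is the node individual i's growing
  # branch currently hangs from
  node_parent <- integer(0)
  node_time <- numeric(0)
  node_label <- character(0)
  new_node <- function(parent, time, label = NA_character_) {
    node_parent[length(node_parent) + 1L] <<- parent
    node_time[length(node_time) + 1L] <<- time
    node_label[length(node_label) + 1L] <<- label
    length(node_parent)
  }
  lineage <- rep(NA_integer_, n)
  lineage[1L] <- new_node(0L, 0)

  tr_donor <- integer(0); tr_recipient <- integer(0); tr_time <- numeric(0)
  sample_sets <- vector("list", quota)
  n_sampled <- 0L
  t <- 0L
  mut_events <- 0L
  infected_steps <- 0L

  while (n_sampled < quota) {
    t <- t + 1L
    inf <- which(status == 1L)
    if (!length(inf)) return(NULL)  # extinct before quota

    # transmission: each susceptible escapes all current infecteds independently
    sus <- which(status == 0L)
    if (length(sus)) {
      p <- 1 - (1 - config$infectiousness)^length(inf)
      newly <- sus[stats::runif(length(sus)) < p]
      if (length(newly)) {
        donors <- inf[sample.int(length(inf), length(newly), replace = TRUE)]
        for (ii in seq_along(newly)) {
          b <- newly[ii]; a <- donors[ii]
          muts[[b]] <- muts[[a]]
          nid <- new_node(lineage[a], t)
          lineage[a] <- nid
          lineage[b] <- nid
          status[b] <- 1L
          tr_donor <- c(tr_donor, a)
          tr_recipient <- c(tr_recipient, b)
          tr_time <- c(tr_time, t)
        }
        inf <- which(status == 1L)
      }
    }

    # mutation: every infected sequence, at previously unused positions
    k <- stats::rpois(length(inf), config$mutation_rate)
    tot <- sum(k)
    if (tot) {
      off <- 0L
      for (ii in seq_along(inf)) {
        if (k[ii]) {
          muts[[inf[ii]]] <- c(muts[[inf[ii]]], next_site + off + seq_len(k[ii]))
          off <- off + k[ii]
        }
      }
      next_site <- next_site + tot
    }
    mut_events <- mut_events + tot
    infected_steps <- infected_steps + length(inf)

    # sampling: remove and record, stopping exactly at the quota
    samp <- inf[stats::runif(length(inf)) < config$sampling_prob]
    for (s in samp) {
      if (n_sampled >= quota) break
      n_sampled <- n_sampled + 1L
      new_node(lineage[s], t, label = sprintf("sample_%d", n_sampled))
      status[s] <- 2L
      sample_sets[[n_sampled]] <- muts[[s]]
    }
  }

  labels <- sprintf("sample_%d", seq_len(quota))
  aln <- pad_to_registry(sample_sets, labels, next_site)
  true_tree <- if (quota >= 2L) {
    genealogy_to_phylo(node_parent, node_time, node_label)
  }

  structure(list(
    alignment = aln,
    true_tree = true_tree,
    transmissions = data.frame(donor = tr_donor, recipient = tr_recipient,
                               time = tr_time),
    n_sites = next_site,
    n_mutation_events = mut_events,
    n_infected_steps = infected_steps,
    duration = t,
    restarts = 0L
  ), class = "sampled_outbreak")
}

# Expand per-sample mutation sets to a full character alignment: ancestral
# allele uniform on ACGT per site, mutant allele uniform on the other three.
pad_to_registry <- function(sample_sets, labels, n_sites) {
  anc_idx <- if (n_sites) sample.int(4L, n_sites, replace = TRUE) else integer(0)
  shift <- if (n_sites) sample.int(3L, n_sites, replace = TRUE) else integer(0)
  mut_idx <- ((anc_idx - 1L + shift) %% 4L) + 1L
  aln <- matrix(NUCLEOTIDES[anc_idx], nrow = length(labels), ncol = n_sites,
                byrow = TRUE, dimnames = list(labels, NULL))
  for (i in seq_along(sample_sets)) {
    s <- sample_sets[[i]]
    if (length(s)) aln[i, s] <- NUCLEOTIDES[mut_idx[s]]
  }
  aln
}

#' @export
print.sampled_outbreak <- function(x, ...) {
  cat(sprintf("Sampled outbreak: %d sequences, %d sites (%d mutation events over %d time-steps%s)\n",
              nrow(x$alignment), x$n_sites, x$n_mutation_events, x$duration,
              if (x$restarts) sprintf(", %d restarts", x$restarts) else ""))
  invisible(x)
}

# Build the pruned sampled genealogy: keep only nodes with a sampled
# descendant, collapse unary chains, branch lengths = time differences.
genealogy_to_phylo <- function(node_parent, node_time, node_label) {
  nn <- length(node_parent)
  keep <- !is.na(node_label)
  for (v in rev(seq_len(nn))) {  # parents are always created before children
    if (keep[v] && node_parent[v] > 0L) keep[node_parent[v]] <- TRUE
  }
  kids <- vector("list", nn)
  for (v in seq_len(nn)) {
    p <- node_parent[v]
    if (keep[v] && p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  build <- function(v, parent_time) {
    len <- node_time[v] - parent_time
    if (!is.na(node_label[v])) {
      list(children = list(), label = node_label[v], comment = "", length = len)
    } else {
      list(children = lapply(kids[[v]], build, parent_time = node_time[v]),
           label = "", comment = "", length = len)
    }
  }
  root <- which(keep & node_parent == 0L)[1L]
  nested <- collapse_unary(build(root, node_time[root]))
  nested_to_phylo(nested)
}

#' Build a neighbour-joining tree from an alignment
#'
#' Distance-based tree rebuilder used by the validation harness: pairwise
#' Hamming distances (sites where either sequence carries an ambiguous
#' character or gap are skipped for that pair), neighbour joining
#' ([ape::nj()]), negative branch lengths clamped to zero, and midpoint
#' rooting ([phangorn::midpoint()]).
#'
#' @param alignment Character matrix with at least 3 sequences.
#' @return A rooted `phylo` tree.
#' @export
build_nj_tree <- function(alignment) {
  aln <- as_alignment(alignment)
  if (nrow(aln) < 3L) stop("need at least 3 sequences to build a tree", call. = FALSE)
  d <- hamming_distance_matrix(aln)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- tryCatch(phangorn::midpoint(tr), error = function(e) tr)
  if (!is.null(tr$edge.length)) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Pairwise Hamming distances; positions with non-ACGT characters in either
# sequence of a pair are excluded for that pair.
hamming_distance_matrix <- function(aln) {
  X <- match(aln, NUCLEOTIDES)
  dim(X) <- dim(aln)
  V <- !is.na(X)
  valid <- tcrossprod(V * 1)
  matches <- matrix(0, nrow(aln), nrow(aln))
  for (b in 1:4) {
    B <- X == b
    B[!V] <- FALSE
    matches <- matches + tcrossprod(B * 1)
  }
  d <- valid - matches
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

## ---- insertion of known homoplasies and recombination ----------------------

# tip ids below every internal node, indexed by (node id - ntip)
clade_tip_sets <- function(tree, kids = children_list(tree)) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", tree$Nnode)
  for (v in postorder_internal(tree, kids)) {
    tips <- integer(0)
    for (child in kids[[v]]) {
      tips <- c(tips, if (child <= ntip) child else sets[[child - ntip]])
    }
    sets[[v - ntip]] <- tips
  }
  sets
}

# Exact parsimony check for one site pattern (named character vector over the
# tree's tips): is it inconsistent with the tree?
site_is_homoplasious <- function(tree, chars) {
  chars <- chars[tree$tip.label]
  bits <- matrix(CHAR_BITS[toupper(chars)], ncol = 1L)
  tl <- fitch_engine(tree, bits)$tree_length
  n_states <- sum(vapply(NUCLEOTIDES, function(b) any(chars == b), logical(1)))
  n_states >= 2L && tl > n_states - 1L
}

#' Insert known homoplasies into an alignment
#'
#' Repeats `count` times: draw a random pair of non-nested internal nodes
#' (neither an ancestor of the other, neither the root, tips excluded); among
#' the sites at which the donor clade is monomorphic for an unambiguous
#' nucleotide found nowhere outside the clade, pick one at random (without
#' replacement across insertions) and assign the donor's nucleotide to every
#' tip below the recipient node. A candidate insertion is accepted only if the
#' resulting site pattern is actually inconsistent with `tree` (single-site
#' parsimony check) — e.g. a donor and recipient that are sister clades would
#' merely create a larger consistent clade, which is not a homoplasy — so
#' every recorded insertion is guaranteed to be flagged by
#' [find_homoplasies()] against the pre-insertion tree.
#'
#' @param tree The tree on which the pair is drawn (typically rebuilt from
#'   `alignment`).
#' @param alignment Character matrix; row names must match the tree's tips.
#' @param count Number of homoplasies to insert.
#' @param max_tries Total draw budget before giving up.
#' @return List with `alignment` (modified copy) and `records` (data frame:
#'   `position`, `donor`, `recipient` node ids, `kind`).
#' @export
insert_homoplasies <- function(tree, alignment, count, max_tries = 200L * max(count, 1L)) {
  aln <- match_tree_alignment(tree, as_alignment(alignment))
  ntip <- length(tree$tip.label)
  L <- ncol(aln)
  count <- as.integer(count)
  stopifnot(count >= 0L)
  rec <- data.frame(position = integer(0), donor = integer(0),
                    recipient = integer(0), kind = character(0))
  if (count == 0L) {
    return(list(alignment = aln, records = rec))
  }

  clades <- clade_tip_sets(tree)
  cand <- setdiff(ntip + seq_len(tree$Nnode), ntip + 1L)  # internal, non-root
  if (length(cand) < 2L) stop("tree has too few internal nodes", call. = FALSE)

  if (L == 0L) stop("alignment has no sites", call. = FALSE)
  # global unambiguous base counts per site, maintained under edits
  counts <- base_counts(aln)

  used <- logical(L)
  tries <- 0L
  positions <- integer(count); donors <- integer(count); recips <- integer(count)
  placed <- 0L

  while (placed < count) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf("ran out of eligible homoplasy insertions: placed %d of %d",
                   placed, count), call. = FALSE)
    }
    pair <- cand[sample.int(length(cand), 2L)]
    ti <- clades[[pair[1L] - ntip]]
    tj <- clades[[pair[2L] - ntip]]
    if (length(intersect(ti, tj))) next  # nested or overlapping

    sub <- aln[ti, , drop = FALSE]
    a1 <- sub[1L, ]
    mono <- .colSums(sub != matrix(a1, length(ti), L, byrow = TRUE), length(ti), L) == 0
    gidx <- match(a1, NUCLEOTIDES)
    tot <- rep(NA_real_, L)
    ok <- !is.na(gidx)
    tot[ok] <- counts[cbind(seq_len(L)[ok], gidx[ok])]
    elig <- which(mono & ok & tot == length(ti) & !used)
    if (!length(elig)) next

    for (s in sample_safe(elig, min(5L, length(elig)))) {
      newcol <- aln[, s]
      newcol[tj] <- a1[s]
      if (site_is_homoplasious(tree, newcol)) {
        old <- aln[tj, s]
        aln[tj, s] <- a1[s]
        # update counts at site s
        for (b in unique(old)) {
          bi <- match(b, NUCLEOTIDES)
          if (!is.na(bi)) counts[s, bi] <- counts[s, bi] - sum(old == b)
        }
        counts[s, gidx[s]] <- counts[s, gidx[s]] + length(tj)
        used[s] <- TRUE
        placed <- placed + 1L
        positions[placed] <- s
        donors[placed] <- pair[1L]
        recips[placed] <- pair[2L]
        break
      }
    }
  }

  list(alignment = aln,
       records = data.frame(position = positions, donor = donors,
                            recipient = recips, kind = "homoplasy"))
}

# sample() without the length-1 surprise
sample_safe <- function(x, size) {
  if (length(x) == 1L) return(x)
  sample(x, size)
}

#' Apply recombination events to an alignment
#'
#' Per event: draw a random pair of non-nested internal nodes (donor `i`,
#' recipient `j`), draw a random contiguous region of `region_length` sites,
#' compute the per-site majority (consensus) nucleotide among the donor
#' clade's tips (ties broken in the fixed order A < C < G < T; sites with no
#' unambiguous donor call are left untouched), and overwrite that region in
#' every tip below the recipient.
#'
#' @param tree Tree on which node pairs are drawn.
#' @param alignment Character matrix; must be at least `region_length` sites.
#' @param n_events Number of recombination events.
#' @param region_length Length of each transferred region.
#' @param max_tries Pair-draw budget per event.
#' @return List with `alignment` (modified copy) and `events` (data frame:
#'   `start`, `donor`, `recipient`).
#' @export
insert_recombination <- function(tree, alignment, n_events, region_length = 100L,
                                 max_tries = 1000L) {
  aln <- match_tree_alignment(tree, as_alignment(alignment))
  ntip <- length(tree$tip.label)
  L <- ncol(aln)
  region_length <- as.integer(region_length)
  if (L < region_length) {
    stop("alignment (", L, " sites) shorter than recombination region (",
         region_length, ")", call. = FALSE)
  }
  clades <- clade_tip_sets(tree)
  cand <- setdiff(ntip + seq_len(tree$Nnode), ntip + 1L)
  starts <- integer(n_events); donors <- integer(n_events); recips <- integer(n_events)

  for (e in seq_len(n_events)) {
    ti <- tj <- NULL
    for (try in seq_len(max_tries)) {
      pair <- cand[sample.int(length(cand), 2L)]
      ti <- clades[[pair[1L] - ntip]]
      tj <- clades[[pair[2L] - ntip]]
      if (!length(intersect(ti, tj))) break
      ti <- NULL
    }
    if (is.null(ti)) stop("no non-nested node pair found", call. = FALSE)
    start <- sample.int(L - region_length + 1L, 1L)
    cols <- start:(start + region_length - 1L)
    sub <- aln[ti, cols, drop = FALSE]
    cnt <- base_counts(sub)
    cons <- NUCLEOTIDES[max.col(cnt, ties.method = "first")]
    no_call <- rowSums(cnt) == 0
    repl <- matrix(cons, length(tj), region_length, byrow = TRUE)
    if (any(no_call)) repl[, no_call] <- aln[tj, cols[no_call]]
    aln[tj, cols] <- repl
    starts[e] <- start; donors[e] <- pair[1L]; recips[e] <- pair[2L]
  }

  list(alignment = aln,
       events = data.frame(start = starts, donor = donors, recipient = recips))
}
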