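# Nucleotide state sets are held as 4-bit masks: A=1, C=2, G=4, T=8.
NUCLEOTIDES <- c("A", "C", "G", "T")
NUC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# IUPAC expansion. Gaps and N carry no information for the parsimony downpass
# and expand to the full set; U is read as T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T")
)
CHAR_BITS <- vapply(IUPAC_SETS, function(s) sum(NUC_BITS[s]), integer(1))

#' Expand an alignment character to its nucleotide set
#'
#' Maps one alignment character (case-insensitive) to the set of nucleotides
#' it may represent: `A`/`C`/`G`/`T` map to themselves, `U` to `T`, the IUPAC
#' ambiguity codes to their standard expansions (`R` to A/G, `Y` to C/T, ...),
#' and `N` and the gap character `-` to the full set A/C/G/T.
#'
#' @param character A single alignment character.
#' @return Character vector of nucleotides (subset of A, C, G, T).
#' @examples
#' expand_state("N")  # "A" "C" "G" "T"
#' expand_state("r")  # "A" "G"
#' @export
expand_state <- function(character) {
  if (!is.character(character) || length(character) != 1L || nchar(character) != 1L) {
    stop("expected a single character", call. = FALSE)
  }
  ch <- toupper(character)
  if (!ch %in% names(IUPAC_SETS)) {
    stop("unrecognised nucleotide character '", character, "'", call. = FALSE)
  }
  IUPAC_SETS[[ch]]
}

# Per-site counts of unambiguous A/C/G/T calls: sites x 4 matrix.
base_counts <- function(aln) {
  L <- ncol(aln)
  n <- nrow(aln)
  out <- matrix(0, L, 4L, dimnames = list(NULL, NUCLEOTIDES))
  for (b in 1:4) out[, b] <- .colSums(aln == NUCLEOTIDES[b], n, L)
  out
}

# Character matrix -> integer bitmask matrix; errors name the offending
# sequence, site and character.
encode_alignment <- function(aln) {
  bits <- CHAR_BITS[aln]
  dim(bits) <- dim(aln)
  if (anyNA(bits)) {
    idx <- which(is.na(bits))[1L]
    r <- (idx - 1L) %% nrow(aln) + 1L
    s <- (idx - 1L) %/% nrow(aln) + 1L
    stop(sprintf("unrecognised character '%s' in sequence '%s' at site %d",
                 aln[r, s], rownames(aln)[r], s), call. = FALSE)
  }
  rownames(bits) <- rownames(aln)
  bits
}

#' Per-site minimum number of changes on a tree (Fitch downpass)
#'
#' For every alignment site, computes the minimum number of nucleotide state
#' changes the tree requires to explain the tip states (the per-site tree
#' length), using a single post-order traversal: each tip carries the
#' nucleotide set of its character (see [expand_state()]); at each internal
#' node the child sets are folded left to right in file order, taking the
#' intersection where it is non-empty and otherwise the union, incrementing
#' that site's change count. On binary trees this is the exact parsimony
#' length. On multifurcations the fold scores the caterpillar (left-to-right)
#' resolution of each node, which never exceeds — and can fall below — the
#' exact minimum on the multifurcating tree itself; it never falls below the
#' `n_states - 1` floor, so consistency indices stay in (0, 1].
#'
#' @param tree A rooted `phylo` tree.
#' @param alignment Character matrix (see [read_fasta()]) whose row names
#'   match `tree$tip.label` exactly.
#' @return Integer vector of per-site tree lengths.
#' @export
fitch_site_lengths <- function(tree, alignment) {
  aln <- match_tree_alignment(tree, as_alignment(alignment))
  fitch_engine(tree, encode_alignment(aln))$tree_length
}

# Downpass engine over bitmask matrix `bits` (rows in tree tip order).
# Returns per-site lengths, per-internal-node "took >= 1 union at this site"
# indicators (annotation targets), and the final node sets.
fitch_engine <- function(tree, bits) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  L <- ncol(bits)
  kids <- children_list(tree)
  po <- postorder_internal(tree, kids)

  sets <- matrix(0L, ntip + nint, L)
  if (L > 0L && ntip > 0L) sets[seq_len(ntip), ] <- bits
  lens <- integer(L)
  union_any <- matrix(FALSE, nint, L)

  for (v in po) {
    ch <- kids[[v]]
    acc <- sets[ch[1L], ]
    for (k in ch[-1L]) {
      cs <- sets[k, ]
      inter <- bitwAnd(acc, cs)
      z <- inter == 0L
      if (any(z)) {
        un <- bitwOr(acc, cs)
        inter[z] <- un[z]
        lens[z] <- lens[z] + 1L
        union_any[v - ntip, z] <- TRUE
      }
      acc <- inter
    }
    sets[v, ] <- acc
  }
  list(tree_length = lens, union_any = union_any, sets = sets)
}

#' Per-site consistency index
#'
#' The consistency index of a site is the minimum conceivable number of
#' changes (the number of distinct unambiguous nucleotides observed at the
#' site minus one) divided by the minimum number of changes actually required
#' on the tree. A value of 1 means the site is entirely consistent with the
#' tree (a single origin per derived state); values below 1 indicate
#' homoplasy. Invariant sites (and sites with at most one unambiguous call)
#' are defined to have index 1: they cannot be inconsistent.
#'
#' @param tree_length Integer vector of per-site minimum changes on the tree
#'   (see [fitch_site_lengths()]).
#' @param n_states Integer vector of distinct unambiguous nucleotides observed
#'   per site.
#' @return Numeric vector of consistency indices in (0, 1].
#' @export
consistency_index <- function(tree_length, n_states) {
  stopifnot(length(tree_length) == length(n_states))
  if (any(tree_length < 0) || any(n_states < 0)) {
    stop("tree_length and n_states must be non-negative", call. = FALSE)
  }
  bad <- n_states >= 2L & tree_length == 0L
  if (any(bad)) {
    stop("internal error: site with >= 2 observed states but tree length 0 (site ",
         which(bad)[1L], ")", call. = FALSE)
  }
  ci <- rep(1, length(tree_length))
  div <- n_states >= 2L
  ci[div] <- (n_states[div] - 1) / tree_length[div]
  ci
}

#' Exact minimum changes by exhaustive enumeration (test oracle)
#'
#' Computes the exact minimum, over every assignment of one nucleotide to each
#' internal node (and, implicitly, the best choice for each ambiguous tip), of
#' the number of branches whose endpoint states differ. This is a brute-force
#' enumeration over all `4^Nnode` internal assignments, independent of the
#' downpass in [fitch_site_lengths()], and is intended as a correctness oracle
#' on small trees.
#'
#' @param tree A rooted `phylo` tree with at most 12 tips.
#' @param site_states The tip states at one site: either a character vector of
#'   single (possibly ambiguous) characters, or a list of nucleotide sets, one
#'   per tip, in `tree$tip.label` order (or named by tip label).
#' @return The exact minimum number of changes (integer).
#' @export
oracle_min_changes <- function(tree, site_states) {
  ntip <- length(tree$tip.label)
  if (ntip > 12L) {
    stop("exhaustive oracle limited to trees with at most 12 tips", call. = FALSE)
  }
  if (is.list(site_states)) {
    tip_bits <- vapply(site_states, function(s) sum(NUC_BITS[toupper(s)]), integer(1))
  } else {
    tip_bits <- CHAR_BITS[toupper(site_states)]
    if (anyNA(tip_bits)) {
      stop("unrecognised tip state '",
           site_states[which(is.na(tip_bits))[1L]], "'", call. = FALSE)
    }
    names(tip_bits) <- names(site_states)
  }
  if (!is.null(names(site_states))) tip_bits <- tip_bits[tree$tip.label]
  if (length(tip_bits) != ntip || anyNA(tip_bits)) {
    stop("need one state per tip", call. = FALSE)
  }

  k <- tree$Nnode
  total <- 4^k
  idx <- seq_len(total) - 1
  pow <- 4^(seq_len(k) - 1)
  st <- vector("list", k)  # lazily decoded state (0..3) of each internal node
  get_st <- function(m) {
    if (is.null(st[[m]])) st[[m]] <<- as.integer((idx %/% pow[m]) %% 4)
    st[[m]]
  }

  cost <- numeric(total)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L] - ntip
    child <- tree$edge[e, 2L]
    ps <- get_st(p)
    if (child > ntip) {
      cost <- cost + (ps != get_st(child - ntip))
    } else {
      allowed <- bitwAnd(bitwShiftL(1L, ps), tip_bits[child]) > 0L
      cost <- cost + !allowed
    }
  }
  as.integer(min(cost))
}

# Require a strict 1:1 match between tree tips and alignment rows; return the
# alignment reordered to tree tip order. Labels are compared after stripping
# surrounding quotes and whitespace.
match_tree_alignment <- function(tree, aln) {
  clean <- function(x) gsub("^['\"]|['\"]$", "", trimws(x))
  tl <- clean(tree$tip.label)
  al <- clean(rownames(aln))
  missing_aln <- setdiff(tl, al)
  missing_tree <- setdiff(al, tl)
  if (length(missing_aln) || length(missing_tree)) {
    stop("tree tips and alignment labels do not match",
         if (length(missing_aln)) paste0("; in tree only: ",
                                         paste(missing_aln, collapse = ", ")),
         if (length(missing_tree)) paste0("; in alignment only: ",
                                          paste(missing_tree, collapse = ", ")),
         call. = FALSE)
  }
  aln[match(tl, al), , drop = FALSE]
}
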