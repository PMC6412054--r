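#' Find homoplasious sites on a rooted phylogeny
#'
#' The package's main entry point. For every alignment site it computes the
#' minimum number of changes on the tree ([fitch_site_lengths()]), derives the
#' consistency index ([consistency_index()]), and flags every site whose index
#' is below 1 as inconsistent (potentially homoplasious). Three artifacts are
#' assembled: a per-site consistency table, a copy of the alignment with the
#' inconsistent sites removed, and a copy of the tree in which every internal
#' node where the downpass required a change (took a union) for a flagged site
#' is annotated with that site's 1-based position.
#'
#' @param tree A rooted `phylo` tree ([read_newick()]). The root is used as
#'   given; no re-rooting is performed.
#' @param alignment A character matrix ([read_fasta()]) whose row names match
#'   `tree$tip.label` exactly (strict 1:1).
#' @return An object of class `homoplasy_scan` with elements:
#'   \describe{
#'     \item{sites}{data frame with one row per site: `position`,
#'       `tree_length`, `n_states`, `consistency_index`, `is_inconsistent`,
#'       `counts_acgt`.}
#'     \item{tree}{the input tree with `node.comment` annotations
#'       (`&homoplasy=<positions>`) on the internal nodes involved.}
#'     \item{alignment}{the input alignment without the inconsistent sites.}
#'     \item{n_sites, n_inconsistent, n_tips}{summary counts.}
#'   }
#' @examples
#' tree <- parse_newick("((A,B),(C,D));")
#' aln <- rbind(A = c("A","A","T"), B = c("A","T","T"),
#'              C = c("T","A","A"), D = c("T","T","A"))
#' scan <- find_homoplasies(tree, aln)
#' scan$sites
#' @seealso [write_homoplasy_outputs()], [write_report()]
#' @export
find_homoplasies <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"))
  aln_in <- as_alignment(alignment)
  aln <- match_tree_alignment(tree, aln_in)

  fit <- fitch_engine(tree, encode_alignment(aln))
  L <- ncol(aln)
  ntip <- nrow(aln)

  counts <- base_counts(aln)
  n_states <- as.integer(rowSums(counts > 0))
  ci <- consistency_index(fit$tree_length, n_states)
  flagged <- ci < 1

  sites <- data.frame(
    position = seq_len(L),
    tree_length = fit$tree_length,
    n_states = n_states,
    consistency_index = ci,
    is_inconsistent = flagged,
    counts_acgt = if (L) paste(counts[, 1], counts[, 2], counts[, 3], counts[, 4],
                               sep = ":") else character(0)
  )

  # annotate internal nodes where the downpass took a union step at a flagged site
  nc <- character(ntip + tree$Nnode)
  if (any(flagged)) {
    for (v in seq_len(tree$Nnode)) {
      pos <- which(flagged & fit$union_any[v, ])
      if (length(pos)) {
        nc[ntip + v] <- paste0("&homoplasy=", paste(pos, collapse = ","))
      }
    }
  }
  ann_tree <- tree
  ann_tree$node.comment <- nc

  structure(list(
    sites = sites,
    tree = ann_tree,
    alignment = aln_in[, !flagged, drop = FALSE],
    n_sites = L,
    n_inconsistent = sum(flagged),
    n_tips = ntip
  ), class = "homoplasy_scan")
}

#' @export
print.homoplasy_scan <- function(x, ...) {
  cat(sprintf("Homoplasy scan: %d tips, %d sites scanned, %d inconsistent\n",
              x$n_tips, x$n_sites, x$n_inconsistent))
  if (x$n_inconsistent > 0L) {
    pos <- x$sites$position[x$sites$is_inconsistent]
    shown <- utils::head(pos, 10L)
    cat("Inconsistent positions: ", paste(shown, collapse = ", "),
        if (length(pos) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.homoplasy_scan <- function(object, ...) {
  structure(list(
    n_tips = object$n_tips,
    n_sites = object$n_sites,
    n_inconsistent = object$n_inconsistent,
    flagged = object$sites[object$sites$is_inconsistent, , drop = FALSE],
    ci_table = table(round(object$sites$consistency_index, 3))
  ), class = "summary.homoplasy_scan")
}

#' @export
print.summary.homoplasy_scan <- function(x, ...) {
  cat(sprintf("Homoplasy scan of %d sites on a %d-tip tree\n", x$n_sites, x$n_tips))
  cat(sprintf("Inconsistent sites (consistency index < 1): %d\n", x$n_inconsistent))
  if (nrow(x$flagged)) {
    cat("\nPer-site detail:\n")
    print(x$flagged, row.names = FALSE)
  }
  invisible(x)
}

#' Plot an annotated homoplasy scan
#'
#' Draws the phylogeny and labels the internal nodes at which a change was
#' required for one or more inconsistent sites with those site positions.
#'
#' @param x A `homoplasy_scan` object.
#' @param ... Passed on to [ape::plot.phylo()].
#' @export
plot.homoplasy_scan <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  nc <- x$tree$node.comment
  ntip <- x$n_tips
  ann <- which(nzchar(nc)) # node ids
  if (length(ann)) {
    labs <- sub("^&homoplasy=", "", nc[ann])
    ape::nodelabels(text = labs, node = ann, frame = "rect", bg = "lightyellow",
                    cex = 0.7)
  }
  invisible(x)
}

#' Write the three scan output files
#'
#' Writes the CSV consistency report, the filtered FASTA alignment (input
#' minus the inconsistent sites) and the annotated Newick tree for a
#' [find_homoplasies()] result.
#'
#' @param scan A `homoplasy_scan` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param include_consistent Report every site, not only inconsistent ones.
#' @param report,filtered_fasta,annotated_tree Toggles for each output.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_homoplasy_outputs <- function(scan, dir = ".", prefix = "homoplasyscan",
                                    include_consistent = FALSE,
                                    report = TRUE, filtered_fasta = TRUE,
                                    annotated_tree = TRUE) {
  stopifnot(inherits(scan, "homoplasy_scan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (report) {
    p <- file.path(dir, paste0(prefix, "_consistencyIndexReport.csv"))
    write_report(scan, p, include_consistent = include_consistent)
    paths["report"] <- p
  }
  if (filtered_fasta) {
    p <- file.path(dir, paste0(prefix, "_withoutInconsistentSites.fasta"))
    write_fasta(scan$alignment, p)
    paths["filtered_fasta"] <- p
  }
  if (annotated_tree) {
    p <- file.path(dir, paste0(prefix, "_annotatedTree.nwk"))
    write_newick(scan$tree, p)
    paths["annotated_tree"] <- p
  }
  invisible(paths)
}
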