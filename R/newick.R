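#' Read a rooted Newick tree
#'
#' Parses a Newick file into an [ape::phylo] object. The tree is used exactly
#' as written: the root in the file is the root used for all downstream
#' parsimony calculations, and no re-rooting is attempted. Square-bracket
#' comment blocks attached to nodes (the dialect written by [write_newick()],
#' e.g. `[&homoplasy=12,40]`) are retained in a `node.comment` element indexed
#' by node number. Unary internal nodes (single-child nodes, which carry no
#' parsimony information) are collapsed, summing branch lengths.
#'
#' @param path Path to a file containing a single Newick string ending in `;`.
#' @return An object of class `phylo` with an additional `node.comment`
#'   character element (one entry per node, `""` where no annotation).
#' @seealso [write_newick()]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop("Newick file not found: ", path, call. = FALSE)
  }
  txt <- trimws(paste(readLines(path, warn = FALSE), collapse = ""))
  if (!nzchar(txt)) {
    stop("empty Newick file: ", path, call. = FALSE)
  }
  parse_newick(txt)
}

#' Write a tree, with node annotations, in Newick format
#'
#' Serialises a `phylo` object to Newick. If the tree carries a `node.comment`
#' element (as produced by [find_homoplasies()]), each non-empty comment is
#' emitted as a square-bracket block immediately after the node it annotates
#' and before its branch length, i.e. `(...)[&homoplasy=12]:0.1`. This is the
#' comment placement understood by FigTree/BEAST-style viewers, and the file
#' remains readable by plain Newick parsers, which skip bracketed comments.
#'
#' @param tree A `phylo` object, optionally with `node.comment`.
#' @param path Output file path.
#' @return Invisibly, the Newick string written.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  s <- deparse_newick(tree)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write Newick file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  on.exit(close(con))
  writeLines(s, con)
  invisible(s)
}

## ---- parser ----------------------------------------------------------------

#' Parse a Newick string
#'
#' Recursive-descent parser behind [read_newick()], exposed for in-memory
#' strings. Produces a nested node list, collapses unary nodes, then converts
#' to `phylo`. Parse errors carry the 1-based character offset at which
#' parsing failed.
#'
#' @param txt A Newick string terminated by `;`.
#' @return A `phylo` object (see [read_newick()]).
#' @export
parse_newick <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else ""
  fail <- function(msg) {
    stop(sprintf("Newick parse error at character %d: %s", pos, msg),
         call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= n && chars[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
  }
  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > n) fail("unterminated quoted label")
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") {  # doubled quote escape
            out <- c(out, "'")
            pos <<- pos + 2L
          } else {
            pos <<- pos + 1L
            break
          }
        } else {
          out <- c(out, ch)
          pos <<- pos + 1L
        }
      }
      return(paste(out, collapse = ""))
    }
    start <- pos
    while (pos <= n && !(chars[pos] %in% c("(", ")", ",", ":", ";", "[", "]"))) {
      pos <<- pos + 1L
    }
    trimws(paste(chars[start:(pos - 1L)][seq_len(max(0L, pos - start))], collapse = ""))
  }
  read_comment <- function() {
    if (peek() != "[") return("")
    pos <<- pos + 1L
    start <- pos
    while (pos <= n && chars[pos] != "]") pos <<- pos + 1L
    if (pos > n) fail("unterminated '[' comment")
    out <- paste(chars[start:(pos - 1L)][seq_len(max(0L, pos - start))], collapse = "")
    pos <<- pos + 1L
    out
  }
  read_length <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && (chars[pos] %in% c("0", "1", "2", "3", "4", "5", "6", "7",
                                          "8", "9", ".", "-", "+", "e", "E"))) {
      pos <<- pos + 1L
    }
    if (pos == start) fail("expected branch length after ':'")
    val <- suppressWarnings(as.numeric(paste(chars[start:(pos - 1L)], collapse = "")))
    if (is.na(val)) fail("malformed branch length")
    val
  }

  parse_clade <- function() {
    skip_ws()
    node <- list(children = list(), label = "", comment = "", length = NA_real_)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_clade()
        skip_ws()
        if (peek() == ",") {
          pos <<- pos + 1L
        } else if (peek() == ")") {
          pos <<- pos + 1L
          break
        } else {
          fail("expected ',' or ')'")
        }
      }
      node$label <- read_label()
    } else {
      node$label <- read_label()
      if (!nzchar(node$label)) fail("expected a tip label")
    }
    skip_ws()
    node$comment <- read_comment()
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      node$length <- read_length()
      skip_ws()
      if (peek() == "[") node$comment <- read_comment()  # tolerate comment after length
    }
    node
  }

  root <- parse_clade()
  skip_ws()
  if (peek() != ";") fail("expected ';' terminating the tree")
  root <- collapse_unary(root)
  nested_to_phylo(root)
}

# Splice out single-child internal nodes, summing branch lengths and keeping
# any annotation found on either node.
collapse_unary <- function(node) {
  node$children <- lapply(node$children, collapse_unary)
  while (length(node$children) == 1L) {
    child <- node$children[[1L]]
    len <- if (is.na(node$length) && is.na(child$length)) NA_real_ else
      sum(c(node$length, child$length), na.rm = TRUE)
    child$length <- len
    if (!nzchar(child$comment)) child$comment <- node$comment
    node <- child
  }
  node
}

count_nested <- function(node) {
  if (length(node$children) == 0L) return(c(tips = 1L, internal = 0L))
  kid <- Reduce(`+`, lapply(node$children, count_nested))
  kid + c(tips = 0L, internal = 1L)
}

# Convert a nested node list to an ape phylo object. Tips are numbered in the
# order they appear in the file; internal nodes in preorder starting at
# ntip + 1 (so the root is ntip + 1, ape's convention); edges in cladewise
# (preorder) order, preserving the child order of the file.
nested_to_phylo <- function(root) {
  cnt <- count_nested(root)
  ntip <- cnt[["tips"]]
  nint <- cnt[["internal"]]
  if (ntip < 2L) stop("tree must contain at least 2 tips", call. = FALSE)

  n_edge <- ntip + nint - 1L
  edge <- matrix(0L, n_edge, 2L)
  edge_len <- rep(NA_real_, n_edge)
  tip_label <- character(ntip)
  node_label <- character(nint)
  comment <- character(ntip + nint)
  tip_i <- 0L
  int_i <- 0L
  edge_i <- 0L

  assign_ids <- function(node) {
    if (length(node$children) == 0L) {
      tip_i <<- tip_i + 1L
      id <- tip_i
      tip_label[tip_i] <<- node$label
    } else {
      int_i <<- int_i + 1L
      id <- ntip + int_i
      node_label[int_i] <<- node$label
    }
    comment[id] <<- node$comment
    for (child in node$children) {
      e <- edge_i <<- edge_i + 1L  # reserve the row before descending (cladewise)
      edge[e, 1L] <<- id
      cid <- assign_ids(child)
      edge[e, 2L] <<- cid
      edge_len[e] <<- child$length
    }
    id
  }
  # two-pass trick: parent ids are known before children are visited, but the
  # child id is filled in after its subtree is numbered
  assign_ids(root)

  if (anyDuplicated(tip_label)) {
    stop("duplicate tip labels: ",
         paste(unique(tip_label[duplicated(tip_label)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(tip_label))) stop("tip with empty label", call. = FALSE)

  tree <- list(edge = edge, Nnode = nint, tip.label = tip_label)
  if (any(!is.na(edge_len))) tree$edge.length <- edge_len
  if (any(nzchar(node_label))) tree$node.label <- node_label
  if (!is.na(root$length)) tree$root.edge <- root$length
  tree$node.comment <- comment
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

## ---- writer ----------------------------------------------------------------

needs_quoting <- function(lab) grepl("[ \t(),:;'\\[\\]]", lab)

quote_label <- function(lab) {
  if (needs_quoting(lab)) paste0("'", gsub("'", "''", lab), "'") else lab
}

format_brlen <- function(x) sprintf("%.10g", x)

deparse_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  comment <- tree$node.comment
  if (is.null(comment)) comment <- character(ntip + tree$Nnode)
  kids <- children_list(tree)
  child_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])

  rec <- function(v) {
    if (v <= ntip) {
      s <- quote_label(tree$tip.label[v])
    } else {
      s <- paste0("(", paste(vapply(kids[[v]], rec, character(1)), collapse = ","), ")")
      if (!is.null(tree$node.label)) {
        lab <- tree$node.label[v - ntip]
        if (!is.na(lab) && nzchar(lab)) s <- paste0(s, quote_label(lab))
      }
    }
    if (nzchar(comment[v])) s <- paste0(s, "[", comment[v], "]")
    e <- child_edge[v]
    if (!is.na(e) && !is.null(tree$edge.length) && !is.na(tree$edge.length[e])) {
      s <- paste0(s, ":", format_brlen(tree$edge.length[e]))
    }
    s
  }
  root <- ntip + 1L
  s <- rec(root)
  if (!is.null(tree$root.edge)) s <- paste0(s, ":", format_brlen(tree$root.edge))
  paste0(s, ";")
}

# children of every node, in edge-matrix (file) order
children_list <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2L])
  }
  ch
}

# internal nodes in postorder (every child precedes its parent), following the
# edge-matrix child order so annotation targets are deterministic
postorder_internal <- function(tree, kids = children_list(tree)) {
  ntip <- length(tree$tip.label)
  out <- integer(tree$Nnode)
  k <- 0L
  rec <- function(v) {
    if (v > ntip) {
      for (child in kids[[v]]) rec(child)
      k <<- k + 1L
      out[k] <<- v
    }
  }
  rec(ntip + 1L)
  out
}
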