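#' Read a FASTA nucleotide alignment
#'
#' Reads an aligned FASTA file into a character matrix with one row per
#' sequence (row names are the labels) and one column per site. Wrapped
#' sequence lines are joined, case is normalised to upper, and the label is
#' the header text after `>` up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A character matrix (sequences x sites) with unique row names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no FASTA records in: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("not a FASTA file (first non-blank line must start with '>'): ", path,
         call. = FALSE)
  }
  labels <- sub("\\s.*$", "", sub("^>\\s*", "", lines[is_hdr]))
  if (any(!nzchar(labels))) stop("FASTA record with empty label in: ", path, call. = FALSE)
  if (anyDuplicated(labels)) {
    stop("duplicate FASTA labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  body <- split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(labels)))
  seqs <- toupper(gsub("\\s", "", vapply(body, paste, character(1), collapse = "")))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("sequences have unequal lengths: ",
         paste(sprintf("%s=%d", labels, lens), collapse = ", "), call. = FALSE)
  }
  aln <- matrix("", nrow = length(labels), ncol = lens[1L],
                dimnames = list(labels, NULL))
  if (lens[1L] > 0L) {
    aln[] <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  aln
}

#' Write an alignment in FASTA format
#'
#' Inverse of [read_fasta()]: labels, order and sequences round-trip exactly.
#' A zero-site alignment (e.g. after every site of an input was filtered out)
#' is written as headers with empty sequences, with a warning, rather than
#' failing, so pipelines survive pathological inputs.
#'
#' @param alignment Character matrix as returned by [read_fasta()], or a named
#'   character vector of equal-length sequence strings.
#' @param path Output file path.
#' @param width Sequence line-wrapping width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(alignment, path, width = 70L) {
  aln <- as_alignment(alignment)
  if (ncol(aln) == 0L) {
    warning("writing alignment with 0 sites: ", path, call. = FALSE)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write FASTA file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    if (nchar(s) == 0L) {
      writeLines("", con)
    } else {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Write the per-site consistency report
#'
#' Writes the CSV report describing the consistency information for each site.
#' By default only inconsistent (homoplasious) sites are reported; with
#' `include_consistent = TRUE` every site gets a row. Columns are
#' `Position` (1-based site index), `ConsistencyIndex`,
#' `MinimumNumberChangesOnTree` (the per-site parsimony tree length) and
#' `CountsACGT` (colon-separated counts of unambiguous A, C, G and T calls at
#' the site).
#'
#' @param records A [find_homoplasies()] result, or its `sites` data frame.
#' @param path Output CSV path.
#' @param include_consistent Report all sites, not only inconsistent ones.
#' @return Invisibly, the data frame written.
#' @export
write_report <- function(records, path, include_consistent = FALSE) {
  sites <- if (inherits(records, "homoplasy_scan")) records$sites else records
  stopifnot(is.data.frame(sites))
  if (!include_consistent) sites <- sites[sites$is_inconsistent, , drop = FALSE]
  out <- data.frame(Position = sites$position,
                    ConsistencyIndex = sites$consistency_index,
                    MinimumNumberChangesOnTree = sites$tree_length,
                    CountsACGT = sites$counts_acgt)
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write report: ", path,
                                    " (", conditionMessage(e), ")", call. = FALSE))
  invisible(out)
}

# Coerce to the internal alignment representation: a character matrix with
# unique row names, upper case.
as_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    aln <- x
  } else if (is.character(x) && !is.null(names(x))) {
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      stop("sequences have unequal lengths: ",
           paste(sprintf("%s=%d", names(x), lens), collapse = ", "), call. = FALSE)
    }
    aln <- matrix("", length(x), lens[1L], dimnames = list(names(x), NULL))
    if (lens[1L] > 0L) aln[] <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  } else {
    stop("alignment must be a character matrix or a named character vector",
         call. = FALSE)
  }
  if (is.null(rownames(aln))) stop("alignment rows must be labelled", call. = FALSE)
  if (anyDuplicated(rownames(aln))) {
    stop("duplicate sequence labels: ",
         paste(unique(rownames(aln)[duplicated(rownames(aln))]), collapse = ", "),
         call. = FALSE)
  }
  toupper_matrix(aln)
}

toupper_matrix <- function(aln) {
  out <- toupper(aln)
  dim(out) <- dim(aln)
  dimnames(out) <- dimnames(aln)
  out
}
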