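# Alignment and tree input/output plus the shared data model.
#
# Alignments are stored as character matrices (one row per sequence, one
# single-letter column per site) of class "aa_msa". Trees are plain ape
# "phylo" objects; branch supports read from internal node labels are kept
# in the labels and exposed numerically through node_support(). Nodes are
# identified throughout the package by their ape node number (tips
# 1..Ntip, internals Ntip+1..Ntip+Nnode), which is stable for a fixed tree.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP <- "-"
AMBIG <- "X"

#' Construct an amino-acid alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the 20 amino-acid one-letter codes plus `-` (gap) and `X` (ambiguous).
#'   Lowercase letters are normalized to uppercase and `.` to `-`.
#' @return An object of class `aa_msa`: a character matrix with one row per
#'   sequence and one column per alignment site.
#' @export
as_msa <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment is empty", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in alignment", call. = FALSE)
  }
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c(AA_LETTERS, GAP, AMBIG))
  if (length(bad) > 0L) {
    stop(sprintf("illegal alignment character(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(mat, class = c("aa_msa", "matrix", "array"))
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences, %d sites\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read an amino-acid alignment from FASTA
#'
#' @param path Path to a FASTA file.
#' @return An [as_msa()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">")) {
    stop("not a FASTA file (no '>' header): ", path, call. = FALSE)
  }
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  if (length(seqs) != length(ids)) stop("malformed FASTA: empty record", call. = FALSE)
  names(seqs) <- ids
  as_msa(seqs)
}

#' Write an alignment to FASTA
#'
#' @param msa An [as_msa()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  seqs <- apply(unclass(msa), 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(msa), "\n", seqs), path)
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Internal node labels that parse as numbers in \[0, 1\] are interpreted as
#' branch support values (the FastTree/RAxML SH-like aLRT dialect) and kept
#' in `node.label`; use [node_support()] to extract them numerically.
#' Missing branch lengths default to 0 with a warning.
#'
#' @param path Path to a file containing a single Newick tree.
#' @param text Newick string, as an alternative to `path`.
#' @return An ape `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick tree", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single Newick tree", call. = FALSE)
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return `path` invisibly, or the Newick string when `path` is `NULL`.
#' @export
write_tree <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Extract numeric branch supports from internal node labels
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (NA where the label is
#'   absent or not a number in \[0, 1\]), named by ape node number.
#' @export
node_support <- function(tree) {
  n <- tree$Nnode
  out <- rep(NA_real_, n)
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    v[!is.na(v) & (v < 0 | v > 1)] <- NA_real_
    out <- v
  }
  names(out) <- as.character(ape::Ntip(tree) + seq_len(n))
  out
}

#' Collapse weakly supported internal edges to polytomies
#'
#' Every internal edge whose child node has support below `threshold` is
#' contracted: the child's children are re-attached to its parent and the
#' contracted edge's length is discarded (re-attached children keep their
#' own branch lengths). The root is never collapsed; unsupported (NA) nodes
#' are kept.
#'
#' @param tree A `phylo` object with supports in `node.label`.
#' @param threshold Support threshold in \[0, 1\]; edges with child support
#'   strictly below it are contracted.
#' @return A `phylo` object, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopif_not_scalar_prob(threshold, "threshold")
  ntip <- ape::Ntip(tree)
  sup <- node_support(tree)
  root <- ntip + 1L
  drop <- which(!is.na(sup) & sup < threshold) + ntip
  drop <- setdiff(drop, root)
  if (length(drop) == 0L) return(tree)

  edge <- tree$edge
  elen <- tree$edge.length
  # contract each doomed node: reroute its children to its parent
  for (nd in drop) {
    up <- which(edge[, 2L] == nd)
    parent <- edge[up, 1L]
    edge[edge[, 1L] == nd, 1L] <- parent
    edge <- edge[-up, , drop = FALSE]
    elen <- elen[-up]
  }
  keep_internal <- sort(setdiff(seq_len(tree$Nnode) + ntip, drop))
  remap <- integer(ntip + tree$Nnode)
  remap[seq_len(ntip)] <- seq_len(ntip)
  remap[keep_internal] <- ntip + seq_along(keep_internal)
  out <- list(edge = cbind(remap[edge[, 1L]], remap[edge[, 2L]]),
              edge.length = elen,
              tip.label = tree$tip.label,
              Nnode = length(keep_internal))
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[keep_internal - ntip]
  }
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Midpoint-root a tree
#'
#' Explicit utility; never applied silently. Marginal reconstruction is
#' root-dependent, so rooting is always the caller's decision.
#'
#' @param tree A `phylo` object.
#' @return A rooted `phylo` object.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Per-node record table paired with a tree
#'
#' A thin validated wrapper: a data frame with a `node` column whose values
#' must be node numbers of `tree`.
#'
#' @param tree A `phylo` object.
#' @param records A data frame with a `node` column.
#' @return The data frame with class `node_table`.
#' @export
node_table <- function(tree, records) {
  stopifnot(is.data.frame(records), "node" %in% names(records))
  nmax <- ape::Ntip(tree) + tree$Nnode
  if (any(records$node < 1L | records$node > nmax)) {
    stop("node_table: node id not present in tree", call. = FALSE)
  }
  structure(records, class = c("node_table", "data.frame"))
}

# children list indexed by node number (list of integer vectors)
children_list <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2L])
  }
  ch
}

# edge length of the branch above each node (NA for root)
parent_edge_length <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  len <- rep(NA_real_, n)
  len[tree$edge[, 2L]] <- tree$edge.length
  len
}

# parent of each node (0 for root)
parent_vec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# internal node numbers in postorder (children before parents)
postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  unique(tr$edge[, 1L])
}
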