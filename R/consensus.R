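# Clade presence/absence coding of input tree sets (matrix representation,
# the input to supertree searches) and a support-aware majority-rule
# consensus built from clade frequencies.

# tip-label sets of all non-trivial clades of one tree (internal non-root
# nodes), in postorder; names are node numbers
tree_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nodes <- setdiff(postorder_nodes(tree), root)
  ch <- children_list(tree)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (nd in postorder_nodes(tree)) {
    desc[[nd]] <- sort(unique(unlist(desc[ch[[nd]]])))
  }
  stats::setNames(desc[nodes], as.character(nodes))
}

#' Matrix-representation coding of a set of trees
#'
#' One column per non-trivial clade (internal non-root node) of each input
#' tree, in input-tree order and postorder within a tree. Taxa inside the
#' clade are coded `1`, other taxa of the same tree `0`, and taxa absent
#' from that tree `?`. Trees with fewer than 3 taxa are skipped with a
#' warning.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A `clade_matrix`: character matrix (rows = union of taxa,
#'   columns = clades, entries `"0"`, `"1"`, `"?"`) with a `source`
#'   attribute giving each column's tree index.
#' @export
mrp_matrix <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  keep <- vapply(trees, function(t) ape::Ntip(t) >= 3L, TRUE)
  if (!all(keep)) warning(sum(!keep), " tree(s) with < 3 taxa skipped")
  trees <- trees[keep]
  if (length(trees) == 0L) stop("no usable trees", call. = FALSE)
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  cols <- list(); src <- integer(0)
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    for (cl in tree_clades(tr)) {
      v <- rep("?", length(taxa))
      names(v) <- taxa
      v[tr$tip.label] <- "0"
      v[cl] <- "1"
      cols[[length(cols) + 1L]] <- v
      src <- c(src, ti)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  structure(m, source = src, class = c("clade_matrix", class(m)))
}

#' Export a clade matrix as relaxed PHYLIP
#'
#' 0/1/? characters, relaxed (whitespace-delimited) names; the input format
#' expected by external binary-character supertree inference.
#'
#' @param m A [mrp_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
             paste(rownames(m), apply(unclass(m), 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Majority-rule consensus with clade frequencies as supports
#'
#' Counts clades across the input trees and keeps those present in strictly
#' more than `min_freq` of them (mutually compatible by construction for
#' `min_freq >= 0.5`); the retained clade frequencies become node supports.
#' Trees with unequal taxon sets are pruned to the common taxa with a
#' warning.
#'
#' @param trees List of rooted `phylo` objects.
#' @param min_freq Frequency threshold (default 0.5, the classical majority
#'   rule).
#' @return A rooted `phylo` object (no branch lengths) whose `node.label`
#'   carries each retained clade's frequency.
#' @export
majority_consensus <- function(trees, min_freq = 0.5) {
  if (min_freq < 0.5 || min_freq > 1) {
    stop("'min_freq' must be in [0.5, 1]", call. = FALSE)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(common) == 0L) stop("empty taxon intersection", call. = FALSE)
  if (!all(vapply(trees, function(t) length(t$tip.label) == length(common), TRUE))) {
    warning("trees pruned to the common taxon set (", length(common), " taxa)")
    trees <- lapply(trees, function(t) {
      ape::keep.tip(t, common)
    })
  }
  nt <- length(trees)
  counts <- list()
  for (tr in trees) {
    for (cl in tree_clades(tr)) {
      if (length(cl) < 2L || length(cl) >= length(common)) next
      key <- paste(cl, collapse = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  freq <- unlist(counts) / nt
  keep <- freq > min_freq
  clades <- lapply(strsplit(names(freq)[keep], "\r", fixed = TRUE), identity)
  freq <- unname(freq[keep])
  build_tree_from_clades(common, clades, freq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble a rooted tree (Newick string) from a nested, compatible clade
# set; supports become internal node labels
build_tree_from_clades <- function(taxa, clades, freqs) {
  ord <- order(-lengths(clades))
  clades <- clades[ord]; freqs <- freqs[ord]
  # recursive grouping: at each level, maximal clades partition the members
  recurse <- function(members, idx) {
    sub <- idx[vapply(idx, function(i) all(clades[[i]] %in% members) &&
                        length(clades[[i]]) < length(members), TRUE)]
    parts <- character(0)
    used <- character(0)
    while (length(sub) > 0L) {
      i <- sub[[1L]]
      parts <- c(parts, paste0(recurse(clades[[i]], sub[-1L]),
                               sprintf("%.6g", freqs[i])))
      used <- c(used, clades[[i]])
      sub <- sub[vapply(sub, function(j) !any(clades[[j]] %in% clades[[i]]), TRUE)]
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  nwk <- paste0(recurse(taxa, seq_along(clades)), ";")
  tr <- ape::read.tree(text = nwk)
  tr
}
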