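# Sequence-similarity graph construction from pairwise E-values and Markov
# clustering (MCL) with an inflation sweep and annotated-member cluster
# selection.

#' Build a similarity graph from pairwise E-values
#'
#' Edges with E-value at most `min_e` get weight `min(-log10(E), cap)`.
#' Degrees are capped by ranking each node's incident edges by weight and
#' keeping an edge only if it is within the top `degree_cap` at both
#' endpoints (mutual retention), which preserves symmetry and guarantees no
#' node exceeds the cap. Self-edges are dropped with a warning, and a
#' warning is raised if the capped graph is disconnected.
#'
#' @param evalues Data frame (or 3-column object) with columns `a`, `b`,
#'   `e`: node ids and positive E-values.
#' @param cap Weight cap (default 200).
#' @param degree_cap Maximum retained edges per node before the symmetric
#'   union (default 280).
#' @param min_e E-value cutoff; pairs above it are discarded (default 0.1).
#' @return A `similarity_graph`: list with `edges` (data frame `a`, `b`,
#'   `weight`), `nodes`, `connected`.
#' @export
build_graph <- function(evalues, cap = 200, degree_cap = 280L, min_e = 0.1) {
  ev <- as.data.frame(evalues)
  names(ev)[1:3] <- c("a", "b", "e")
  if (any(ev$e <= 0)) stop("E-values must be > 0", call. = FALSE)
  self <- ev$a == ev$b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    ev <- ev[!self, , drop = FALSE]
  }
  ev <- ev[ev$e <= min_e, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no edges pass the E-value cutoff", call. = FALSE)
  ev$weight <- pmin(-log10(ev$e), cap)
  # collapse duplicate pairs (keep heaviest), undirected
  key <- ifelse(ev$a < ev$b, paste(ev$a, ev$b), paste(ev$b, ev$a))
  ord <- order(key, -ev$weight)
  ev <- ev[ord, , drop = FALSE]
  ev <- ev[!duplicated(key[ord]), , drop = FALSE]
  rownames(ev) <- NULL

  # per-node keep-heaviest; an edge survives only if both endpoints keep it
  long <- rbind(data.frame(n = ev$a, w = ev$weight, id = seq_len(nrow(ev))),
                data.frame(n = ev$b, w = ev$weight, id = seq_len(nrow(ev))))
  kept <- lapply(split(long, long$n), function(d) {
    d$id[order(-d$w)][seq_len(min(nrow(d), degree_cap))]
  })
  tab <- table(unlist(kept))
  keep_ids <- as.integer(names(tab)[tab == 2L])
  ev <- ev[sort(keep_ids), , drop = FALSE]
  nodes <- sort(unique(c(ev$a, ev$b)))
  g <- igraph::graph_from_data_frame(ev[, c("a", "b", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  connected <- igraph::is_connected(g)
  if (!connected) warning("similarity graph is disconnected after capping")
  structure(list(edges = ev[, c("a", "b", "weight")], nodes = nodes,
                 connected = connected),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (x$connected) "" else " (disconnected)"))
  invisible(x)
}

#' Markov clustering
#'
#' Standard MCL on the column-stochastic similarity matrix: self-loops are
#' set to each node's maximum incident weight, the graph is pre-inflated
#' once (entrywise power `preinflation`, then renormalized) to sharpen
#' contrast, and expansion (matrix squaring) alternates with inflation
#' (entrywise power `inflation`, renormalize) until the largest column
#' change drops below 1e-6 or 200 iterations. Clusters are the connected
#' components of the converged matrix's support.
#'
#' @param graph A [build_graph()] result.
#' @param inflation Inflation exponent (> 1).
#' @param preinflation One-off pre-inflation exponent (default 3).
#' @return A `clustering`: list with `clusters` (list of node-id vectors),
#'   `membership` (named integer vector), `inflation`, `converged`,
#'   `iterations`, `stochastic_dev` (per-iteration max |column sum - 1|,
#'   checked before renormalization-sensitive steps).
#' @export
mcl <- function(graph, inflation, preinflation = 3) {
  if (inflation <= 1) stop("'inflation' must be > 1", call. = FALSE)
  nodes <- graph$nodes
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(graph$edges$a, nodes); ib <- match(graph$edges$b, nodes)
  M[cbind(ia, ib)] <- graph$edges$weight
  M[cbind(ib, ia)] <- graph$edges$weight
  diag(M) <- if (n > 1L) apply(M, 1L, max) else 1
  norm_cols <- function(X) sweep(X, 2L, colSums(X), "/")
  M <- norm_cols(M^preinflation)
  converged <- FALSE
  dev <- numeric(0)
  for (it in seq_len(200L)) {
    E <- M %*% M                 # expansion
    E <- norm_cols(E^inflation)  # inflation
    dev <- c(dev, max(abs(colSums(E) - 1)))
    delta <- max(abs(E - M))
    M <- E
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within 200 iterations")
  supp <- M > 1e-8
  g <- igraph::graph_from_adjacency_matrix(supp | t(supp), mode = "undirected")
  memb <- igraph::components(g)$membership
  names(memb) <- nodes
  clusters <- split(nodes, memb)
  names(clusters) <- NULL
  structure(list(clusters = clusters, membership = memb,
                 inflation = inflation, converged = converged,
                 iterations = length(dev), stochastic_dev = dev),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters at inflation %.3g (%d iterations%s)\n",
              length(x$clusters), x$inflation, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Select the clustering that best concentrates annotated members
#'
#' Scores each clustering by the mean number of annotated nodes per cluster,
#' over clusters containing at least one annotated node, and returns the
#' argmax; ties go to the lowest inflation. Alternative scorings: `"max"`
#' (largest annotated count in any cluster) and `"purity"` (mean fraction of
#' a cluster that is annotated).
#'
#' @param clusterings List of [mcl()] results (e.g. an inflation sweep).
#' @param annotated Character vector of annotated node ids (non-empty).
#' @param score One of `"mean"` (default), `"max"`, `"purity"`.
#' @return The selected `clustering`, with its `selection_score` attached.
#' @export
select_clustering <- function(clusterings, annotated, score = c("mean", "max", "purity")) {
  score <- match.arg(score)
  if (length(annotated) == 0L) stop("'annotated' must be non-empty", call. = FALSE)
  scores <- vapply(clusterings, function(cl) {
    counts <- vapply(cl$clusters, function(members) sum(members %in% annotated), 0)
    sizes <- lengths(cl$clusters)
    has <- counts > 0
    if (!any(has)) return(NA_real_)
    switch(score,
           mean = mean(counts[has]),
           max = max(counts),
           purity = mean(counts[has] / sizes[has]))
  }, 0)
  if (all(is.na(scores))) {
    stop("no clustering contains an annotated node", call. = FALSE)
  }
  infl <- vapply(clusterings, `[[`, 0, "inflation")
  best <- which(!is.na(scores) & scores == max(scores, na.rm = TRUE))
  pick <- best[which.min(infl[best])]
  out <- clusterings[[pick]]
  out$selection_score <- scores[pick]
  out
}

#' Write a clustering as a node/cluster TSV
#'
#' @param clustering An [mcl()] result.
#' @param path Optional output path.
#' @return Data frame with `node`, `cluster_id`.
#' @export
write_clusters_tsv <- function(clustering, path = NULL) {
  out <- data.frame(node = names(clustering$membership),
                    cluster_id = unname(clustering$membership))
  if (!is.null(path)) write_tsv(out, path)
  out
}
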