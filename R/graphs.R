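# Binary FCN construction by proportional thresholding plus the three
# global measures used as classification features.

new_fcn_graph <- function(adjacency, pt_level = NA_real_) {
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected",
                                           diag = FALSE)
  structure(list(graph = g, pt_level = pt_level), class = "fcn_graph")
}

#' @export
print.fcn_graph <- function(x, ...) {
  cat(sprintf(
    "<fcn_graph> %d nodes, %d edges%s\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    if (is.na(x$pt_level)) "" else sprintf(" (PT = %d%%)", round(100 * x$pt_level))
  ))
  invisible(x)
}

#' Proportional thresholding of a distance matrix
#'
#' Keeps the `ceiling(pt * M * (M - 1) / 2)` smallest-distance (strongest)
#' pairs as edges of a binary undirected graph, so graphs across subjects
#' share the same density. Ties at the cut break by a stable sort on
#' (distance, node-pair lexicographic order), making the edge set
#' deterministic. Edge sets are nested in `pt`.
#'
#' @param D Distance matrix (any metric).
#' @param pt Proportion of edges kept, in `(0, 1]`. The study grid is
#'   0.20--0.70 in steps of 0.02.
#' @return An `"fcn_graph"` (igraph plus the PT level).
#' @export
proportional_threshold <- function(D, pt) {
  D <- check_distance_matrix(D)
  pt <- check_number(pt, "pt", min = 0, max = 1, strict_min = TRUE)
  m <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], pairs[, 1L], pairs[, 2L], method = "radix")
  n_keep <- ceiling(pt * m * (m - 1) / 2)
  keep <- pairs[ord[seq_len(n_keep)], , drop = FALSE]
  adj <- matrix(0L, m, m)
  adj[keep] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(D)
  new_fcn_graph(adj, pt_level = pt)
}

#' Largest connected component of an FCN
#'
#' Induced subgraph on the component with the most nodes; ties take the
#' component containing the lowest node index.
#'
#' @param G An `"fcn_graph"`.
#' @return An `"fcn_graph"` on the surviving nodes.
#' @export
largest_component <- function(G) {
  g <- G$graph
  if (igraph::vcount(g) == 0L) abort_field("G", "graph is empty")
  comps <- igraph::components(g)
  best <- which(comps$csize == max(comps$csize))
  if (length(best) > 1L) {
    first_node <- vapply(best, function(cc) min(which(comps$membership == cc)), integer(1))
    best <- best[which.min(first_node)]
  }
  sub <- igraph::induced_subgraph(g, which(comps$membership == best))
  structure(list(graph = sub, pt_level = G$pt_level), class = "fcn_graph")
}

#' Average shortest-path length
#'
#' Mean unweighted hop distance over all ordered pairs of distinct nodes,
#' `L = 1/(N (N - 1)) * sum_{i != j} d(i, j)`. Requires a connected graph
#' with at least two nodes; take [largest_component()] first when
#' thresholding fragments the graph.
#'
#' @param G An `"fcn_graph"`.
#' @return A single number `>= 1`.
#' @export
average_path_length <- function(G) {
  g <- G$graph
  if (igraph::vcount(g) < 2L) abort_field("G", "needs at least 2 nodes")
  if (igraph::components(g)$no != 1L) {
    rlang::abort("graph is disconnected; take the largest component first",
                 class = "fcnembed_disconnected_error")
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = FALSE)
}

#' Global clustering coefficient (transitivity)
#'
#' Ratio of closed triplets to all triplets. Graphs without any triplet
#' (e.g. a single edge) return 0 with a warning.
#'
#' @param G An `"fcn_graph"`.
#' @return A number in `[0, 1]`.
#' @export
global_clustering <- function(G) {
  deg <- igraph::degree(G$graph)
  if (sum(choose(deg, 2)) == 0) {
    warning("graph has no connected triplet; clustering defined as 0")
    return(0)
  }
  igraph::transitivity(G$graph, type = "global")
}

#' Median node degree
#'
#' Median of the degree distribution (mean of the middle two for even node
#' counts).
#'
#' @param G An `"fcn_graph"`.
#' @return A single number.
#' @export
median_degree <- function(G) {
  if (igraph::vcount(G$graph) == 0L) abort_field("G", "graph is empty")
  stats::median(igraph::degree(G$graph))
}

#' Global graph features of a thresholded FCN
#'
#' Applies proportional thresholding, restricts to the largest connected
#' component, and computes the three global measures used as
#' classification features.
#'
#' @param D Distance matrix.
#' @param pt Proportional threshold in `(0, 1]`.
#' @return A one-row tibble: `pt`, `n_nodes` (of the largest component),
#'   `L`, `Cg`, `Mk`.
#' @examples
#' D <- euclidean_distance(matrix(rnorm(20 * 30), 20))
#' graph_features(D, pt = 0.3)
#' @export
graph_features <- function(D, pt) {
  G <- largest_component(proportional_threshold(D, pt))
  tibble::tibble(
    pt = pt,
    n_nodes = igraph::vcount(G$graph),
    L = average_path_length(G),
    Cg = suppressWarnings(global_clustering(G)),
    Mk = median_degree(G)
  )
}
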