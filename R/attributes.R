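# The four local attributes behind the LWC score. Each exported function
# returns a tibble keyed by node label; the *_values() internals return bare
# numeric vectors in vertex order and are what the pipeline composes.

degree_values <- function(graph) {
  unname(as.numeric(igraph::degree(graph, loops = FALSE)))
}

# Local clustering coefficient clc_i = 2 e_i / (k_i (k_i - 1)), where e_i is
# the number of edges among i's neighbours; 0 by convention when k_i <= 1.
clustering_values <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(numeric(0))
  unname(igraph::transitivity(graph, type = "localundirected", isolates = "zero"))
}

# Two-hop degree: the number of distinct nodes within distance <= 2 of i,
# excluding i itself. Computed as a depth-2 neighbourhood union over the
# adjacency list, so every node is counted once however many two-hop paths
# reach it.
two_hop_degree_values <- function(graph, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_list(graph)
  vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    ball <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
    sum(ball != i)
  }, numeric(1))
}

# Two-hop clustering coefficient: the sum of the clustering coefficients of
# i's one-hop neighbours.
two_hop_clustering_values <- function(graph, adj = NULL, clc = NULL) {
  if (is.null(adj)) adj <- adjacency_list(graph)
  if (is.null(clc)) clc <- clustering_values(graph)
  vapply(unname(adj), function(nb) sum(clc[nb]), numeric(1))
}

#' Per-node local attributes
#'
#' Computes the four local attributes that feed the LWC score:
#' degree `k`, two-hop degree `thk` (distinct nodes within distance 2,
#' excluding the node itself), clustering coefficient `clc`
#' (`2 e_i / (k_i (k_i - 1))`, zero for degree below 2), and two-hop
#' clustering coefficient `thclc` (sum of the neighbours' clustering
#' coefficients). `k` and `clc` capture a node's direct influence on its
#' one-hop neighbourhood; `thk` and `thclc` capture the indirect influence
#' it exerts through two-hop paths.
#'
#' @param graph An igraph graph with at least one node.
#' @return A tibble with columns `node`, `k`, `thk`, `clc`, `thclc`, one
#'   row per node in graph vertex order.
#' @examples
#' local_attributes(toy_graph("triangle_tail"))
#' @export
local_attributes <- function(graph) {
  assert_graph(graph)
  adj <- adjacency_list(graph)
  clc <- clustering_values(graph)
  tibble(
    node = node_labels(graph),
    k = degree_values(graph),
    thk = two_hop_degree_values(graph, adj),
    clc = clc,
    thclc = two_hop_clustering_values(graph, adj, clc)
  )
}

#' @rdname local_attributes
#' @export
node_degree <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), k = degree_values(graph))
}

#' @rdname local_attributes
#' @export
node_clustering <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), clc = clustering_values(graph))
}

#' @rdname local_attributes
#' @export
two_hop_degree <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), thk = two_hop_degree_values(graph))
}

#' @rdname local_attributes
#' @export
two_hop_clustering <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), thclc = two_hop_clustering_values(graph))
}
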