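# Comparison centralities: betweenness, closeness, local centrality,
# clustered local degree, plus degree and the clustering coefficient used
# directly as rankings. Shortest-path machinery comes from igraph; the
# neighbourhood-sum measures are computed here.

#' Baseline node centralities
#'
#' @description
#' Per-node centrality scores for the classical comparison methods:
#'
#' * `betweenness_centrality()` — unnormalized shortest-path betweenness,
#'   `b_i = sum over pairs j != s != i of n_js(i) / n_js` (each unordered
#'   pair counted once, endpoints excluded).
#' * `closeness_centrality()` — `c_i = 1 / sum_j d_ij` on a connected
#'   graph. When unreachable pairs exist the convention `1/inf = 0` is
#'   applied termwise, i.e. the harmonic form `sum_j 1/d_ij`; a singleton
#'   graph scores 0.
#' * `local_centrality()` — `N(w)` is the number of nodes within two hops
#'   of w, `Q(u) = sum of N(w) over neighbours w of u`, and the score of v
#'   is `CL(v) = sum of Q(u) over neighbours u of v`.
#' * `clustered_local_degree()` — `(1 + clc_i) * sum of k_j over
#'   neighbours j of i`: the neighbour-degree sum moderated by the node's
#'   own clustering coefficient. Isolated nodes score 0.
#'
#' @param graph An igraph graph.
#' @return A tibble with columns `node` and the score column named after
#'   the measure (`bc`, `cc`, `localc`, `cld`).
#' @examples
#' closeness_centrality(toy_graph("p3"))
#' @name baseline_centralities
NULL

betweenness_values <- function(graph) {
  unname(as.numeric(igraph::betweenness(graph, directed = FALSE, normalized = FALSE)))
}

closeness_values <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 1L) return(0)
  if (igraph::is_connected(graph)) {
    unname(as.numeric(igraph::closeness(graph, normalized = FALSE)))
  } else {
    unname(as.numeric(igraph::harmonic_centrality(graph, normalized = FALSE)))
  }
}

local_centrality_values <- function(graph) {
  adj <- adjacency_list(graph)
  n2 <- two_hop_degree_values(graph, adj)
  q <- vapply(adj, function(nb) sum(n2[nb]), numeric(1))
  vapply(adj, function(nb) sum(q[nb]), numeric(1))
}

clustered_local_degree_values <- function(graph) {
  adj <- adjacency_list(graph)
  k <- degree_values(graph)
  clc <- clustering_values(graph)
  (1 + clc) * vapply(adj, function(nb) sum(k[nb]), numeric(1))
}

#' @rdname baseline_centralities
#' @export
betweenness_centrality <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), bc = betweenness_values(graph))
}

#' @rdname baseline_centralities
#' @export
closeness_centrality <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), cc = closeness_values(graph))
}

#' @rdname baseline_centralities
#' @export
local_centrality <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), localc = local_centrality_values(graph))
}

#' @rdname baseline_centralities
#' @export
clustered_local_degree <- function(graph) {
  assert_graph(graph)
  tibble(node = node_labels(graph), cld = clustered_local_degree_values(graph))
}

centrality_methods <- c("degree", "bc", "cc", "localc", "cld", "clc", "lwc")

centrality_values <- function(graph, method) {
  switch(method,
    degree = degree_values(graph),
    bc = betweenness_values(graph),
    cc = closeness_values(graph),
    localc = local_centrality_values(graph),
    cld = clustered_local_degree_values(graph),
    clc = clustering_values(graph),
    lwc = {
      fit <- lwc(graph)
      fit$score[match(node_labels(graph), fit$node)]
    },
    stop("unknown centrality method: ", method, call. = FALSE)
  )
}

#' Rank nodes by a named centrality method
#'
#' Convenience wrapper producing a tie-aware [rank_nodes()] ranking for any
#' of the supported methods: `"degree"`, `"bc"` (betweenness), `"cc"`
#' (closeness), `"localc"` (local centrality), `"cld"` (clustered local
#' degree), `"clc"` (clustering coefficient), `"lwc"`.
#'
#' @param graph An igraph graph.
#' @param method Method name.
#' @param signif_digits Tie tolerance passed to [rank_nodes()].
#' @return A tibble with columns `node`, `score`, `rank` (for
#'   `method = "lwc"`, the full `lwc_ranking` object).
#' @examples
#' centrality_ranking(toy_graph("star5"), "degree")
#' @export
centrality_ranking <- function(graph, method = centrality_methods,
                               signif_digits = 12) {
  method <- match.arg(method)
  assert_graph(graph)
  if (method == "lwc") return(lwc(graph, signif_digits = signif_digits))
  rank_nodes(
    tibble(node = node_labels(graph), score = centrality_values(graph, method)),
    signif_digits = signif_digits
  )
}
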