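# Synthetic networks: Erdos-Renyi and Barabasi-Albert generators plus a
# registry of small labelled fixtures with hand-checkable attribute values.

#' Generate an Erdős–Rényi G(n, p) graph
#'
#' Each of the `choose(n, 2)` node pairs is included independently with
#' probability `p`. Reproducible: the same `rng_seed` always yields the
#' same edge set. Node labels are `"1" ... "n"`.
#'
#' @param n Number of nodes (>= 1).
#' @param p Edge probability in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return An igraph graph.
#' @examples
#' igraph::ecount(generate_er(10, 1, rng_seed = 1)) # 45
#' @export
generate_er <- function(n, p, rng_seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is.na(p) || p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(rng_seed))
  g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Generate a Barabási–Albert preferential-attachment graph
#'
#' Starts from a complete graph on `m + 1` nodes; each subsequent node
#' attaches to `m` distinct existing nodes chosen with probability
#' proportional to their degree. The edge count is therefore exactly
#' `choose(m + 1, 2) + m * (n - m - 1)`. Reproducible given `rng_seed`.
#'
#' @param n Number of nodes.
#' @param m Edges attached by each new node, `1 <= m < n`.
#' @param rng_seed Integer seed.
#' @return An igraph graph with labels `"1" ... "n"`.
#' @export
generate_ba <- function(n, m, rng_seed = 1) {
  if (m < 1 || m >= n) stop("`m` must satisfy 1 <= m < n", call. = FALSE)
  set.seed(as.integer(rng_seed))
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                         start.graph = igraph::make_full_graph(m + 1),
                         algorithm = "psumtree")
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

toy_edges <- list(
  triangle      = c("1","2", "1","3", "2","3"),
  k4            = c("1","2", "1","3", "1","4", "2","3", "2","4", "3","4"),
  k5            = NULL, # built below as a complete graph
  c5            = c("1","2", "2","3", "3","4", "4","5", "5","1"),
  p3            = c("1","2", "2","3"),
  p5            = c("1","2", "2","3", "3","4", "4","5"),
  star5         = NULL, # centre "1", leaves "2".."6"
  star20        = NULL, # centre "1", leaves "2".."21"
  triangle_tail = c("1","2", "1","3", "2","3", "3","4", "4","5"),
  two_triangles = c("1","2", "1","3", "2","3", "4","5", "4","6", "5","6")
)

#' Named toy graphs
#'
#' A registry of small fixed labelled graphs used throughout the tests and
#' examples: `"triangle"`, `"k4"`, `"k5"`, `"c5"` (5-cycle), `"p3"`,
#' `"p5"` (paths), `"star5"`, `"star20"` (stars: centre `"1"` plus 5 or 20
#' leaves), `"triangle_tail"` (edges 1-2, 1-3, 2-3, 3-4, 4-5), and
#' `"two_triangles"` (two disjoint triangles).
#'
#' @param name Fixture name.
#' @return An igraph graph with small-integer character labels.
#' @examples
#' network_summary(toy_graph("triangle_tail"))
#' @export
toy_graph <- function(name) {
  if (!name %in% names(toy_edges)) {
    stop("unknown toy graph: '", name, "'. Known: ",
         paste(names(toy_edges), collapse = ", "), call. = FALSE)
  }
  star <- function(leaves) {
    as.character(rbind("1", as.character(seq_len(leaves) + 1L)))
  }
  complete <- function(n) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    as.character(t(idx[order(idx[, 1], idx[, 2]), , drop = FALSE]))
  }
  ends <- switch(name,
    k5 = complete(5),
    star5 = star(5),
    star20 = star(20),
    toy_edges[[name]]
  )
  igraph::graph_from_edgelist(matrix(ends, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}
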