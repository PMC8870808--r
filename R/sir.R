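# Discrete-time SIR Monte-Carlo spreading: the ground-truth influence of a
# node is the mean outbreak size over repeated simulations seeded at that
# node. Synchronous (generation-based) updates: at every step each infected
# node tries to infect each susceptible neighbour independently with
# probability beta, then recovers with probability gamma.

#' Degree-based epidemic threshold
#'
#' Returns `<k> / (<k^2> - <k>)`, the standard degree-based critical
#' infection probability of the SIR model on an uncorrelated network.
#' Spreading experiments are usually run slightly above this value;
#' [influence_table()] with `beta = "auto"` uses 1.5 times the threshold
#' (capped at 1).
#'
#' @param graph An igraph graph with `<k^2> > <k>`.
#' @return The threshold as a single number.
#' @examples
#' epidemic_threshold(toy_graph("k5")) # 1/3
#' @export
epidemic_threshold <- function(graph) {
  assert_graph(graph)
  k <- degree_values(graph)
  kbar <- mean(k)
  k2 <- mean(k^2)
  if (k2 <= kbar) {
    stop("epidemic threshold undefined: <k^2> <= <k> (graph too sparse/regular)",
         call. = FALSE)
  }
  kbar / (k2 - kbar)
}

resolve_beta <- function(graph, beta) {
  if (identical(beta, "auto")) return(min(1, 1.5 * epidemic_threshold(graph)))
  beta <- as.numeric(beta)
  if (is.na(beta) || beta < 0 || beta > 1) {
    stop("`beta` must be in [0, 1] or \"auto\"", call. = FALSE)
  }
  beta
}

# One SIR realization from a single infected seed; returns the number of
# ever-infected nodes (seed included). `adj` is the integer adjacency list.
sir_spread_once <- function(adj, seed_idx, beta, gamma) {
  n <- length(adj)
  susceptible <- rep(TRUE, n)
  susceptible[seed_idx] <- FALSE
  infected <- seed_idx
  total <- 1L
  while (length(infected) > 0L) {
    new_inf <- integer(0)
    if (beta > 0) {
      targets <- unlist(adj[infected], use.names = FALSE)
      targets <- targets[susceptible[targets]]
      if (length(targets) > 0L) {
        m <- tabulate(targets, nbins = n)
        cand <- which(m > 0L)
        # P(infection) after m independent contacts = 1 - (1 - beta)^m
        hit <- runif(length(cand)) < 1 - (1 - beta)^m[cand]
        new_inf <- cand[hit]
        susceptible[new_inf] <- FALSE
        total <- total + length(new_inf)
      }
    }
    recovered <- if (gamma >= 1) rep(TRUE, length(infected)) else
      runif(length(infected)) < gamma
    infected <- c(infected[!recovered], new_inf)
  }
  total
}

#' Simulate one SIR outbreak from a seed node
#'
#' Runs a single discrete-time SIR realization with the given infection
#' probability `beta` and recovery probability `gamma`, starting from
#' `seed_node` infected and everyone else susceptible, until no infected
#' nodes remain. Uses the current RNG state.
#'
#' @param graph An igraph graph.
#' @param seed_node Label of the initially infected node.
#' @param beta Infection probability per infected-susceptible contact per
#'   step, in \[0, 1\], or `"auto"` (1.5 times [epidemic_threshold()],
#'   capped at 1).
#' @param gamma Recovery probability per step (default 1: every infected
#'   node recovers right after its infection attempts).
#' @return Integer outbreak size: the number of ever-infected nodes,
#'   including the seed. Always in `[1, n_nodes]`; equals 1 when
#'   `beta = 0` and `n_nodes` on a connected graph when `beta = 1`,
#'   `gamma = 1`.
#' @examples
#' simulate_spread(toy_graph("k5"), "1", beta = 1)
#' @export
simulate_spread <- function(graph, seed_node, beta, gamma = 1) {
  assert_graph(graph)
  labs <- node_labels(graph)
  idx <- match(as.character(seed_node), labs)
  if (is.na(idx)) stop("unknown seed node: ", seed_node, call. = FALSE)
  beta <- resolve_beta(graph, beta)
  if (gamma <= 0 || gamma > 1) stop("`gamma` must be in (0, 1]", call. = FALSE)
  sir_spread_once(adjacency_list(graph), idx, beta, gamma)
}

#' SIR ground-truth influence of every node
#'
#' For each node, runs `runs` independent SIR simulations seeded at that
#' node and records the mean outbreak size — the node's spreading
#' influence, used as ground truth when evaluating centrality rankings.
#' Each (node, run) pair gets its own RNG substream derived from
#' `rng_seed`, the node label and the run index, so results are
#' reproducible and independent of node iteration order.
#'
#' @param graph An igraph graph.
#' @param beta Infection probability in \[0, 1\] or `"auto"` (default).
#' @param gamma Recovery probability (default 1).
#' @param runs Simulations per seed node (default 100).
#' @param rng_seed Integer master seed (default 1).
#' @param nodes Optional subset of node labels to simulate (default: all).
#' @return A tibble with columns `node`, `influence` (mean outbreak size,
#'   in `[1, n_nodes]`), carrying the resolved `beta`, `gamma`, `runs`,
#'   and `rng_seed` as attribute `config`.
#' @examples
#' influence_table(toy_graph("star5"), beta = 0.5, runs = 20, rng_seed = 7)
#' @export
influence_table <- function(graph, beta = "auto", gamma = 1, runs = 100,
                            rng_seed = 1, nodes = NULL) {
  assert_graph(graph)
  beta <- resolve_beta(graph, beta)
  if (gamma <= 0 || gamma > 1) stop("`gamma` must be in (0, 1]", call. = FALSE)
  if (runs < 1) stop("`runs` must be >= 1", call. = FALSE)
  labs <- node_labels(graph)
  if (is.null(nodes)) nodes <- labs
  nodes <- as.character(nodes)
  if (!all(nodes %in% labs)) {
    stop("unknown node(s): ", paste(setdiff(nodes, labs), collapse = ", "),
         call. = FALSE)
  }
  adj <- adjacency_list(graph)
  means <- vapply(nodes, function(lab) {
    idx <- match(lab, labs)
    node_h <- label_hash(lab)
    sizes <- vapply(seq_len(runs), function(r) {
      set.seed(combine_seed(rng_seed, node_h, r))
      sir_spread_once(adj, idx, beta, gamma)
    }, numeric(1))
    mean(sizes)
  }, numeric(1))
  structure(
    tibble(node = nodes, influence = unname(means)),
    config = list(beta = beta, gamma = gamma, runs = runs, rng_seed = rng_seed),
    class = c("sir_influence", "tbl_df", "tbl", "data.frame")
  )
}
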