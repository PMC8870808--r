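# Independent oracles, deliberately built from different primitives than the
# implementation: distance matrices instead of adjacency unions, geodesic
# enumeration instead of Brandes accumulation, dense outer products instead
# of pair loops.

# Two-hop degree via the all-pairs distance matrix.
thk_distance_oracle <- function(g) {
  d <- igraph::distances(g)
  unname(rowSums(d >= 1 & d <= 2))
}

# Unnormalized betweenness by enumerating every geodesic of every pair.
betweenness_brute_oracle <- function(g) {
  n <- igraph::vcount(g)
  b <- numeric(n)
  if (n < 3) return(b)
  for (j in seq_len(n - 1)) {
    for (s in (j + 1):n) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = j, to = s)$vpaths
      )
      paths <- Filter(function(p) length(p) > 0, paths)
      if (length(paths) == 0) next
      for (p in paths) {
        interior <- as.integer(p)[-c(1, length(p))]
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

# Direct evaluation of the LWC formulas on raw igraph primitives, with no
# package intermediates: distance-matrix two-hop degree, adjacency-matrix
# neighbour sums, plain matrix arithmetic for normalization/entropy/weights.
lwc_direct_oracle <- function(g) {
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(a)
  clc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  p <- cbind(
    k = k,
    thk = thk_distance_oracle(g),
    clc = clc,
    thclc = as.numeric(a %*% clc)
  )
  r <- apply(p, 2, function(x) {
    if (max(x) == 0) return(x)
    d <- x / max(x)
    d / sum(d)
  })
  r <- matrix(r, nrow = n, dimnames = dimnames(p))
  ent <- apply(r, 2, function(x) {
    if (all(x == 0)) return(NA_real_)
    x <- x[x > 0]
    -sum(x * log(x)) / log(n)
  })
  w <- pmax(1 - ent, 0)
  w[is.na(ent)] <- 0
  if (sum(w) <= 1e-12) {
    live <- !is.na(ent)
    if (!any(live)) live <- rep(TRUE, 4)
    w <- ifelse(live, 1 / sum(live), 0)
  } else {
    w <- w / sum(w)
  }
  list(scores = as.numeric(r %*% w), weights = unname(w),
       entropies = unname(ifelse(is.na(ent), 0, ent)))
}

# Kendall tau-a by dense outer products (O(n^2) memory; small n only).
kendall_tau_brute_oracle <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  sum((sx * sy)[upper.tri(sx)]) / (0.5 * length(x) * (length(x) - 1))
}

# Fixture battery shared by the formula-equivalence checks.
fixture_battery <- function() {
  toys <- c("triangle", "k4", "k5", "c5", "p3", "p5", "star5",
            "triangle_tail", "two_triangles")
  gs <- lapply(toys, toy_graph)
  names(gs) <- toys
  gs$er_small <- generate_er(20, 0.2, rng_seed = 11)
  gs$er_dense <- generate_er(15, 0.5, rng_seed = 12)
  gs$ba_small <- generate_ba(25, 2, rng_seed = 13)
  gs
}

# Ranking tibble straight from given scores, for metric tests.
make_ranking <- function(labels, scores) {
  rank_nodes(tibble::tibble(node = as.character(labels), score = scores))
}
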