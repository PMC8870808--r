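# Internal helpers shared across modules.

# Node labels of a graph, always character, defaulting to 1..n.
node_labels <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  as.character(nm)
}

# Deterministic ordering of labels: numeric order when every label parses
# as a number (the common case for edge-list files), lexicographic otherwise.
label_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) order(num, method = "radix") else order(labels, method = "radix")
}

assert_graph <- function(graph, nonempty = TRUE) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (nonempty && igraph::vcount(graph) == 0L) {
    stop("graph has no nodes", call. = FALSE)
  }
  invisible(graph)
}

# Adjacency as a list of integer vertex indices, in vertex order.
adjacency_list <- function(graph) {
  unname(lapply(igraph::as_adj_list(graph, mode = "all"), as.integer))
}

# Deterministic 31-bit hash of a label string, for RNG substream derivation.
label_hash <- function(label) {
  h <- 0
  for (v in utf8ToInt(as.character(label))) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Combine seed components into a valid set.seed() argument below 2^31.
combine_seed <- function(...) {
  h <- 0
  for (v in c(...)) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}
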