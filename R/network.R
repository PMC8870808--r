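#' Read an undirected simple network from a file
#'
#' Reads a graph from a GML file (the dialect used by the classic
#' Newman-archive datasets: `graph [ node [ id ... label ... ] edge [
#' source ... target ... ] ]`) or from a plain edge list with one edge per
#' line, whitespace- or comma-separated, with `#` or `%` comment lines.
#' Whatever the file declares, the result is undirected and unweighted:
#' directed edges are symmetrized, duplicate and reversed-duplicate edges
#' are collapsed, and self-loops are dropped (with a message giving the
#' count).
#'
#' Node labels are preserved verbatim: the GML `label` (falling back to
#' `id` when labels are absent or non-unique), or the raw tokens of the
#' edge list. All per-node tibbles returned by the package are keyed by
#' these labels.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default; decided by the `.gml` extension),
#'   `"gml"`, or `"edgelist"`.
#' @return An undirected simple [igraph][igraph::igraph-package] graph with
#'   vertex names set to the original labels.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# toy", "1 2", "2 1", "2 3"), f)
#' g <- read_graph_file(f)
#' igraph::ecount(g) # 2: the reversed duplicate is collapsed
#' @export
read_graph_file <- function(path, format = c("auto", "gml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "edgelist"
  }
  g <- switch(format,
    gml = read_gml_graph(path),
    edgelist = read_edgelist_graph(path)
  )
  g <- igraph::as_undirected(g, mode = "collapse")
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops > 0) message("dropped ", n_loops, " self-loop(s) from ", basename(path))
  g
}

read_gml_graph <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop("failed to parse GML file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  lab <- igraph::vertex_attr(g, "label")
  if (is.null(lab) || anyDuplicated(lab)) lab <- igraph::vertex_attr(g, "id")
  if (is.null(lab) || anyDuplicated(lab)) lab <- seq_len(igraph::vcount(g))
  igraph::V(g)$name <- as.character(lab)
  g
}

read_edgelist_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#%].*)?$", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges found in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[idx]), "[,;[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge record at line ", idx[bad[1L]], " of ", path,
         ": '", lines[idx[bad[1L]]], "'", call. = FALSE)
  }
  ends <- vapply(toks, function(x) x[1:2], character(2))
  igraph::graph_from_edgelist(t(ends), directed = FALSE)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component. When
#' several components tie for the largest size, the one containing the
#' smallest node label wins, so the result is deterministic.
#' Idempotent: applying it twice changes nothing.
#'
#' @param graph An igraph graph.
#' @return An igraph graph on the largest component, labels preserved.
#' @export
largest_component <- function(graph) {
  assert_graph(graph)
  comp <- igraph::components(graph)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    labs <- node_labels(graph)
    first_lab <- vapply(cand, function(ci) {
      members <- labs[comp$membership == ci]
      members[label_order(members)][1L]
    }, character(1))
    cand <- cand[label_order(first_lab)[1L]]
  }
  igraph::induced_subgraph(graph, which(comp$membership == cand[1L]))
}

#' Summary statistics of a network
#'
#' One-row tibble with node count, edge count, average degree
#' (exactly `2 * n_edges / n_nodes`), maximum degree, and the average of
#' per-node clustering coefficients (nodes of degree below 2 count as 0).
#'
#' @param graph An igraph graph with at least one node.
#' @return A tibble with columns `n_nodes`, `n_edges`, `avg_degree`,
#'   `max_degree`, `avg_clustering`.
#' @examples
#' network_summary(toy_graph("k5"))
#' @export
network_summary <- function(graph) {
  assert_graph(graph)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  tibble(
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    max_degree = if (n > 0) max(deg) else 0,
    avg_clustering = mean(clustering_values(graph))
  )
}

#' Write a graph as a plain edge list
#'
#' One edge per line, the two node labels separated by a space. Reading the
#' file back with [read_graph_file()] recovers a graph with the same label
#' set and edge set (isolated nodes are not representable in an edge list).
#'
#' @param graph An igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  assert_graph(graph, nonempty = FALSE)
  labs <- node_labels(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  writeLines(paste(labs[el[, 1]], labs[el[, 2]]), path)
  invisible(path)
}
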