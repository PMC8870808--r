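# The LWC pipeline: decision matrix -> column normalization -> attribute
# entropies -> entropy weights -> weighted scores -> tie-aware ranking.

lwc_attribute_names <- c("k", "thk", "clc", "thclc")

#' Normalize an attribute table column-by-column
#'
#' Each attribute column is divided by its maximum and then by the sum of
#' those ratios, so every non-degenerate column becomes a discrete
#' probability distribution over nodes (entries in \[0, 1\] summing to 1).
#' An all-zero column stays all-zero. The two-stage max-then-sum
#' normalization makes the result invariant under uniform rescaling of any
#' raw attribute.
#'
#' @param attrs A tibble with a `node` column and one numeric column per
#'   attribute (as returned by [local_attributes()]). All entries must be
#'   non-negative.
#' @return A tibble of the same shape with normalized columns.
#' @export
normalize_attributes <- function(attrs) {
  stopifnot(is.data.frame(attrs), "node" %in% names(attrs))
  dplyr::mutate(attrs, dplyr::across(
    dplyr::where(is.numeric),
    function(x) {
      if (any(x < 0)) stop("attribute values must be non-negative", call. = FALSE)
      mx <- max(x)
      if (mx == 0) return(x)
      d <- x / mx
      d / sum(d)
    }
  ))
}

#' Entropy-derived attribute weights
#'
#' For each normalized attribute column the Shannon entropy
#' `E_j = -(1/ln n) * sum_i r_ij ln r_ij` (with `0 ln 0 = 0`) measures how
#' evenly the attribute is spread over the nodes: `E_j = 1` for a uniform
#' column, 0 for a one-hot column. The weight of attribute j is
#' `w_j = (1 - E_j) / sum_j (1 - E_j)`, so attributes that discriminate
#' more between nodes (lower entropy) weigh more.
#'
#' Degenerate cases: an all-zero source column carries no information and
#' its weight is forced to 0 before renormalizing; when every remaining
#' entropy equals 1 (all attributes uniform, e.g. on a vertex-transitive
#' graph) the weights fall back to equal weights over the non-degenerate
#' attributes, which leaves the (total-tie) ranking unchanged under any
#' weighting.
#'
#' @param normalized A normalized attribute tibble from
#'   [normalize_attributes()], with at least 2 rows.
#' @return A tibble with columns `attribute`, `entropy`, `weight`; weights
#'   sum to 1.
#' @export
entropy_weights <- function(normalized) {
  stopifnot(is.data.frame(normalized), "node" %in% names(normalized))
  cols <- names(normalized)[vapply(normalized, is.numeric, TRUE)]
  n <- nrow(normalized)
  if (n < 2L) stop("entropy weights need at least 2 nodes (ln n = 0 for n = 1)",
                   call. = FALSE)
  ent <- vapply(cols, function(cl) {
    r <- normalized[[cl]]
    pos <- r > 0
    if (!any(pos)) return(NA_real_) # all-zero source column
    -sum(r[pos] * log(r[pos])) / log(n)
  }, numeric(1))
  # 1 - E can dip epsilon-negative in floating point; clamp at 0.
  raw_w <- pmax(1 - ent, 0)
  raw_w[is.na(ent)] <- 0
  if (sum(raw_w) <= 1e-12) {
    live <- !is.na(ent)
    if (!any(live)) live <- rep(TRUE, length(cols))
    w <- ifelse(live, 1 / sum(live), 0)
  } else {
    w <- raw_w / sum(raw_w)
  }
  tibble(
    attribute = cols,
    entropy = unname(ifelse(is.na(ent), 0, ent)),
    weight = unname(w)
  )
}

#' Weighted LWC scores
#'
#' The LWC value of node i is the weighted row sum
#' `sum_j w_j r_ij` of its normalized attributes.
#'
#' @param normalized Normalized attribute tibble ([normalize_attributes()]).
#' @param weights Weight tibble from [entropy_weights()] (its `attribute`
#'   column must match the attribute columns of `normalized`).
#' @return A tibble with columns `node`, `score`.
#' @export
lwc_scores <- function(normalized, weights) {
  stopifnot(is.data.frame(normalized), "node" %in% names(normalized))
  cols <- names(normalized)[vapply(normalized, is.numeric, TRUE)]
  if (!setequal(cols, weights$attribute)) {
    stop("weights do not match the attribute columns of the normalized matrix",
         call. = FALSE)
  }
  w <- setNames(weights$weight, weights$attribute)[cols]
  score <- as.numeric(as.matrix(normalized[cols]) %*% w)
  tibble(node = normalized$node, score = score)
}

#' Rank nodes by score, descending, with tie-aware ranks
#'
#' Nodes are ordered by decreasing score; nodes whose scores agree to
#' `signif_digits` significant digits share a rank, and ranks run 1, 2, ...
#' over the distinct score values (dense ranking, so tie-group sizes are
#' what the monotonicity metric consumes). Tied nodes are listed in node
#' label order, which makes the output deterministic.
#'
#' @param scores A tibble with columns `node` and `score` (any per-node
#'   score: LWC, a baseline centrality, or mean SIR spread).
#' @param signif_digits Number of significant digits at which two scores
#'   are considered equal (default 12). A relative, not absolute,
#'   tolerance: centralities on large sparse graphs can be of order 1e-5
#'   with genuine differences near 1e-10.
#' @return A tibble with columns `node`, `score`, `rank`, sorted by
#'   descending score.
#' @examples
#' rank_nodes(tibble::tibble(node = c("a", "b", "c", "d"),
#'                           score = c(0.5, 0.3, 0.3, 0.1)))
#' @export
rank_nodes <- function(scores, signif_digits = 12) {
  stopifnot(is.data.frame(scores), all(c("node", "score") %in% names(scores)))
  key <- signif(scores$score, signif_digits)
  # position of each node in label order, used to break ties deterministically
  lab_rank <- integer(nrow(scores))
  lab_rank[label_order(scores$node)] <- seq_len(nrow(scores))
  ord <- order(-key, lab_rank, method = "radix")
  key_sorted <- key[ord]
  rank_vals <- cumsum(c(1L, diff(match(key_sorted, unique(key_sorted))) != 0L))
  tibble(
    node = scores$node[ord],
    score = scores$score[ord],
    rank = as.integer(rank_vals)
  )
}

#' Multiple-local-attributes weighted centrality (LWC)
#'
#' Runs the full LWC pipeline on a graph: build the node-by-attribute
#' decision matrix (degree, two-hop degree, clustering coefficient,
#' two-hop clustering coefficient), normalize each attribute column,
#' derive entropy weights, score every node with the weighted sum, and
#' rank in descending score order.
#'
#' @param graph An igraph graph with at least 2 nodes.
#' @param signif_digits Tie tolerance passed to [rank_nodes()].
#' @return A tibble of class `lwc_ranking` with columns `node`, `score`,
#'   `rank`, plus attributes `weights` (the [entropy_weights()] tibble) and
#'   `attributes` (the raw decision matrix). Use [tidy()] / [glance()] to
#'   extract them.
#' @examples
#' fit <- lwc(toy_graph("triangle_tail"))
#' fit
#' glance(fit)
#' @export
lwc <- function(graph, signif_digits = 12) {
  assert_graph(graph)
  attrs <- local_attributes(graph)
  norm <- normalize_attributes(attrs)
  w <- entropy_weights(norm)
  ranking <- rank_nodes(lwc_scores(norm, w), signif_digits = signif_digits)
  structure(
    ranking,
    weights = w,
    attributes = attrs,
    class = c("lwc_ranking", class(ranking))
  )
}

#' @export
tidy.lwc_ranking <- function(x, ...) {
  tibble(node = x$node, score = x$score, rank = x$rank)
}

#' @export
glance.lwc_ranking <- function(x, ...) {
  w <- attr(x, "weights")
  out <- tibble(
    n_nodes = nrow(x),
    n_distinct_ranks = length(unique(x$rank)),
    monotonicity = monotonicity(x)
  )
  if (!is.null(w)) {
    wide <- setNames(as.list(w$weight), paste0("w_", w$attribute))
    out <- dplyr::bind_cols(out, as_tibble(wide))
  }
  out
}

#' @export
print.lwc_ranking <- function(x, ...) {
  w <- attr(x, "weights")
  cat("LWC ranking of", nrow(x), "nodes\n")
  if (!is.null(w)) {
    cat("entropy weights:",
        paste(sprintf("%s=%.4f", w$attribute, w$weight), collapse = ", "), "\n")
  }
  print(tidy(x), ...)
  invisible(x)
}
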