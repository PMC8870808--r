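# Ranking-quality metrics: monotonicity (tie discrimination), CCDF of
# scores, Kendall tau-a against the SIR ground truth, the imprecision
# function of the top-p fraction, and top-k Jaccard similarity.

#' Monotonicity of a ranking
#'
#' `M(S) = (1 - sum_s n_s (n_s - 1) / (n (n - 1)))^2`, where `n_s` are the
#' tie-group sizes of the ranking. 1 means every node has a unique rank
#' (perfect discrimination); 0 means all nodes are tied. Depends only on
#' the tie pattern, so it is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param ranking A ranking tibble from [rank_nodes()] (columns `node`,
#'   `score`, `rank`) covering at least 2 nodes.
#' @return `M` in \[0, 1\].
#' @examples
#' monotonicity(rank_nodes(tibble::tibble(node = letters[1:4],
#'                                        score = c(4, 3, 3, 1))))
#' @export
monotonicity <- function(ranking) {
  stopifnot(is.data.frame(ranking), "rank" %in% names(ranking))
  n <- nrow(ranking)
  if (n < 2L) stop("monotonicity needs at least 2 ranked nodes", call. = FALSE)
  sizes <- tabulate(ranking$rank)
  (1 - sum(sizes * (sizes - 1)) / (n * (n - 1)))^2
}

#' Complementary cumulative distribution of ranking scores
#'
#' For every distinct score value `s` (descending), the fraction of nodes
#' whose score is at least `s`. A slowly decaying CCDF over many distinct
#' values indicates fine rank discrimination; a method that ties many
#' nodes produces few, large steps.
#'
#' @param ranking A ranking tibble from [rank_nodes()].
#' @return A tibble with columns `score`, `fraction`, one row per distinct
#'   score, in descending score order; `fraction` reaches 1 at the
#'   minimum score.
#' @export
ccdf_curve <- function(ranking) {
  stopifnot(is.data.frame(ranking), all(c("score", "rank") %in% names(ranking)))
  n <- nrow(ranking)
  grp <- dplyr::summarise(
    dplyr::group_by(ranking, .data$rank),
    score = dplyr::first(.data$score),
    count = dplyr::n(),
    .groups = "drop"
  )
  grp <- dplyr::arrange(grp, .data$rank)
  tibble(score = grp$score, fraction = cumsum(grp$count) / n)
}

kendall_tau_values <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    s <- s + sum(sign((x[i] - x[rest]) * (y[i] - y[rest])))
  }
  s / (0.5 * n * (n - 1))
}

#' Kendall tau-a between two rankings
#'
#' `tau = sum_{i<j} sgn((x_i - x_j)(y_i - y_j)) / (n (n - 1) / 2)` on the
#' rank values of the two lists. This is the uncorrected tau-a: tied pairs
#' contribute 0 to the numerator and the denominator counts all pairs, so
#' tie-heavy rankings (e.g. plain degree) are penalized rather than
#' rescaled.
#'
#' @param truth,method Ranking tibbles over the same node set (columns
#'   `node`, `rank`).
#' @return `tau` in \[-1, 1\].
#' @examples
#' a <- rank_nodes(tibble::tibble(node = c("a", "b", "c"), score = 3:1))
#' b <- rank_nodes(tibble::tibble(node = c("a", "b", "c"), score = c(3, 1, 2)))
#' kendall_tau(a, b) # 1/3
#' @export
kendall_tau <- function(truth, method) {
  stopifnot(is.data.frame(truth), is.data.frame(method))
  if (!setequal(truth$node, method$node) ||
      nrow(truth) != nrow(method)) {
    stop("the two rankings must cover the same node set", call. = FALSE)
  }
  x <- truth$rank
  y <- method$rank[match(truth$node, method$node)]
  kendall_tau_values(x, y)
}

#' Imprecision of a method's top-p node set
#'
#' `eps(p) = 1 - M(p) / M_eff(p)`, where `M(p)` is the mean SIR influence
#' of the top `ceiling(p * n)` nodes of the method's ranking and
#' `M_eff(p)` the mean influence of the truly top `ceiling(p * n)` nodes
#' (by influence). 0 means the method's top set spreads as much as the
#' optimal one; the value is reported unclamped, so Monte-Carlo noise can
#' make it slightly negative when the method's set out-spreads the
#' truth's.
#'
#' @param influence An [influence_table()] tibble (columns `node`,
#'   `influence`).
#' @param method A ranking tibble over the same node set.
#' @param p Fraction of nodes to inspect, in (0, 1\].
#' @return `eps(p)` as a single number.
#' @export
imprecision <- function(influence, method, p) {
  stopifnot(is.data.frame(influence), all(c("node", "influence") %in% names(influence)))
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("`p` must be a single value in (0, 1]", call. = FALSE)
  }
  if (!setequal(influence$node, method$node)) {
    stop("influence table and ranking must cover the same node set", call. = FALSE)
  }
  n <- nrow(influence)
  top <- ceiling(p * n)
  truth_rank <- rank_nodes(tibble(node = influence$node, score = influence$influence))
  inf_of <- setNames(influence$influence, influence$node)
  m_meth <- mean(inf_of[method$node[seq_len(top)]])
  m_eff <- mean(inf_of[truth_rank$node[seq_len(top)]])
  1 - m_meth / m_eff
}

#' Jaccard similarity of two top-k node sets
#'
#' `J(T) = |top_T(truth) intersect top_T(method)| /
#' |top_T(truth) union top_T(method)|`, using the first `T` rows of each
#' ranking (rankings list tied nodes in deterministic label order).
#'
#' @param truth,method Ranking tibbles over the same node set.
#' @param top_t Number of top nodes to compare, `1 <= top_t <= n`.
#' @return `J` in \[0, 1\]; always 1 at `top_t = n`.
#' @export
jaccard_topk <- function(truth, method, top_t) {
  n <- nrow(truth)
  if (length(top_t) != 1L || is.na(top_t) || top_t < 1 || top_t > n) {
    stop("`top_t` must be in [1, n]", call. = FALSE)
  }
  if (!setequal(truth$node, method$node)) {
    stop("the two rankings must cover the same node set", call. = FALSE)
  }
  a <- truth$node[seq_len(top_t)]
  b <- method$node[seq_len(top_t)]
  length(intersect(a, b)) / length(union(a, b))
}

#' Evaluate centrality methods against the SIR ground truth
#'
#' Runs the full evaluation protocol on one graph: simulate the SIR ground
#' truth once ([influence_table()]), rank every requested method, and
#' score each ranking with monotonicity, Kendall tau-a against the ground
#' truth, the imprecision curve over `p_grid`, the top-k Jaccard curve
#' over `top_k`, and the score CCDF.
#'
#' @param graph An igraph graph.
#' @param methods Character vector of method names (see
#'   [centrality_ranking()]).
#' @param beta,gamma,runs,rng_seed SIR parameters, as in
#'   [influence_table()].
#' @param p_grid Fractions for the imprecision curve (default 0.01 to 0.10
#'   in steps of 0.01).
#' @param top_k Top-set sizes for the Jaccard curve (default 10, 20, 100,
#'   capped at n).
#' @return An object of class `lwc_evaluation`: a list with tibbles
#'   `summary` (method, monotonicity, kendall_tau), `imprecision`,
#'   `jaccard`, `ccdf`, the `influence` table, the `truth` ranking, the
#'   per-method `rankings`, and the resolved `config`. `tidy()` returns
#'   the summary; `autoplot()` draws the curves.
#' @examples
#' \donttest{
#' ev <- evaluate_methods(generate_ba(60, 2, rng_seed = 1),
#'                        methods = c("degree", "lwc"), runs = 30)
#' tidy(ev)
#' }
#' @export
evaluate_methods <- function(graph, methods = c("degree", "bc", "cc", "localc",
                                                "cld", "lwc"),
                             beta = "auto", gamma = 1, runs = 100,
                             rng_seed = 1,
                             p_grid = seq(0.01, 0.1, by = 0.01),
                             top_k = c(10, 20, 100)) {
  assert_graph(graph)
  methods <- match.arg(methods, centrality_methods, several.ok = TRUE)
  if (any(p_grid <= 0 | p_grid > 1)) stop("`p_grid` must lie in (0, 1]", call. = FALSE)
  n <- igraph::vcount(graph)
  top_k <- sort(unique(pmin(as.integer(top_k), n)))
  influence <- influence_table(graph, beta = beta, gamma = gamma, runs = runs,
                               rng_seed = rng_seed)
  truth <- rank_nodes(tibble(node = influence$node, score = influence$influence))
  rankings <- lapply(setNames(methods, methods),
                     function(m) centrality_ranking(graph, m))
  summary <- dplyr::bind_rows(lapply(methods, function(m) {
    tibble(method = m,
           monotonicity = monotonicity(rankings[[m]]),
           kendall_tau = kendall_tau(truth, rankings[[m]]))
  }))
  imp <- tidyr::expand_grid(method = methods, p = p_grid)
  imp$imprecision <- purrr::map2_dbl(imp$method, imp$p, function(m, p) {
    imprecision(influence, rankings[[m]], p)
  })
  jac <- tidyr::expand_grid(method = methods, top_t = top_k)
  jac$jaccard <- purrr::map2_dbl(jac$method, jac$top_t, function(m, tt) {
    jaccard_topk(truth, rankings[[m]], tt)
  })
  ccdf <- dplyr::bind_rows(lapply(methods, function(m) {
    dplyr::mutate(ccdf_curve(rankings[[m]]), method = m, .before = 1)
  }))
  structure(
    list(summary = summary, imprecision = imp, jaccard = jac, ccdf = ccdf,
         influence = influence, truth = truth, rankings = rankings,
         config = attr(influence, "config")),
    class = "lwc_evaluation"
  )
}

#' @export
tidy.lwc_evaluation <- function(x, ...) x$summary

#' @export
glance.lwc_evaluation <- function(x, ...) {
  cfg <- x$config
  tibble(n_nodes = nrow(x$influence), n_methods = nrow(x$summary),
         beta = cfg$beta, gamma = cfg$gamma, runs = cfg$runs,
         rng_seed = cfg$rng_seed)
}

#' @export
print.lwc_evaluation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("SIR-based evaluation (beta = %.4f, gamma = %g, runs = %d, seed = %d)\n",
              cfg$beta, cfg$gamma, cfg$runs, cfg$rng_seed))
  print(x$summary, ...)
  invisible(x)
}
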