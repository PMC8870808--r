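attr_tbl <- function(...) {
  cols <- list(...)
  tibble::tibble(node = as.character(seq_along(cols[[1]])), !!!cols)
}

test_that("column normalization: max-divide then sum-divide", {
  out <- normalize_attributes(attr_tbl(k = c(2, 2, 3, 2, 1)))
  expect_equal(out$k, c(0.2, 0.2, 0.3, 0.2, 0.1))

  out2 <- normalize_attributes(attr_tbl(k = rep(7, 4)))
  expect_equal(out2$k, rep(0.25, 4))

  out3 <- normalize_attributes(attr_tbl(k = c(1, 2), clc = c(0, 0)))
  expect_equal(out3$clc, c(0, 0))
  expect_error(normalize_attributes(attr_tbl(k = c(-1, 2))), "non-negative")
})

test_that("normalization is invariant under uniform scaling of a raw column", {
  at <- local_attributes(toy_graph("triangle_tail"))
  scaled <- dplyr::mutate(at, k = k * 17.5, thclc = thclc * 0.03)
  expect_equal(normalize_attributes(at), normalize_attributes(scaled))
})

test_that("entropies hit their closed forms", {
  w <- entropy_weights(attr_tbl(a = rep(0.2, 5)))
  expect_equal(w$entropy[w$attribute == "a"], 1)

  onehot <- entropy_weights(attr_tbl(a = c(1, 0, 0, 0), b = c(.25, .25, .25, .25)))
  expect_equal(onehot$entropy, c(0, 1))
  expect_equal(onehot$weight, c(1, 0)) # all weight on the discriminating column

  mid <- entropy_weights(attr_tbl(a = c(0.2, 0.2, 0.3, 0.2, 0.1)))
  expect_equal(mid$entropy, 0.9674887649, tolerance = 1e-9)

  expect_error(entropy_weights(attr_tbl(a = 1)), "at least 2")
})

test_that("degenerate columns are handled: zero columns, all-uniform fallback", {
  # all-zero column gets weight 0 even though its raw entropy would be minimal
  w <- entropy_weights(attr_tbl(a = c(0.1, 0.3, 0.6), z = c(0, 0, 0)))
  expect_equal(w$weight[w$attribute == "z"], 0)
  expect_equal(sum(w$weight), 1)

  # every column uniform -> equal weights
  u <- entropy_weights(attr_tbl(a = rep(1 / 3, 3), b = rep(1 / 3, 3),
                                c = rep(1 / 3, 3), d = rep(1 / 3, 3)))
  expect_equal(u$weight, rep(0.25, 4))

  # uniform + all-zero mix -> equal weights over the live columns only
  m <- entropy_weights(attr_tbl(a = rep(0.25, 4), z = rep(0, 4)))
  expect_equal(m$weight, c(1, 0))
})

test_that("weighted scores project and conserve mass", {
  norm <- normalize_attributes(local_attributes(toy_graph("k5")))
  w <- entropy_weights(norm)
  sc <- lwc_scores(norm, w)
  expect_equal(sc$score, rep(1 / 5, 5)) # symmetry: every node 1/n

  # weights (1,0,0,0) project onto the normalized degree column
  wdeg <- tibble::tibble(attribute = c("k", "thk", "clc", "thclc"),
                         entropy = 0, weight = c(1, 0, 0, 0))
  norm2 <- normalize_attributes(local_attributes(toy_graph("triangle_tail")))
  expect_equal(lwc_scores(norm2, wdeg)$score, norm2$k)

  bad <- tibble::tibble(attribute = c("x", "y"), entropy = 0, weight = c(.5, .5))
  expect_error(lwc_scores(norm2, bad), "do not match")
})

test_that("rank_nodes produces dense, tie-aware, deterministic ranks", {
  r <- make_ranking(c("d", "b", "c", "a"), c(0.1, 0.3, 0.3, 0.5))
  expect_equal(r$node, c("a", "b", "c", "d"))
  expect_equal(r$rank, c(1L, 2L, 2L, 3L))

  tied <- make_ranking(c("3", "1", "2"), rep(1, 3))
  expect_equal(tied$rank, rep(1L, 3))
  expect_equal(tied$node, c("1", "2", "3")) # label order within ties

  # near-equal scores below the significant-digit tolerance are tied
  near <- make_ranking(c("a", "b"), c(1, 1 + 1e-14))
  expect_equal(near$rank, c(1L, 1L))
})

test_that("the full pipeline matches the direct-formula oracle to 1e-12", {
  for (g in fixture_battery()) {
    fit <- lwc(g)
    oracle <- lwc_direct_oracle(g)
    labs <- igraph::V(g)$name
    expect_equal(fit$score[match(labs, fit$node)], oracle$scores,
                 tolerance = 1e-12)
    expect_equal(attr(fit, "weights")$weight, oracle$weights, tolerance = 1e-12)
    expect_equal(attr(fit, "weights")$entropy, oracle$entropies, tolerance = 1e-12)
  }
})

test_that("weights and normalized columns conserve their sums", {
  for (g in list(toy_graph("triangle_tail"), generate_ba(30, 2, 5))) {
    norm <- normalize_attributes(local_attributes(g))
    for (cl in c("k", "thk", "clc", "thclc")) {
      s <- sum(norm[[cl]])
      expect_true(abs(s - 1) < 1e-9 || s == 0)
    }
    w <- entropy_weights(norm)
    expect_equal(sum(w$weight), 1, tolerance = 1e-9)
    expect_true(all(w$weight >= 0))
    expect_true(all(w$entropy >= 0 & w$entropy <= 1 + 1e-12))
  }
})

test_that("vertex-transitive graphs give every node the same LWC and rank 1", {
  for (nm in c("c5", "k4", "k5")) {
    fit <- lwc(toy_graph(nm))
    expect_equal(unique(fit$rank), 1L)
    expect_length(unique(fit$score), 1)
  }
})

test_that("on the triangle-with-tail the entropy weighting favours clustering", {
  # clc is the most discriminating column on this fixture, so nodes 1 and 2
  # (clc = 1) share the top rank and the hub node 3 comes second, even
  # though node 3 dominates the k and thk columns.
  fit <- lwc(toy_graph("triangle_tail"))
  top <- fit$node[fit$rank == 1L]
  expect_setequal(top, c("1", "2"))
  expect_equal(fit$rank[fit$node == "3"], 2L)
  at <- attr(fit, "attributes")
  expect_equal(at$node[which.max(at$k)], "3")
  expect_equal(at$node[which.max(at$thk)], "3")
  w <- attr(fit, "weights")
  expect_gt(w$weight[w$attribute == "clc"], w$weight[w$attribute == "k"])
})

test_that("tidy and glance expose the fit", {
  fit <- lwc(toy_graph("triangle_tail"))
  td <- tidy(fit)
  expect_named(td, c("node", "score", "rank"))
  gl <- glance(fit)
  expect_equal(gl$n_nodes, 5)
  expect_equal(gl$w_k + gl$w_thk + gl$w_clc + gl$w_thclc, 1, tolerance = 1e-12)
  expect_true(gl$monotonicity > 0 && gl$monotonicity <= 1)
})
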