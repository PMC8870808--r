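test_that("monotonicity reflects the tie structure", {
  distinct <- make_ranking(letters[1:5], c(5, 4, 3, 2, 1))
  expect_equal(monotonicity(distinct), 1)

  tied <- make_ranking(letters[1:4], rep(1, 4))
  expect_equal(monotonicity(tied), 0)

  one_pair <- make_ranking(letters[1:4], c(4, 3, 3, 1))
  expect_equal(monotonicity(one_pair), 25 / 36)

  expect_error(monotonicity(make_ranking("a", 1)), "at least 2")
})

test_that("monotonicity is invariant under strictly monotone score transforms", {
  sc <- c(9, 7, 7, 4, 2, 2, 2, 1)
  a <- make_ranking(letters[1:8], sc)
  b <- make_ranking(letters[1:8], exp(sc / 3))
  expect_equal(monotonicity(a), monotonicity(b))
})

test_that("ccdf curve steps through distinct scores and ends at 1", {
  r <- make_ranking(letters[1:4], c(4, 3, 2, 1))
  cc <- ccdf_curve(r)
  expect_equal(cc$fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(cc$score, c(4, 3, 2, 1))

  tied <- ccdf_curve(make_ranking(letters[1:4], rep(2, 4)))
  expect_equal(nrow(tied), 1)
  expect_equal(tied$fraction, 1)
})

test_that("kendall tau-a matches enumeration and the tie-free library value", {
  a <- make_ranking(c("1", "2", "3"), c(3, 2, 1))
  b <- make_ranking(c("1", "2", "3"), c(3, 1, 2))
  expect_equal(kendall_tau(a, a), 1)
  expect_equal(kendall_tau(a, b), 1 / 3)

  rev_b <- make_ranking(c("1", "2", "3"), c(1, 2, 3))
  expect_equal(kendall_tau(a, rev_b), -1)

  # random permutations, no ties: equals cor(..., method = "kendall")
  for (n in c(50, 120, 200)) {
    set.seed(n)
    x <- sample(n); y <- sample(n)
    ra <- make_ranking(as.character(1:n), -x)
    rb <- make_ranking(as.character(1:n), -y)
    expect_equal(kendall_tau(ra, rb),
                 unname(stats::cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }

  # with ties: matches the dense outer-product oracle
  set.seed(99)
  x <- sample(1:4, 30, replace = TRUE)
  y <- sample(1:6, 30, replace = TRUE)
  ra <- make_ranking(as.character(1:30), -x)
  rb <- make_ranking(as.character(1:30), -y)
  xr <- ra$rank[match(as.character(1:30), ra$node)]
  yr <- rb$rank[match(as.character(1:30), rb$node)]
  expect_equal(kendall_tau(ra, rb), kendall_tau_brute_oracle(xr, yr))

  expect_error(kendall_tau(a, make_ranking(c("1", "2", "9"), 1:3)),
               "same node set")
})

test_that("imprecision measures the spreading shortfall of the top-p set", {
  inf <- structure(
    tibble::tibble(node = as.character(1:10), influence = 10:1),
    class = c("tbl_df", "tbl", "data.frame")
  )
  truth_like <- make_ranking(as.character(1:10), 10:1)
  expect_equal(imprecision(inf, truth_like, 0.3), 0)
  expect_equal(imprecision(inf, truth_like, 1), 0)

  # method's top 3 are the nodes ranked 2, 3, 4 by the truth
  method <- make_ranking(as.character(1:10), c(1, 10, 9, 8, 2, 3, 4, 5, 6, 7) / 10)
  expect_equal(imprecision(inf, method, 0.3), 1 - 8 / 9)

  # bottom-picking method: positive by construction
  bottom <- make_ranking(as.character(1:10), 1:10)
  eps <- imprecision(inf, bottom, 0.3)
  expect_equal(eps, 1 - 2 / 9)
  expect_gt(eps, 0)

  expect_error(imprecision(inf, truth_like, 0), "p")
  expect_error(imprecision(inf, truth_like, 1.2), "p")
})

test_that("top-k jaccard counts set overlap", {
  a <- make_ranking(c("a", "b", "c", "d"), c(4, 3, 2, 1))
  b <- make_ranking(c("a", "b", "c", "d"), c(1, 4, 3, 2))
  expect_equal(jaccard_topk(a, a, 2), 1)
  expect_equal(jaccard_topk(a, b, 2), 1 / 3) # {a,b} vs {b,c}
  expect_equal(jaccard_topk(a, b, 4), 1)     # full sets always coincide
  c_ <- make_ranking(c("a", "b", "c", "d"), c(1, 2, 3, 4))
  expect_equal(jaccard_topk(a, c_, 2), 0)
  expect_error(jaccard_topk(a, b, 0), "top_t")
  expect_error(jaccard_topk(a, b, 5), "top_t")
})

test_that("evaluate_methods runs the full protocol reproducibly", {
  g <- generate_ba(40, 2, rng_seed = 3)
  ev <- evaluate_methods(g, methods = c("degree", "lwc"), beta = 0.3,
                         runs = 20, rng_seed = 4, p_grid = c(0.05, 0.1),
                         top_k = c(5, 10))
  expect_setequal(ev$summary$method, c("degree", "lwc"))
  expect_true(all(ev$summary$kendall_tau >= -1 & ev$summary$kendall_tau <= 1))
  expect_true(all(ev$summary$monotonicity >= 0 & ev$summary$monotonicity <= 1))
  expect_equal(nrow(ev$imprecision), 4)
  expect_equal(nrow(ev$jaccard), 4)

  # evaluating the truth against itself: tau-a equals 1 minus the tied-pair
  # fraction (tied pairs add 0 to the numerator), eps = 0, J = 1
  sizes <- tabulate(ev$truth$rank)
  expect_equal(kendall_tau(ev$truth, ev$truth),
               1 - sum(sizes * (sizes - 1)) / (40 * 39))
  expect_equal(imprecision(ev$influence, ev$truth, 0.1), 0)
  expect_equal(jaccard_topk(ev$truth, ev$truth, 10), 1)

  ev2 <- evaluate_methods(g, methods = c("degree", "lwc"), beta = 0.3,
                          runs = 20, rng_seed = 4, p_grid = c(0.05, 0.1),
                          top_k = c(5, 10))
  expect_identical(ev$summary, ev2$summary)
})

test_that("total-tie ground truth yields tau 0 under tau-a", {
  # beta = 0: every influence is exactly 1, all truth ranks tie, the tau
  # numerator vanishes
  ev <- evaluate_methods(toy_graph("k5"), methods = c("degree", "lwc"),
                         beta = 0, runs = 5, rng_seed = 1,
                         p_grid = 0.2, top_k = 5)
  expect_equal(ev$influence$influence, rep(1, 5))
  expect_equal(ev$summary$kendall_tau, c(0, 0))
})

test_that("autoplot returns ggplot objects for every panel", {
  g <- generate_ba(30, 2, rng_seed = 6)
  ev <- evaluate_methods(g, methods = c("degree", "lwc"), beta = 0.3,
                         runs = 10, rng_seed = 1, p_grid = 0.1, top_k = 5)
  for (tp in c("ccdf", "imprecision", "jaccard")) {
    expect_s3_class(autoplot(ev, type = tp), "ggplot")
  }
  expect_s3_class(autoplot(lwc(g)), "ggplot")
})
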