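test_that("Pearson matrix matches the defining sum formula", {
  # 3 channels x 5 samples, computed by the explicit sums
  x <- rbind(c(1, 3, 2, 5, 4), c(2, 2, 4, 6, 7), c(9, 7, 5, 3, 1))
  rec <- make_rec(x, c("A", "B", "C"), fs = 10)
  cm <- correlation_matrix(rec)
  manual_r <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cm$r["A", "B"], manual_r(x[1, ], x[2, ]))
  expect_equal(cm$r["A", "C"], manual_r(x[1, ], x[3, ]))
  expect_equal(cm$r["B", "C"], manual_r(x[2, ], x[3, ]))
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
})

test_that("exact copies and negations give r of 1 and -1", {
  set.seed(41)
  a <- rnorm(100)
  cm <- correlation_matrix(make_rec(rbind(a, a, -a), c("X", "Y", "Z"), fs = 100))
  expect_equal(cm$r["X", "Y"], 1)
  expect_equal(cm$r["X", "Z"], -1)
  zed <- make_rec(rbind(a, rep(2, 100)), c("X", "FLAT"), fs = 100)
  expect_error(correlation_matrix(zed), "FLAT")
})

test_that("binarize handles complete and empty graphs", {
  r <- matrix(0.9, 5, 5); diag(r) <- 1
  cm <- structure(list(r = r, channels = LETTERS[1:5], band = "t"),
                  class = "corr_matrix")
  full <- binarize(cm, 0.5)
  expect_equal(unname(full$degree), rep(4, 5))
  expect_equal(unname(full$clustering), rep(1, 5))
  expect_equal(full$density, 1)

  r2 <- matrix(0.1, 5, 5); diag(r2) <- 1
  cm2 <- structure(list(r = r2, channels = LETTERS[1:5], band = "t"),
                   class = "corr_matrix")
  empty <- binarize(cm2, 0.5)
  expect_equal(unname(empty$degree), rep(0, 5))
  expect_equal(unname(empty$clustering), rep(0, 5))
  expect_error(binarize(cm2, 1.2), "threshold")
})

test_that("degree and clustering match the exhaustive oracle and igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:100) {
    n <- sample(4:8, 1)
    cm <- random_cm(n, 4100 + seed)
    net <- binarize(cm, 0.3)
    oracle <- brute_metrics(net$adjacency)
    expect_equal(unname(net$degree), oracle$degree)
    expect_equal(unname(net$clustering), oracle$clustering)
    # independent library cross-check
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
    expect_equal(unname(net$degree), as.numeric(igraph::degree(g)))
    ig_c <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    ig_c[is.nan(ig_c)] <- 0
    expect_equal(unname(net$clustering), ig_c)
    # adjacency invariants
    expect_true(all(net$adjacency == t(net$adjacency)))
    expect_equal(unname(diag(net$adjacency)), rep(0L, n))
    expect_equal(sum(net$degree) %% 2, 0)
  }
})

test_that("raising the threshold never adds edges or degree", {
  for (seed in 1:50) {
    cm <- random_cm(10, 4200 + seed)
    prev <- binarize(cm, 0.1)
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      cur <- binarize(cm, th)
      expect_true(all(cur$degree <= prev$degree))
      expect_lte(sum(cur$adjacency), sum(prev$adjacency))
      prev <- cur
    }
  }
})

test_that("threshold selection honors isolation and density criteria", {
  # two dense 4-node blocks joined by weaker bridges
  r <- matrix(0.2, 8, 8)
  r[1:4, 1:4] <- 0.8; r[5:8, 5:8] <- 0.8
  r[1, 5] <- r[5, 1] <- r[2, 6] <- r[6, 2] <- 0.6
  diag(r) <- 1
  cm <- structure(list(r = r, channels = sprintf("N%d", 1:8), band = "t"),
                  class = "corr_matrix")
  th <- select_threshold(cm, c(0.1, 0.5))
  net <- binarize(cm, th)
  expect_true(all(net$degree > 0))
  expect_gte(net$density, 0.1)
  expect_lte(net$density, 0.5)
  # largest qualifying grid value: every higher grid step must fail a criterion
  for (higher in seq(th + 0.01, 0.99, by = 0.01)) {
    nh <- binarize(cm, higher)
    expect_true(any(nh$degree == 0) || nh$density < 0.1 || nh$density > 0.5)
  }

  # complete matrix at r = 0.9: largest no-isolation grid value is selected
  rc <- matrix(0.9, 5, 5); diag(rc) <- 1
  cmc <- structure(list(r = rc, channels = LETTERS[1:5], band = "t"),
                   class = "corr_matrix")
  th_c <- suppressWarnings(select_threshold(cmc, c(0.5, 0.99)))
  expect_true(th_c %in% c(0.89, 0.90))
  expect_true(all(binarize(cmc, th_c)$degree > 0))

  # uncorrelated input: nothing connects
  ri <- diag(5)
  cmi <- structure(list(r = ri, channels = LETTERS[1:5], band = "t"),
                   class = "corr_matrix")
  expect_error(select_threshold(cmi), "isolated")
})

test_that("network features report node rows plus whole-network means", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  cm <- structure(list(r = tri * 0.9 + diag(3), channels = c("A", "B", "C"),
                       band = "t"), class = "corr_matrix")
  feats <- network_features(binarize(cm, 0.5))
  wb <- dplyr::filter(feats, channel == "whole_brain")
  expect_equal(wb$value[wb$feature_name == "degree"], 2)
  expect_equal(wb$value[wb$feature_name == "clustering"], 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 0.9; star <- star + t(star); diag(star) <- 1
  cms <- structure(list(r = star, channels = sprintf("N%d", 1:5), band = "t"),
                   class = "corr_matrix")
  net <- binarize(cms, 0.5)
  expect_equal(unname(net$degree), c(4, 1, 1, 1, 1))
  expect_equal(unname(net$clustering), rep(0, 5))
  el <- edge_list(net)
  expect_equal(nrow(el), 4)
  expect_true(all(el$channel_a == "N1"))
})
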