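two_triangles <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
}

random_weighted_graph <- function(n, p_edge = 0.4, max_w = 5) {
  repeat {
    adj <- matrix(stats::runif(n * n) < p_edge, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    if (any(adj)) break
  }
  el <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = letters[el[, 1]], to = letters[el[, 2]],
               weight = sample.int(max_w, nrow(el), replace = TRUE)),
    directed = FALSE,
    vertices = data.frame(name = letters[1:n])
  )
  g
}

test_that("score_modularity reproduces closed-form cases", {
  tri2 <- two_triangles()
  one <- stats::setNames(rep(1, 6), letters[1:6])
  expect_equal(score_modularity(tri2, one), 0)

  by_triangle <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(score_modularity(tri2, by_triangle), 0.5) # 2*(3/6 - (6/12)^2)

  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  singletons <- stats::setNames(1:3, letters[1:3])
  expect_equal(score_modularity(tri, singletons), -1 / 3)

  # coverage error
  expect_error(score_modularity(tri, c(a = 1, b = 1)),
               class = "tcmnet_coverage_error")
  # edgeless graph
  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b")
  expect_error(score_modularity(g0, c(a = 1, b = 1)),
               class = "tcmnet_no_edges")
})

test_that("score_modularity agrees with igraph and the direct sum on random instances", {
  withr::local_seed(2024)
  for (rep in 1:50) {
    n <- sample(4:9, 1)
    g <- random_weighted_graph(n)
    memb <- stats::setNames(sample.int(3, n, replace = TRUE),
                            igraph::V(g)$name)
    q <- score_modularity(g, memb)
    expect_equal(q, direct_modularity(g, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
    # unweighted mode matches igraph on weight-1 edges
    q_u <- score_modularity(g, memb, weighted = FALSE)
    expect_equal(q_u, igraph::modularity(g, memb, weights = rep(1, igraph::gsize(g))),
                 tolerance = 1e-12)
  }
})

test_that("fast_greedy recovers cliques, handles disconnection, stays at Q = 0 on a triangle", {
  # two 4-cliques joined by one bridge
  cl <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                           e - f, e - g, e - h, f - g, f - h, g - h,
                           d - e)
  p <- fast_greedy(cl)
  expect_equal(dplyr::n_distinct(p$assignment$community), 2)
  expect_equal(p$membership[c("a", "b", "c", "d")],
               rep(p$membership[["a"]], 4), ignore_attr = TRUE)
  oracle <- exhaustive_best_partition(cl)
  expect_equal(p$modularity, oracle$q, tolerance = 1e-12)

  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  pt <- fast_greedy(tri)
  expect_equal(dplyr::n_distinct(pt$assignment$community), 1)
  expect_equal(pt$modularity, 0)

  # disconnected cliques are never merged
  disc <- igraph::make_graph(~ a - b, b - c, c - a, x - y, y - z, z - x)
  pd <- fast_greedy(disc)
  expect_equal(dplyr::n_distinct(pd$assignment$community), 2)
  expect_equal(pd$modularity, exhaustive_best_partition(disc)$q,
               tolerance = 1e-12)

  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  expect_error(fast_greedy(g0), class = "tcmnet_no_edges")
})

test_that("fast_greedy partition invariants hold and stored Q matches rescoring", {
  withr::local_seed(31)
  for (rep in 1:20) {
    g <- random_weighted_graph(sample(4:10, 1))
    p <- fast_greedy(g)
    labs <- sort(unique(p$assignment$community))
    expect_identical(labs, seq(0L, max(labs))) # contiguous from 0
    expect_equal(nrow(p$assignment), igraph::vcount(g))
    expect_equal(p$modularity, score_modularity(g, p), tolerance = 1e-12)
    expect_gte(p$modularity, -0.5)
    expect_lte(p$modularity, 1)
  }
})

test_that("fast_greedy never beats, and usually attains, the exhaustive optimum", {
  withr::local_seed(5150)
  attained <- 0
  for (rep in 1:15) {
    g <- random_weighted_graph(sample(4:7, 1), p_edge = 0.5)
    p <- fast_greedy(g)
    best <- exhaustive_best_partition(g)
    expect_lte(p$modularity, best$q + 1e-12)
    if (abs(p$modularity - best$q) < 1e-9) attained <- attained + 1
  }
  expect_gte(attained, 1)
})

test_that("node-id permutation changes neither Q nor the communities (up to relabeling)", {
  withr::local_seed(8)
  g <- random_weighted_graph(9, p_edge = 0.35)
  p1 <- fast_greedy(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  p2 <- fast_greedy(g2)
  expect_equal(p1$modularity, p2$modularity, tolerance = 1e-12)
  expect_equal(brute_ari(p1$membership, p2$membership), 1)
})

test_that("compare_partitions rescoring is self-consistent and averages correctly", {
  withr::local_seed(12)
  g <- random_weighted_graph(8)
  cmp <- compare_partitions(list(g1 = g), algos = "fast_greedy")
  expect_equal(cmp$scores$modularity, fast_greedy(g)$modularity)
  expect_equal(cmp$winner, "fast_greedy")

  cmp2 <- compare_partitions(list(g1 = g, g2 = g), algos = "fast_greedy")
  expect_equal(glance(cmp2)$mean_modularity, cmp$scores$modularity)

  expect_error(compare_partitions(list(g1 = g), algos = "no_such_algo"),
               class = "tcmnet_registry_error")

  # an externally registered partitioner is rescored, not trusted
  register_partitioner("all_in_one", function(g) {
    stats::setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  })
  cmp3 <- compare_partitions(list(g1 = g), algos = c("fast_greedy", "all_in_one"))
  expect_equal(cmp3$scores$modularity[cmp3$scores$algorithm == "all_in_one"], 0)
  expect_equal(cmp3$winner, "fast_greedy")
})

test_that("planted disconnected blocks make the planted partition optimal for fast_greedy", {
  ds <- generate_dataset(synthetic_config(n_blocks = 3, cross_block_rate = 0,
                                          seed = 17))
  g <- build_bipartite(ds$incidence)
  p <- project(g, "herb")
  planted <- stats::setNames(planted_partition(ds)$community,
                             planted_partition(ds)$node)
  fg <- fast_greedy(p)
  expect_equal(fg$modularity, score_modularity(p, planted), tolerance = 1e-12)
})

test_that("reduce_graph conserves weight and reproduces small cases", {
  tri2_bridge <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                                    c - d)
  by_tri <- stats::setNames(c(0, 0, 0, 1, 1, 1), letters[1:6])
  r <- reduce_graph(tri2_bridge, by_tri)
  expect_equal(nrow(r$nodes), 2)
  expect_equal(r$edges$weight, 1)
  expect_equal(r$nodes$intra_weight, c(3, 3))

  one <- stats::setNames(rep(0, 6), letters[1:6])
  r1 <- reduce_graph(tri2_bridge, one)
  expect_equal(nrow(r1$nodes), 1)
  expect_equal(nrow(r1$edges), 0)

  withr::local_seed(77)
  for (rep in 1:10) {
    g <- random_weighted_graph(sample(5:10, 1))
    memb <- stats::setNames(sample.int(3, igraph::vcount(g), replace = TRUE),
                            igraph::V(g)$name)
    r <- reduce_graph(g, memb)
    expect_equal(sum(r$edges$weight) + sum(r$nodes$intra_weight),
                 sum(igraph::E(g)$weight))
  }
})

test_that("adjusted_rand matches the contingency-table definition", {
  withr::local_seed(4)
  for (rep in 1:10) {
    n <- 30
    ids <- sprintf("N%02d", 1:n)
    a <- stats::setNames(sample.int(4, n, replace = TRUE), ids)
    b <- stats::setNames(sample.int(3, n, replace = TRUE), ids)
    expect_equal(adjusted_rand(a, b), brute_ari(a, b), tolerance = 1e-12)
  }
  ids <- sprintf("N%02d", 1:10)
  a <- stats::setNames(rep(1:2, each = 5), ids)
  expect_equal(adjusted_rand(a, a), 1)
})

test_that("partition CSV round trip and broom methods", {
  withr::local_seed(3)
  g <- random_weighted_graph(8)
  p <- fast_greedy(g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(p, path)
  back <- read_partition(path)
  expect_equal(back, p$assignment)
  expect_equal(tidy(p), p$assignment)
  gl <- glance(p)
  expect_equal(gl$modularity, p$modularity)
  expect_equal(gl$n_nodes, 8L)
})
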