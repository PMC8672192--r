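# Removal, attribute sampling/binning, and the aggregation operators.

test_that("batch_schedule splits evenly with the remainder up front", {
  expect_equal(batch_schedule(10, removal_schedule(5, 5)), rep(1L, 5))
  s <- batch_schedule(2500, removal_schedule(125, 50))
  expect_length(s, 50L)
  expect_equal(sum(s), 2375L)
  expect_equal(s, c(rep(48L, 25), rep(47L, 25)))
  s2 <- batch_schedule(2500, removal_schedule(125, 35, 1250))
  expect_length(s2, 35L)
  expect_equal(sum(s2), 1125L)
  expect_error(batch_schedule(10, removal_schedule(9, 5)), "infeasible")
})

test_that("remove_nodes_random keeps labels and induces the subgraph", {
  g <- generate_er(60, 250, seed = 4)
  expect_identical(remove_nodes_random(g, 0), g)
  h <- remove_nodes_random(g, 20, seed = 1)
  expect_equal(n_nodes(h), 40L)
  expect_true(all(h$nodes %in% g$nodes))
  # oracle recount: surviving edges = induced subgraph of the survivor set
  keep <- h$nodes
  ind <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, ,
                 drop = FALSE]
  expect_equal(edge_key(h), edge_key(netgraph(keep, ind)))
  expect_error(remove_nodes_random(g, 61), "more nodes")
  # triangle minus one node: 2 nodes, 1 edge, by symmetry
  t1 <- remove_nodes_random(graph_cycle(3), 1, seed = 2)
  expect_equal(c(n_nodes(t1), n_edges(t1)), c(2L, 1L))
})

test_that("remove_edges_random retains nodes and exact counts", {
  g <- generate_er(40, 200, seed = 6)
  expect_identical(remove_edges_random(g, 0), g)
  h <- remove_edges_random(g, 80, seed = 1)
  expect_equal(n_edges(h), 120L)
  expect_equal(h$nodes, g$nodes)
  expect_true(all(edge_key(h) %in% edge_key(g)))
  k5 <- ng(5, t(combn(5, 2)))
  expect_equal(n_edges(remove_edges_random(k5, 10, seed = 1)), 0L)
  expect_equal(n_nodes(remove_edges_random(k5, 10, seed = 1)), 5L)
  expect_error(remove_edges_random(g, 500), "more edges")
})

test_that("sample_skew_normal collapses to the normal at alpha 0 and is seeded", {
  x <- sample_skew_normal(10000, 0, seed = 1)
  expect_gt(stats::ks.test(x, "pnorm")$p.value, 0.01)
  expect_identical(sample_skew_normal(50, 4, seed = 3),
                   sample_skew_normal(50, 4, seed = 3))
  # right skew at alpha = 4
  y <- sample_skew_normal(20000, 4, seed = 2)
  expect_gt(mean((y - mean(y))^3), 0)
})

test_that("bin_values uses equal widths with right-closed last bin", {
  # internal boundary values go to the higher bin (design decision)
  expect_equal(bin_values(c(0, 0.25, 0.5, 0.75, 1), 2), c(1L, 1L, 2L, 2L, 2L))
  expect_equal(bin_values(rep(3.7, 10), 5), rep(1L, 10))
  expect_equal(bin_values(c(-1, 1), 4), c(1L, 4L))
  v <- sample_skew_normal(2500, 4, seed = 9)
  b <- bin_values(v, 50)
  expect_true(all(b >= 1L & b <= 50L))
  # equal widths: recompute interval membership directly
  w <- (max(v) - min(v)) / 50
  expect_true(all(b == pmin(floor((v - min(v)) / w) + 1, 50)))
})

test_that("shared_neighbor_proportion matches the worked six-node example", {
  # nodes 3,4 shared; node 2 sees 100% of its neighbours shared with node 1
  base <- rbind(c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(2, 3), c(2, 4))
  for (edges in list(base, rbind(base, c(1, 2)))) {  # direct edge ignored
    g <- ng(6, edges)
    expect_equal(shared_neighbor_proportion(g, 1, 2), 1.0)
    expect_equal(shared_neighbor_proportion(g, 2, 1), 1.0)
  }
  g <- ng(6, base)
  expect_equal(shared_neighbor_proportion(g, 5, 6), 1.0)  # both only see 1
  # N(3) = {1,2}, N(5) = {1}: the smaller side is fully shared -> 1
  expect_equal(shared_neighbor_proportion(g, 3, 5), 1.0)
  # disjoint neighbourhoods -> 0  (N(1)\{3} = {4,5,6}, N(3)\{1} = {2})
  expect_equal(shared_neighbor_proportion(g, 1, 3), 0.0)
  expect_error(shared_neighbor_proportion(g, 2, 2), "distinct")
})

test_that("shared_neighbor_proportion equals the brute-force oracle", {
  set.seed(31)
  for (rep in 1:5) {
    g <- rand_gnp(8, 0.4)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(shared_neighbor_proportion(g, i, j),
                   oracle_shared_prop(g, i, j),
                   info = sprintf("rep %d pair (%d,%d)", rep, i, j))
      expect_equal(shared_neighbor_proportion(g, i, j),
                   shared_neighbor_proportion(g, j, i))
    }
  }
})

test_that("systematic_aggregation matches the plain-R scan oracle", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    g <- rand_gnp(n, runif(1, 0.3, 0.7))
    bins <- sample.int(3, n, replace = TRUE)
    p <- runif(1, 0.2, 0.9)
    got <- systematic_aggregation(g, bins, p)
    want <- oracle_aggregation(g, bins, p)
    expect_equal(got$n_aggregations, want$n_aggregations)
    expect_equal(edge_key(got$graph), edge_key(want$graph))
    expect_equal(n_nodes(got$graph), n - got$n_aggregations)
  }
})

test_that("aggregation respects bins, strict threshold and report fields", {
  # twin leaves attached to the same two hubs merge; p = 1 never merges
  g <- ng(4, rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  r <- systematic_aggregation(g, c(1, 1, 2, 2), 0.8)
  expect_equal(r$n_aggregations, 2L)
  expect_equal(unname(r$survivor_map), c(1L, 3L))
  expect_equal(r$merges$proportion, c(1, 1))
  expect_equal(systematic_aggregation(g, c(1, 1, 2, 2), 1)$n_aggregations, 0L)
  # merges are bin-local: split the twins across bins and nothing merges
  expect_equal(systematic_aggregation(g, c(1, 2, 3, 4), 0.5)$n_aggregations,
               0L)
  # audit frame is serializable
  df <- as.data.frame(r)
  expect_named(df, c("bin", "survivor", "merged", "proportion"))
})

test_that("merge count is non-increasing in the threshold p", {
  set.seed(12)
  g <- rand_gnp(40, 0.35)
  bins <- bin_values(sample_skew_normal(40, 4), 4)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(p) {
    systematic_aggregation(g, bins, p)$n_aggregations
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[9])  # strictly falls somewhere on the grid
})

test_that("random_aggregation merges exactly n and keeps the graph simple", {
  g <- generate_er(50, 200, seed = 8)
  expect_identical(edge_key(random_aggregation(g, 0, seed = 1)$graph),
                   edge_key(g))
  r <- random_aggregation(g, 20, seed = 2)
  expect_equal(n_nodes(r$graph), 30L)
  expect_equal(r$n_aggregations, 20L)
  expect_true(all(r$graph$edges[, 1] < r$graph$edges[, 2]))
  expect_false(anyDuplicated(edge_key(r$graph)) > 0)
  expect_false(any(r$merges$merged %in% r$graph$nodes))
  expect_error(random_aggregation(g, 50), "at most")
  # deterministic under seed
  expect_identical(edge_key(random_aggregation(g, 20, seed = 2)$graph),
                   edge_key(r$graph))
})

test_that("every surviving aggregated edge maps back to an original edge", {
  set.seed(55)
  g <- rand_gnp(15, 0.4)
  bins <- sample.int(3, 15, replace = TRUE)
  r <- systematic_aggregation(g, bins, 0.3)
  # resolve each endpoint through the survivor map back to merged sets
  # (transitively: a node merged into v may itself have absorbed others)
  group_of <- function(v) {
    grp <- v
    repeat {
      add <- r$merges$merged[r$merges$survivor %in% grp]
      add <- setdiff(add, grp)
      if (!length(add)) return(grp)
      grp <- c(grp, add)
    }
  }
  ok <- apply(r$graph$edges, 1, function(e) {
    any(outer(group_of(e[1]), group_of(e[2]), Vectorize(function(a, b) {
      any(g$edges[, 1] == min(a, b) & g$edges[, 2] == max(a, b))
    })))
  })
  expect_true(all(ok))
})
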