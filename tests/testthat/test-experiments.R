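# Orchestration: table shapes, determinism, seeding, sigmoid fit and
# beta calibration.  Experiment configurations here are desk-scale.

tiny_spec <- function() network_spec("er", 30L, er_edges = 90L)

test_that("derive_seed is deterministic, sensitive and in range", {
  expect_identical(derive_seed(42, "graph", 3), derive_seed(42, "graph", 3))
  expect_false(derive_seed(42, "graph", 3) == derive_seed(42, "graph", 4))
  expect_false(derive_seed(42, "graph", 3) == derive_seed(43, "graph", 3))
  expect_false(derive_seed(42, "run", 3) == derive_seed(42, "graph", 3))
  s <- vapply(1:200, function(i) derive_seed(7, "x", i), numeric(1))
  expect_true(all(s >= 1 & s <= 2^31 - 1))
  expect_false(anyDuplicated(s) > 0)
})

test_that("node_removal_experiment has the exact table shape", {
  cfg <- experiment_config(tiny_spec(), n_graphs = 2, n_inits = 3,
                           removal_schedule(5, 5),
                           sir_params(0.1, 0.3, 0.1, max_iters = 100),
                           base_seed = 11)
  tab <- node_removal_experiment(cfg)
  # 6 levels (intact + 5 batches) x 2 graphs x 3 inits x 5 metrics
  expect_equal(nrow(tab), 6 * 2 * 3 * 5)
  expect_equal(length(unique(tab$level)), 6L)
  expect_equal(min(tab$level), 5)    # level label = nodes remaining
  expect_equal(max(tab$level), 30)
  # bulk pre-removal adds one level
  cfg2 <- experiment_config(tiny_spec(), 1, 2, removal_schedule(5, 4, 10),
                            sir_params(0.1, 0.3, 0.1, 100), base_seed = 11)
  tab2 <- node_removal_experiment(cfg2)
  expect_equal(length(unique(tab2$level)), 6L)  # intact + bulk + 4 batches
  expect_true(20 %in% tab2$level)
  # bit-identical rerun
  expect_identical(tab, node_removal_experiment(cfg))
})

test_that("node_aggregation_experiment matches merge counts across levels", {
  cfg <- experiment_config(tiny_spec(), n_graphs = 3, n_inits = 2,
                           aggregation_config(4, 5L, 0.3),
                           threshold_params(0.5, 0.3, 30),
                           base_seed = 99)
  lv <- prepare_aggregation_levels(cfg)
  tab <- node_aggregation_experiment(cfg, levels = lv)
  expect_equal(nrow(tab), 3 * 3 * 2 * 5)
  expect_setequal(unique(tab$level), c("none", "shared_neighbor", "random"))
  agg <- attr(tab, "aggregation")
  expect_equal(nrow(agg), 3L)
  for (gi in 1:3) {
    # the random level always performs exactly the systematic merge count
    expect_equal(n_nodes(lv[[gi]]$none) - n_nodes(lv[[gi]]$random),
                 lv[[gi]]$n_aggregations)
    expect_equal(n_nodes(lv[[gi]]$none) - n_nodes(lv[[gi]]$shared_neighbor),
                 lv[[gi]]$n_aggregations)
  }
  # reproducible without the precomputed levels
  expect_identical(tab, node_aggregation_experiment(cfg))
})

test_that("zero merges collapse the three levels onto one graph", {
  cfg <- experiment_config(tiny_spec(), 1, 1,
                           aggregation_config(4, 30L, 1),  # p = 1: no merges
                           threshold_params(0.5, 0.3), base_seed = 5)
  lv <- prepare_aggregation_levels(cfg)[[1]]
  expect_equal(lv$n_aggregations, 0L)
  expect_identical(edge_key(lv$none), edge_key(lv$shared_neighbor))
  expect_identical(edge_key(lv$none), edge_key(lv$random))
})

test_that("real_world removal runs trials on a fixed loaded graph", {
  g <- generate_er(100, 400, seed = 31)
  cfg <- experiment_config(tiny_spec(), n_graphs = 2, n_inits = 1,
                           removal_schedule(NA, 3),
                           sir_params(0, 0.5, 0.1, 50), base_seed = 3)
  tab <- real_world_removal_experiment(cfg, g)
  expect_equal(length(unique(tab$level)), 4L)          # intact + 3 batches
  expect_equal(min(tab$level), ceiling(0.05 * 100))    # removal to 5%
  # beta = 0: attack rate stays at the seeded fraction at every level
  tot <- tab[tab$metric == "total_infected_frac", ]
  expect_true(all(abs(tot$value - round(0.1 * tot$level) / tot$level) < 1e-12))
})

test_that("fit_sigmoid recovers exact parameters and flags flat data", {
  x <- seq(125, 2500, length.out = 50)
  y <- 1 / (1 + exp(-(-0.01) * (x - 1000)))
  f <- fit_sigmoid(x, y)
  expect_equal(f$k, -0.01, tolerance = 1e-4)
  expect_equal(f$x0, 1000, tolerance = 1e-4)
  expect_lt(f$residual_sse, 1e-10)
  expect_false(f$degenerate)

  flat <- fit_sigmoid(x, rep(0.5, 50))
  expect_true(flat$degenerate)
  expect_lt(abs(flat$k), 1e-6)

  # noisy transition: midpoint recovered within the transition zone
  set.seed(17)
  yn <- pmin(pmax(1 / (1 + exp(-0.02 * (x - 900))) +
                    rnorm(50, 0, 0.05), 0), 1)
  fn <- fit_sigmoid(x, yn)
  expect_gt(fn$x0, 700)
  expect_lt(fn$x0, 1100)
})

test_that("calibrate_beta walks the grid and fails on capped spread", {
  k50 <- netgraph(1:50, t(combn(50, 2)))
  b <- calibrate_beta(k50, gamma = 0.01, init_frac = 0.1, grid_step = 0.005,
                      target_frac = 0.95, n_inits = 3, seed = 2)
  expect_equal(b, 0.005)   # near-certain full spread at the first grid value
  expect_equal(b / 0.005, round(b / 0.005))

  # 10% isolated nodes cap the attack rate at 0.9 < 0.95
  iso <- netgraph(1:50, t(combn(45, 2)))
  expect_error(
    calibrate_beta(iso, 0.01, 0.1, grid_step = 0.25, target_frac = 0.95,
                   n_inits = 2, max_iters = 500, seed = 3),
    class = "netdegrade_calibration_failure")
})

test_that("removal deepening lowers SIR spread (sign test, scaled design)", {
  # scaled-down version of the batched removal design: 12 base seeds,
  # compare the intact-level mean with the final-level mean per replicate
  diffs <- vapply(1:12, function(s) {
    cfg <- experiment_config(network_spec("er", 50L, er_edges = 200L),
                             1, 4, removal_schedule(5, 4),
                             sir_params(0.05, 0.1, 0.1, 500),
                             base_seed = 1000 + s)
    tab <- node_removal_experiment(cfg)
    tot <- tab[tab$metric == "total_infected_frac", ]
    mean(tot$value[tot$level == 50]) - mean(tot$value[tot$level == 5])
  }, numeric(1))
  expect_gt(sum(diffs > 0), 9)   # binom(12, 0.5) tail: p < 0.02 for >= 10
})
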