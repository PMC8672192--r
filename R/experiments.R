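# Experiment orchestration: replicated removal and aggregation designs,
# sigmoid transition fitting, and infection-probability calibration.

#' Deterministic seed derivation
#'
#' Derives a substream seed from a base seed and an arbitrary list of string
#' or integer qualifiers (stage name, graph index, batch index, ...), via a
#' multiplicative congruential mix modulo `2^31 - 1`.  Every random stage of
#' an experiment takes its own derived seed, so any single table row can be
#' re-run in isolation.
#'
#' @param base integer base seed.
#' @param ... character or numeric qualifiers.
#' @return an integer in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483647
  h <- as.numeric(base) %% m
  for (p in list(...)) {
    v <- if (is.character(p)) {
      cc <- utf8ToInt(p)
      sum(cc * seq_along(cc)) %% m
    } else {
      as.numeric(p) %% m
    }
    h <- (h * 69069 + v + 1) %% m
  }
  as.integer(h) + 1L
}

#' Network specification
#'
#' Topology plus the generator parameters needed for it.  The default sizes
#' are the study design: 2,500 nodes with a normalized average degree of
#' about 0.1 for every topology (ER 312,500 edges; WS k = 250, rewiring 0.1;
#' BA m = 132).
#'
#' @param topology one of `"er"`, `"ws"`, `"ba"`.
#' @param n_nodes node count.
#' @param er_edges edge count (ER only).
#' @param ws_k even neighbour count (WS only).
#' @param ws_rewire_prob rewiring probability (WS only).
#' @param ba_m attachment count (BA only).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(topology = c("er", "ws", "ba"), n_nodes = 2500L,
                         er_edges = 312500L, ws_k = 250L,
                         ws_rewire_prob = 0.1, ba_m = 132L) {
  topology <- match.arg(topology)
  structure(list(topology = topology, n_nodes = as.integer(n_nodes),
                 er_edges = as.integer(er_edges), ws_k = as.integer(ws_k),
                 ws_rewire_prob = ws_rewire_prob, ba_m = as.integer(ba_m)),
            class = "network_spec")
}

#' Generate a graph from a specification
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed.
#' @return a `netgraph`.
#' @export
generate_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  switch(spec$topology,
    er = generate_er(spec$n_nodes, spec$er_edges, seed),
    ws = generate_ws(spec$n_nodes, spec$ws_k, spec$ws_rewire_prob, seed),
    ba = generate_ba(spec$n_nodes, spec$ba_m, seed))
}

#' Experiment configuration
#'
#' @param network_spec a [network_spec()].
#' @param n_graphs independently generated graphs (or removal trials on a
#'   loaded graph); the study design uses 20 for synthetic networks and 10
#'   trials for real-world ones.
#' @param n_inits random diffusion initializations per graph and level
#'   (design: 10).
#' @param handling a [removal_schedule()] or [aggregation_config()].
#' @param diffusion a [sir_params()] or [threshold_params()].
#' @param base_seed integer base seed; all stage seeds derive from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(network_spec, n_graphs, n_inits, handling,
                              diffusion, base_seed) {
  stopifnot(inherits(network_spec, "network_spec"),
            n_graphs >= 1, n_inits >= 1,
            inherits(handling, c("removal_schedule", "aggregation_config")),
            inherits(diffusion, c("sir_params", "threshold_params")))
  structure(list(network_spec = network_spec,
                 n_graphs = as.integer(n_graphs),
                 n_inits = as.integer(n_inits),
                 handling = handling, diffusion = diffusion,
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

run_model <- function(g, diffusion, seed) {
  if (inherits(diffusion, "sir_params")) run_sir(g, diffusion, seed)
  else run_threshold(g, diffusion, seed)
}

# Rows for one (graph, level): n_inits runs x 5 metrics, tidy.
level_rows <- function(g, diffusion, n_inits, base_seed, gi, level_id,
                       level_label) {
  out <- vector("list", n_inits)
  for (init in seq_len(n_inits)) {
    res <- run_model(g, diffusion,
                     derive_seed(base_seed, "run", gi, level_id, init))
    v <- summarize_all(res)
    out[[init]] <- data.frame(graph = gi, level = level_label,
                              replicate = init, metric = names(v),
                              value = unname(v))
  }
  do.call(rbind, out)
}

#' Batched node-removal experiment
#'
#' For each of `n_graphs` generated graphs: run the diffusion model with
#' `n_inits` initializations on the intact graph, then repeatedly remove a
#' batch of random nodes (cumulatively, on the same graph instance) and
#' re-run, recording all five summary metrics each time.  If the schedule
#' has a bulk pre-removal, one additional level is recorded right after it.
#'
#' @param config an [experiment_config()] whose `handling` is a
#'   [removal_schedule()].
#' @return a tidy data frame with columns `graph`, `level` (nodes
#'   remaining), `replicate`, `metric`, `value`.
#' @export
node_removal_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(config$handling, "removal_schedule"))
  sched <- config$handling
  base <- config$base_seed
  rows <- list()
  for (gi in seq_len(config$n_graphs)) {
    g <- generate_graph(config$network_spec, derive_seed(base, "graph", gi))
    counts <- batch_schedule(n_nodes(g), sched)
    cur <- g
    lvl <- 0L
    tab <- list(level_rows(cur, config$diffusion, config$n_inits, base, gi,
                           lvl, n_nodes(cur)))
    if (sched$initial_bulk_removal > 0L) {
      cur <- remove_nodes_random(cur, sched$initial_bulk_removal,
                                 derive_seed(base, "bulk", gi))
      lvl <- lvl + 1L
      tab[[length(tab) + 1L]] <- level_rows(cur, config$diffusion,
                                            config$n_inits, base, gi, lvl,
                                            n_nodes(cur))
    }
    for (bi in seq_along(counts)) {
      cur <- remove_nodes_random(cur, counts[bi],
                                 derive_seed(base, "remove", gi, bi))
      lvl <- lvl + 1L
      tab[[length(tab) + 1L]] <- level_rows(cur, config$diffusion,
                                            config$n_inits, base, gi, lvl,
                                            n_nodes(cur))
    }
    rows[[gi]] <- do.call(rbind, tab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prepare aggregation handling levels for one graph
#'
#' Samples skew-normal attributes, bins them, applies the systematic
#' shared-neighbour aggregation, and performs the matched number of random
#' merges on an independent copy.
#'
#' @param g a `netgraph`.
#' @param agg_config an [aggregation_config()].
#' @param seed seed from which the attribute and random-merge substreams are
#'   derived.
#' @return a list with elements `none`, `shared_neighbor`, `random` (the
#'   three graphs), `n_aggregations`, and the systematic `report`.
#' @export
aggregation_levels <- function(g, agg_config, seed) {
  stopifnot(inherits(agg_config, "aggregation_config"))
  vals <- sample_skew_normal(n_nodes(g), agg_config$alpha,
                             seed = derive_seed(seed, "attributes"))
  bins <- bin_values(vals, agg_config$n_bins)
  rep_sys <- systematic_aggregation(g, bins, agg_config$shared_threshold)
  rep_rnd <- random_aggregation(g, rep_sys$n_aggregations,
                                seed = derive_seed(seed, "random_merge"))
  list(none = g, shared_neighbor = rep_sys$graph, random = rep_rnd$graph,
       n_aggregations = rep_sys$n_aggregations, report = rep_sys)
}

#' Prepare all aggregation levels of an experiment
#'
#' Generates the `n_graphs` graphs of `config` and builds the three handling
#' levels for each.  The result can be passed to
#' [node_aggregation_experiment()] (for instance to share one expensive set
#' of aggregated graphs between an SIR and a Threshold run on identical
#' networks).
#'
#' @param config an [experiment_config()] whose `handling` is an
#'   [aggregation_config()].
#' @return a list of [aggregation_levels()] results, one per graph.
#' @export
prepare_aggregation_levels <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(config$handling, "aggregation_config"))
  base <- config$base_seed
  lapply(seq_len(config$n_graphs), function(gi) {
    g <- generate_graph(config$network_spec, derive_seed(base, "graph", gi))
    aggregation_levels(g, config$handling, derive_seed(base, "aggregate", gi))
  })
}

#' Node-aggregation experiment
#'
#' For each graph: run the diffusion model on the intact graph, on the
#' systematically aggregated copy, and on an independent copy degraded by
#' the same number of random merges -- three labelled handling levels.
#'
#' @inheritParams prepare_aggregation_levels
#' @param levels optional precomputed [prepare_aggregation_levels()] output;
#'   must match `config$n_graphs`.
#' @return a tidy data frame (`graph`, `level`, `replicate`, `metric`,
#'   `value`) with an `"aggregation"` attribute holding per-graph merge
#'   counts and normalized average degrees.
#' @export
node_aggregation_experiment <- function(config, levels = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(config$handling, "aggregation_config"))
  if (is.null(levels)) levels <- prepare_aggregation_levels(config)
  stopifnot(length(levels) == config$n_graphs)
  base <- config$base_seed
  level_names <- c("none", "shared_neighbor", "random")
  rows <- list()
  agg_info <- list()
  for (gi in seq_len(config$n_graphs)) {
    lv <- levels[[gi]]
    for (li in seq_along(level_names)) {
      nm <- level_names[li]
      rows[[length(rows) + 1L]] <- level_rows(lv[[nm]], config$diffusion,
                                              config$n_inits, base, gi, li,
                                              nm)
    }
    agg_info[[gi]] <- data.frame(
      graph = gi, n_aggregations = lv$n_aggregations,
      degree_none = normalized_average_degree(lv$none),
      degree_shared_neighbor = normalized_average_degree(lv$shared_neighbor),
      degree_random = normalized_average_degree(lv$random))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aggregation") <- do.call(rbind, agg_info)
  out
}

#' Node-removal experiment on a loaded real-world graph
#'
#' Like [node_removal_experiment()], but each of `config$n_graphs` trials
#' starts from a fresh copy of the supplied graph instead of a newly
#' generated one.  If the schedule's `final_node_count` is `NA`, it is set
#' to `ceiling(0.05 * N)` (removal until 5% of nodes remain).
#'
#' @param config an [experiment_config()] whose `handling` is a
#'   [removal_schedule()]; its `network_spec` is ignored.
#' @param graph the loaded `netgraph`.
#' @return a tidy data frame as in [node_removal_experiment()].
#' @export
real_world_removal_experiment <- function(config, graph) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(config$handling, "removal_schedule"))
  sched <- config$handling
  if (is.na(sched$final_node_count)) {
    sched$final_node_count <- as.integer(ceiling(0.05 * n_nodes(graph)))
  }
  base <- config$base_seed
  rows <- list()
  for (gi in seq_len(config$n_graphs)) {
    counts <- batch_schedule(n_nodes(graph), sched)
    cur <- graph
    lvl <- 0L
    tab <- list(level_rows(cur, config$diffusion, config$n_inits, base, gi,
                           lvl, n_nodes(cur)))
    if (sched$initial_bulk_removal > 0L) {
      cur <- remove_nodes_random(cur, sched$initial_bulk_removal,
                                 derive_seed(base, "bulk", gi))
      lvl <- lvl + 1L
      tab[[length(tab) + 1L]] <- level_rows(cur, config$diffusion,
                                            config$n_inits, base, gi, lvl,
                                            n_nodes(cur))
    }
    for (bi in seq_along(counts)) {
      cur <- remove_nodes_random(cur, counts[bi],
                                 derive_seed(base, "remove", gi, bi))
      lvl <- lvl + 1L
      tab[[length(tab) + 1L]] <- level_rows(cur, config$diffusion,
                                            config$n_inits, base, gi, lvl,
                                            n_nodes(cur))
    }
    rows[[gi]] <- do.call(rbind, tab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the transition-zone sigmoid
#'
#' Least-squares fit of `f(x) = 1 / (1 + exp(-k (x - x0)))` to mean metric
#' values across handling levels, characterizing the zone where model output
#' switches between no-spread and full-spread regimes.  Nonlinear least
#' squares is tried first (with a scale offset so exact, zero-residual data
#' do not abort); Nelder-Mead minimization of the SSE is the fallback.
#'
#' @param x handling levels (e.g. nodes remaining).
#' @param y mean metric values in `[0, 1]`, same length as `x` (>= 3).
#' @param initial_guess optional `c(k, x0)` start.
#' @return an object of class `sigmoid_fit` with fields `k`, `x0`,
#'   `residual_sse`, `converged` and `degenerate`.
#' @export
fit_sigmoid <- function(x, y, initial_guess = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.null(initial_guess)) {
    x0 <- mean(range(x))
    tr <- sum((x - mean(x)) * (y - mean(y)))
    sgn <- if (tr >= 0) 1 else -1
    k0 <- sgn * 4 / max(diff(range(x)), .Machine$double.eps)
    initial_guess <- c(k = k0, x0 = x0)
  }
  sse <- function(par) {
    f <- 1 / (1 + exp(-par[1] * (x - par[2])))
    sum((y - f)^2)
  }
  fit <- tryCatch(
    nls(y ~ 1 / (1 + exp(-k * (x - x0))),
        start = list(k = initial_guess[[1]], x0 = initial_guess[[2]]),
        control = nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    par <- coef(fit)
    converged <- TRUE
  } else {
    op <- optim(c(initial_guess[[1]], initial_guess[[2]]), sse,
                method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-12))
    par <- c(k = op$par[1], x0 = op$par[2])
    converged <- op$convergence == 0
  }
  structure(list(k = unname(par[1]), x0 = unname(par[2]),
                 residual_sse = sse(unname(par)), converged = converged,
                 degenerate = abs(par[1]) < 1e-8 || sd(y) < 1e-10),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> k = %.6g, x0 = %.6g, SSE = %.3g%s%s\n",
              x$k, x$x0, x$residual_sse,
              if (x$converged) "" else " (not converged)",
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Calibrate the infection probability for near-full spread
#'
#' Walks the grid `grid_step, 2*grid_step, ...` and returns the smallest
#' infection probability whose mean attack rate over `n_inits` SIR runs
#' reaches `target_frac`.  Used on real-world networks, which are typically
#' disconnected, to place the model in its critical region (e.g. at least
#' 95% of the population infected on average, on a 0.005 grid).
#'
#' @param graph a `netgraph`.
#' @param gamma recovery probability.
#' @param init_frac initial infected fraction.
#' @param grid_step grid increment (default 0.005).
#' @param target_frac required mean attack rate in `(0, 1]` (default 0.95).
#' @param n_inits runs averaged per grid value (default 10).
#' @param max_iters SIR iteration cap.
#' @param seed optional RNG seed.
#' @return the calibrated probability, an exact multiple of `grid_step`.
#'   Throws a condition of class `netdegrade_calibration_failure` if no grid
#'   value at most 1 reaches the target.
#' @export
calibrate_beta <- function(graph, gamma, init_frac, grid_step = 0.005,
                           target_frac = 0.95, n_inits = 10L,
                           max_iters = 2500L, seed = NULL) {
  stopifnot(grid_step > 0, target_frac > 0, target_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- 0L
  repeat {
    s <- s + 1L
    beta <- s * grid_step
    if (beta > 1 + 1e-12) {
      stop(errorCondition(
        sprintf("no infection probability on the %g grid reaches %g",
                grid_step, target_frac),
        class = c("netdegrade_calibration_failure",
                  "netdegrade_runtime_error")))
    }
    p <- sir_params(min(beta, 1), gamma, init_frac, max_iters)
    means <- vapply(seq_len(n_inits), function(i) {
      summarize_diffusion(run_sir(graph, p), "total_infected_frac")
    }, numeric(1))
    if (mean(means) >= target_frac) return(beta)
  }
}
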