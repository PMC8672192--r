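# Degradation models: batched random removal and entity-resolution-style
# node aggregation.

#' Removal schedule
#'
#' Parameters of a batched random node-removal experiment: nodes are removed
#' in `n_batches` near-equal batches until `final_node_count` remain,
#' optionally after a single bulk pre-removal (used by the SIR removal
#' design, where full spread is certain on large graphs).
#'
#' @param final_node_count nodes remaining after the last batch (default 125,
#'   i.e. 5% of a 2,500-node graph).  `NA` is allowed and means "5% of the
#'   loaded graph", resolved by [real_world_removal_experiment()].
#' @param n_batches number of removal batches (35 for the SIR design, 50 for
#'   the Threshold design).
#' @param initial_bulk_removal nodes removed in one step before batching
#'   starts (1,250 in the SIR removal design, else 0).
#' @return an object of class `removal_schedule`.
#' @export
removal_schedule <- function(final_node_count = 125L, n_batches,
                             initial_bulk_removal = 0L) {
  final_node_count <- as.integer(final_node_count)
  n_batches <- as.integer(n_batches)
  initial_bulk_removal <- as.integer(initial_bulk_removal)
  stopifnot(is.na(final_node_count) || final_node_count >= 1L,
            n_batches >= 1L, initial_bulk_removal >= 0L)
  structure(list(final_node_count = final_node_count,
                 n_batches = n_batches,
                 initial_bulk_removal = initial_bulk_removal),
            class = "removal_schedule")
}

#' Aggregation configuration
#'
#' Parameters of the shared-neighbour aggregation model: each node receives a
#' skew-normal attribute, attributes are cut into `n_bins` equal-width bins,
#' and node pairs within a bin are merged when their shared-neighbour
#' proportion strictly exceeds `shared_threshold`.
#'
#' @param alpha skewness of the attribute distribution (default 4).
#' @param n_bins number of equal-width bins (default 50).
#' @param shared_threshold merge threshold `p` in `[0, 1]` (0.8 for the
#'   Watts-Strogatz design, 0.57 for Barabasi-Albert).
#' @param seed optional RNG seed used when the configuration is applied
#'   outside an experiment.
#' @return an object of class `aggregation_config`.
#' @export
aggregation_config <- function(alpha = 4, n_bins = 50L, shared_threshold,
                               seed = NULL) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, shared_threshold >= 0, shared_threshold <= 1)
  structure(list(alpha = alpha, n_bins = n_bins,
                 shared_threshold = shared_threshold, seed = seed),
            class = "aggregation_config")
}

#' Per-batch removal counts
#'
#' Splits the total removal (start minus bulk minus final) into
#' `schedule$n_batches` positive integers, as equal as possible with the
#' remainder spread over the earliest batches.
#'
#' @param start_n node count before any removal.
#' @param schedule a [removal_schedule()].
#' @return integer vector of per-batch counts.
#' @examples
#' batch_schedule(10, removal_schedule(5, 5))  # 1 1 1 1 1
#' @export
batch_schedule <- function(start_n, schedule) {
  stopifnot(inherits(schedule, "removal_schedule"))
  total <- start_n - schedule$initial_bulk_removal - schedule$final_node_count
  nb <- schedule$n_batches
  if (total < nb) {
    stop(sprintf(
      "infeasible schedule: %d nodes to remove across %d batches", total, nb),
      call. = FALSE)
  }
  base <- total %/% nb
  rem <- total %% nb
  as.integer(base + (seq_len(nb) <= rem))
}

#' Random node removal
#'
#' Deletes a uniformly chosen subset of `count` nodes together with all their
#' incident edges.  Survivors keep their labels.
#'
#' @param g a `netgraph`.
#' @param count number of nodes to delete.
#' @param seed optional RNG seed.
#' @return the degraded `netgraph`.
#' @export
remove_nodes_random <- function(g, count, seed = NULL) {
  count <- as.integer(count)
  N <- n_nodes(g)
  if (count > N) stop("cannot remove more nodes than exist", call. = FALSE)
  if (count == 0L) return(g)
  if (!is.null(seed)) set.seed(seed)
  drop <- g$nodes[sample.int(N, count)]
  keep_nodes <- setdiff(g$nodes, drop)
  if (n_edges(g) > 0L) {
    ok <- !(g$edges[, 1L] %in% drop) & !(g$edges[, 2L] %in% drop)
    edges <- g$edges[ok, , drop = FALSE]
  } else {
    edges <- NULL
  }
  netgraph(keep_nodes, edges, id_map = g$id_map)
}

#' Random edge removal
#'
#' Deletes a uniformly chosen subset of `count` edges; all nodes are
#' retained, possibly isolated.
#'
#' @inheritParams remove_nodes_random
#' @param count number of edges to delete.
#' @return the degraded `netgraph`.
#' @export
remove_edges_random <- function(g, count, seed = NULL) {
  count <- as.integer(count)
  L <- n_edges(g)
  if (count > L) stop("cannot remove more edges than exist", call. = FALSE)
  if (count == 0L) return(g)
  if (!is.null(seed)) set.seed(seed)
  keep <- setdiff(seq_len(L), sample.int(L, count))
  netgraph(g$nodes, g$edges[keep, , drop = FALSE], id_map = g$id_map)
}

#' Skew-normal attribute sampler
#'
#' Draws `n` i.i.d. values from the standard skew-normal law with shape
#' `alpha`, using the convolution representation
#' `delta * |U0| + sqrt(1 - delta^2) * U1` with `delta = alpha/sqrt(1+alpha^2)`
#' and `U0, U1` independent standard normals.  `alpha = 0` reduces to the
#' standard normal; the mean is `sqrt(2/pi) * delta`.
#'
#' @param n sample size.
#' @param alpha skewness parameter.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
sample_skew_normal <- function(n, alpha, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  delta <- alpha / sqrt(1 + alpha^2)
  delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
}

#' Equal-width binning
#'
#' Cuts `values` into `K` equal-width intervals spanning the observed range.
#' Internal boundary values fall in the higher bin; the maximum falls in bin
#' `K` (rightmost interval closed).  A constant vector maps entirely to
#' bin 1.
#'
#' @param values nonempty numeric vector.
#' @param K number of bins.
#' @return integer vector of 1-based bin indices aligned with `values`.
#' @export
bin_values <- function(values, K) {
  K <- as.integer(K)
  stopifnot(K >= 1L, length(values) >= 1L)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  w <- (hi - lo) / K
  idx <- floor((values - lo) / w) + 1
  as.integer(pmin(idx, K))
}

#' Shared-neighbour proportion
#'
#' With `A = N(i) \ {j}`, `B = N(j) \ {i}` and `S` their intersection,
#' returns `max(|S|/|A|, |S|/|B|)`; a ratio with zero denominator counts
#' as 0.  Any direct edge between `i` and `j` is ignored.  Symmetric in its
#' node arguments.
#'
#' @param g a `netgraph`.
#' @param i,j distinct node labels of `g`.
#' @return a fraction in `[0, 1]`.
#' @export
shared_neighbor_proportion <- function(g, i, j) {
  if (i == j) stop("i and j must be distinct nodes", call. = FALSE)
  pi_ <- match(i, g$nodes); pj <- match(j, g$nodes)
  if (is.na(pi_) || is.na(pj)) stop("node not in graph", call. = FALSE)
  adj <- adjacency_list(g)
  A <- setdiff(adj[[pi_]], j)
  B <- setdiff(adj[[pj]], i)
  S <- intersect(A, B)
  r1 <- if (length(A) > 0L) length(S) / length(A) else 0
  r2 <- if (length(B) > 0L) length(S) / length(B) else 0
  max(r1, r2)
}

new_aggregation_report <- function(n_aggregations, merges, graph) {
  survivor_map <- merges$survivor
  names(survivor_map) <- merges$merged
  structure(list(n_aggregations = n_aggregations, merges = merges,
                 survivor_map = survivor_map, graph = graph),
            class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf("<aggregation_report> %d merges; degraded graph: %d nodes, %d edges\n",
              x$n_aggregations, n_nodes(x$graph), n_edges(x$graph)))
  invisible(x)
}

#' Audit table of an aggregation
#'
#' One row per merge: bin index (NA for random merges), surviving node,
#' merged node, and the shared-neighbour proportion that triggered the merge
#' (NA for random merges).  Suitable for `write.csv()`.
#'
#' @param x an `aggregation_report`.
#' @param ... unused.
#' @export
as.data.frame.aggregation_report <- function(x, ...) x$merges

#' Systematic shared-neighbour aggregation
#'
#' Scans bins in ascending index and, within each bin, ordered node pairs
#' `(i, j)` with `i < j` in ascending label order, skipping deleted nodes.
#' Whenever the shared-neighbour proportion on the current (live) graph
#' strictly exceeds `p`, node `j`'s edges are reattached to `i` (self-loops
#' and duplicates dropped), `j` is deleted, and the scan continues
#' immediately -- the sequential semantics without transitive-closure
#' reconciliation.
#'
#' @param g a `netgraph`.
#' @param bins integer bin index per node, aligned with `g$nodes`.
#' @param p strict merge threshold in `[0, 1]`.
#' @return an `aggregation_report` with fields `n_aggregations`, `merges`,
#'   `survivor_map` and the degraded `graph`.
#' @export
systematic_aggregation <- function(g, bins, p) {
  N <- n_nodes(g)
  if (length(bins) != N) {
    stop("bins must assign every node of g", call. = FALSE)
  }
  res <- cpp_systematic_aggregation(N, edge_index(g), as.integer(bins), p)
  alive <- as.logical(res$alive)
  graph <- netgraph(g$nodes[alive],
                    if (nrow(res$edges) > 0L)
                      cbind(g$nodes[res$edges[, 1L]], g$nodes[res$edges[, 2L]])
                    else NULL,
                    id_map = g$id_map)
  merges <- data.frame(bin = as.integer(res$bin),
                       survivor = g$nodes[res$survivor],
                       merged = g$nodes[res$merged],
                       proportion = res$proportion)
  new_aggregation_report(nrow(merges), merges, graph)
}

#' Random aggregation baseline
#'
#' Performs `n_merges` successive merges, each of a uniformly chosen ordered
#' pair of distinct surviving nodes (the second merged into the first, with
#' the same edge-reattachment rule as [systematic_aggregation()]).  Matched
#' to the systematic merge count, this is the baseline that separates the
#' effect of aggregating at all from the effect of aggregating by
#' neighbourhood similarity.
#'
#' @param g a `netgraph`.
#' @param n_merges number of merges, at most `N - 1`.
#' @param seed optional RNG seed.
#' @return an `aggregation_report`.
#' @export
random_aggregation <- function(g, n_merges, seed = NULL) {
  n_merges <- as.integer(n_merges)
  N <- n_nodes(g)
  if (n_merges >= N && n_merges > 0L) {
    stop("n_merges must be at most N - 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_random_aggregation(N, edge_index(g), n_merges)
  alive <- as.logical(res$alive)
  graph <- netgraph(g$nodes[alive],
                    if (nrow(res$edges) > 0L)
                      cbind(g$nodes[res$edges[, 1L]], g$nodes[res$edges[, 2L]])
                    else NULL,
                    id_map = g$id_map)
  merges <- data.frame(bin = rep(NA_integer_, n_merges),
                       survivor = g$nodes[res$survivor],
                       merged = g$nodes[res$merged],
                       proportion = rep(NA_real_, n_merges))
  new_aggregation_report(n_merges, merges, graph)
}
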