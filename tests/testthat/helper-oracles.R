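# Fixture builders and independent brute-force oracles.  Everything here is
# written from the definitions in plain R, independent of the package's
# implementation paths (the C++ kernels in particular).

# tiny graph constructor from an edge matrix
ng <- function(n, edges) netgraph(seq_len(n), edges)

graph_k4 <- function() ng(4, t(combn(4, 2)))
graph_path3 <- function() ng(3, rbind(c(1, 2), c(2, 3)))  # 2 is the centre
graph_cycle <- function(n) ng(n, cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
graph_star <- function(k) ng(k + 1L, cbind(1L, 1L + seq_len(k)))  # 1 = hub

# independent G(n, p) sampler for property tests (base R, not the package)
rand_gnp <- function(n, p) {
  pairs <- t(combn(n, 2))
  ng(n, pairs[runif(nrow(pairs)) < p, , drop = FALSE])
}

# adjacency as a list of integer vectors, built directly from the edge matrix
oracle_adj <- function(g) {
  adj <- rep(list(integer(0)), n_nodes(g))
  e <- g$edges
  for (r in seq_len(nrow(e))) {
    a <- match(e[r, 1], g$nodes); b <- match(e[r, 2], g$nodes)
    adj[[a]] <- c(adj[[a]], g$nodes[b])
    adj[[b]] <- c(adj[[b]], g$nodes[a])
  }
  names(adj) <- g$nodes
  adj
}

# shared-neighbour proportion from first principles (set arithmetic)
oracle_shared_prop <- function(g, i, j) {
  adj <- oracle_adj(g)
  A <- setdiff(adj[[as.character(i)]], j)
  B <- setdiff(adj[[as.character(j)]], i)
  S <- intersect(A, B)
  mx <- 0
  if (length(A)) mx <- max(mx, length(S) / length(A))
  if (length(B)) mx <- max(mx, length(S) / length(B))
  mx
}

# full sequential aggregation scan, plain R, from the stated semantics
oracle_aggregation <- function(g, bins, p) {
  adj <- lapply(oracle_adj(g), unique)
  labels <- g$nodes
  alive <- rep(TRUE, length(labels))
  names(alive) <- labels
  merges <- 0L
  prop_of <- function(i, j) {
    A <- setdiff(adj[[as.character(i)]], j)
    B <- setdiff(adj[[as.character(j)]], i)
    S <- intersect(A, B)
    mx <- 0
    if (length(A)) mx <- max(mx, length(S) / length(A))
    if (length(B)) mx <- max(mx, length(S) / length(B))
    mx
  }
  for (k in sort(unique(bins))) {
    mem <- labels[bins == k]
    for (a in seq_along(mem)) {
      i <- mem[a]
      if (!alive[as.character(i)]) next
      if (a >= length(mem)) next
      for (b in (a + 1L):length(mem)) {
        j <- mem[b]
        if (!alive[as.character(j)]) next
        if (prop_of(i, j) > p) {
          for (nb in adj[[as.character(j)]]) {
            adj[[as.character(nb)]] <- setdiff(adj[[as.character(nb)]], j)
            if (nb != i) {
              adj[[as.character(i)]] <- union(adj[[as.character(i)]], nb)
              adj[[as.character(nb)]] <- union(adj[[as.character(nb)]], i)
            }
          }
          adj[[as.character(j)]] <- integer(0)
          alive[as.character(j)] <- FALSE
          merges <- merges + 1L
        }
      }
    }
  }
  edges <- do.call(rbind, lapply(labels[alive], function(v) {
    nbs <- adj[[as.character(v)]]
    nbs <- nbs[nbs > v]
    if (length(nbs)) cbind(v, nbs) else NULL
  }))
  list(n_aggregations = merges,
       graph = netgraph(labels[alive], edges))
}

# synchronous threshold cascade to its fixed point, plain R
oracle_threshold <- function(g, init_labels, thresh, max_iters = 1000L) {
  adj <- oracle_adj(g)
  infected <- g$nodes %in% init_labels
  names(infected) <- g$nodes
  for (it in seq_len(max_iters)) {
    frac <- vapply(seq_along(adj), function(a) {
      nbs <- adj[[a]]
      if (length(nbs) == 0L) return(0)
      sum(infected[as.character(nbs)]) / length(nbs)
    }, numeric(1))
    newly <- !infected & frac > thresh
    if (!any(newly)) break
    infected[newly] <- TRUE
  }
  g$nodes[infected]
}

# canonical sorted edge-key string, for graph equality checks
edge_key <- function(g) {
  if (n_edges(g) == 0L) return(character(0))
  sort(paste(g$edges[, 1], g$edges[, 2]))
}

# threshold run with an explicit seed set, states recorded
run_threshold_with_seeds <- function(g, seeds, thresh) {
  run_threshold(g, threshold_params(thresh, 0, max_iters = n_nodes(g) + 1L),
                record_states = TRUE, initial_infected = seeds)
}
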