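# Simple undirected graph container and the synthetic generators.
#
# A `netgraph` stores an explicit vector of integer node labels plus a
# canonical edge matrix (two columns, first endpoint < second, unique rows).
# Labels stay stable under degradation: removing or merging nodes never
# relabels the survivors, so results at different degradation levels are
# directly comparable.

canonical_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 2L))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (anyNA(edges)) stop("edge endpoints must be integers", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed in a netgraph", call. = FALSE)
  }
  m <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  m <- unique(m)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Construct a simple undirected graph
#'
#' @param nodes integer vector of node labels (duplicates are collapsed).
#' @param edges two-column matrix of node labels; order and duplicates are
#'   irrelevant (edge-set semantics).  Self-loops are an error.
#' @param id_map optional vector mapping internal labels to original
#'   identifiers (as produced by [load_edge_list()]), indexed by label.
#' @return an object of class `netgraph` with fields `nodes`, `edges` and
#'   (optionally) `id_map`.
#' @examples
#' g <- netgraph(1:3, rbind(c(1, 2), c(2, 3)))
#' n_nodes(g); n_edges(g)
#' @export
netgraph <- function(nodes, edges = NULL, id_map = NULL) {
  nodes <- sort(unique(as.integer(nodes)))
  if (anyNA(nodes)) stop("node labels must be integers", call. = FALSE)
  edges <- canonical_edges(edges)
  if (NROW(edges) > 0L && !all(edges %in% nodes)) {
    stop("every edge endpoint must be a listed node", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, id_map = id_map),
            class = "netgraph")
}

#' @rdname netgraph
#' @param g a `netgraph`.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname netgraph
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("<netgraph> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

# Edge matrix re-expressed in contiguous 1..N indices for the C++ kernels.
edge_index <- function(g) {
  if (n_edges(g) == 0L) return(matrix(integer(0), 0L, 2L))
  matrix(match(g$edges, g$nodes), ncol = 2L)
}

# Adjacency list in label space, one entry per node (possibly empty).
adjacency_list <- function(g) {
  n <- n_nodes(g)
  adj <- vector("list", n)
  if (n_edges(g) > 0L) {
    ei <- edge_index(g)
    both <- c(ei[, 1L], ei[, 2L])
    nb <- g$nodes[c(ei[, 2L], ei[, 1L])]
    grp <- split(nb, both)
    adj[as.integer(names(grp))] <- grp
  }
  names(adj) <- g$nodes
  adj
}

#' Node degrees
#'
#' @param g a `netgraph`.
#' @return integer vector of degrees aligned with `g$nodes`.
#' @export
graph_degrees <- function(g) {
  d <- integer(n_nodes(g))
  if (n_edges(g) > 0L) {
    ei <- edge_index(g)
    t <- tabulate(c(ei[, 1L], ei[, 2L]), nbins = n_nodes(g))
    d <- as.integer(t)
  }
  names(d) <- g$nodes
  d
}

#' Normalized average degree
#'
#' The average degree `2L/N` divided by `N - 1`: the fraction of possible
#' partners the average node is connected to.
#'
#' @param g a `netgraph` with at least 2 nodes.
#' @return a number in `[0, 1]`.
#' @examples
#' normalized_average_degree(generate_er(10, 20, seed = 1))
#' @export
normalized_average_degree <- function(g) {
  N <- n_nodes(g)
  if (N < 2L) {
    stop("normalized average degree is undefined for N < 2", call. = FALSE)
  }
  (2 * n_edges(g) / N) / (N - 1)
}

#' Erdos-Renyi graph with fixed node and edge counts
#'
#' Draws uniformly from the simple graphs with exactly `n` nodes and `L`
#' edges (the G(n, M) variant).  Sampling keeps the first `L` distinct pairs
#' of an i.i.d. uniform pair stream, which yields a uniformly distributed
#' edge set.
#'
#' @param n node count.
#' @param L edge count, at most `n(n-1)/2`.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return a `netgraph`.
#' @examples
#' g <- generate_er(50, 100, seed = 7)
#' @export
generate_er <- function(n, L, seed = NULL) {
  n <- as.integer(n); L <- as.integer(L)
  stopifnot(n >= 0L, L >= 0L)
  max_edges <- n * (n - 1) / 2
  if (L > max_edges) {
    stop(sprintf("L = %d exceeds the maximum %g for n = %d", L, max_edges, n),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  keys <- numeric(0)
  while (length(keys) < L) {
    batch <- max(1000L, as.integer(ceiling((L - length(keys)) * 1.4)))
    a <- sample.int(n, batch, replace = TRUE)
    b <- sample.int(n, batch, replace = TRUE)
    ok <- a != b
    k <- (pmin(a, b)[ok] - 1) * n + pmax(a, b)[ok]
    keys <- unique(c(keys, k))
  }
  keys <- keys[seq_len(L)]
  i <- ((keys - 1) %/% n) + 1
  j <- ((keys - 1) %% n) + 1
  netgraph(seq_len(n), cbind(as.integer(i), as.integer(j)))
}

#' Watts-Strogatz small-world graph
#'
#' Ring lattice on `n` nodes where each node links to its `k` nearest
#' neighbours (`k/2` on each side), after which every lattice edge is,
#' independently with probability `p_rewire`, detached at its far endpoint
#' and reattached to a uniformly chosen node, avoiding self-loops and
#' duplicate edges.  The edge count `n*k/2` is conserved exactly.
#'
#' @param n node count.
#' @param k even neighbour count, `k < n`.
#' @param p_rewire rewiring probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return a `netgraph` with exactly `n*k/2` edges.
#' @examples
#' g <- generate_ws(20, 4, 0.1, seed = 1)
#' @export
generate_ws <- function(n, k, p_rewire, seed = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (k %% 2L != 0L) stop("k must be even", call. = FALSE)
  stopifnot(k >= 2L, k < n, p_rewire >= 0, p_rewire <= 1)
  if (!is.null(seed)) set.seed(seed)
  half <- k %/% 2L
  src <- rep(seq_len(n), half)
  off <- rep(seq_len(half), each = n)
  dst <- ((src + off - 1L) %% n) + 1L
  key <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  ekey <- key(src, dst)

  rewire <- runif(length(ekey)) < p_rewire
  cur_keys <- ekey[!rewire]
  srcs <- src[rewire]
  new_keys <- numeric(length(srcs))
  todo <- seq_along(srcs)
  rounds <- 0L
  while (length(todo) > 0L) {
    rounds <- rounds + 1L
    if (rounds > 10000L) {
      stop("rewiring failed to find free endpoints; graph too dense",
           call. = FALSE)
    }
    cand <- sample.int(n, length(todo), replace = TRUE)
    k2 <- key(srcs[todo], cand)
    bad <- cand == srcs[todo] | k2 %in% cur_keys | duplicated(k2)
    new_keys[todo[!bad]] <- k2[!bad]
    cur_keys <- c(cur_keys, k2[!bad])
    todo <- todo[bad]
  }
  allk <- c(ekey[!rewire], new_keys)
  i <- ((allk - 1) %/% n) + 1
  j <- ((allk - 1) %% n) + 1
  netgraph(seq_len(n), cbind(as.integer(i), as.integer(j)))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Starts from `m` edge-less seed nodes; each subsequent node attaches `m`
#' edges to distinct existing nodes with probability proportional to their
#' current degree (uniform while all degrees are zero, so the first incoming
#' node connects to every seed).  The edge count is exactly `m * (n - m)`.
#'
#' @param n node count.
#' @param m attachment count, `1 <= m < n`.
#' @param seed optional RNG seed.
#' @return a `netgraph`.
#' @examples
#' g <- generate_ba(50, 3, seed = 2)
#' n_edges(g)  # 3 * 47
#' @export
generate_ba <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m >= n) stop("m must satisfy 1 <= m < n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- m * (n - m)
  ei <- integer(L); ej <- integer(L)
  rep_list <- integer(2L * L)
  pos <- 0L; e <- 0L

  # first incoming node: all degrees are zero, attachment is forced/uniform
  tg <- seq_len(m)
  ei[e + seq_len(m)] <- m + 1L
  ej[e + seq_len(m)] <- tg
  e <- e + m
  rep_list[pos + seq_len(2L * m)] <- c(rep(m + 1L, m), tg)
  pos <- pos + 2L * m

  if (n > m + 1L) {
    for (v in (m + 2L):n) {
      # distinct degree-proportional targets: successive distinct draws from
      # the endpoint multiset
      tg <- integer(0)
      while (length(tg) < m) {
        draw <- rep_list[sample.int(pos, 2L * m, replace = TRUE)]
        tg <- unique(c(tg, draw))
      }
      tg <- tg[seq_len(m)]
      ei[e + seq_len(m)] <- v
      ej[e + seq_len(m)] <- tg
      e <- e + m
      rep_list[pos + seq_len(2L * m)] <- c(rep(v, m), tg)
      pos <- pos + 2L * m
    }
  }
  netgraph(seq_len(n), cbind(ei, ej))
}

#' Load a SNAP-dialect edge list
#'
#' Reads a whitespace-separated text edge list: lines starting with `#` are
#' comments, the first two columns are integer node ids, extra columns (such
#' as an edge sign) are ignored.  The graph is returned as a simple
#' undirected graph: self-loops are dropped and duplicate or reversed
#' duplicate edges collapse.  Node ids are relabelled to contiguous integers;
#' the original ids are kept in `id_map`.
#'
#' @param path path to the edge-list file.
#' @param directed_to_undirected kept for interface compatibility; the
#'   container is always undirected, so both values behave identically.
#' @return a `netgraph` with `id_map` set.
#' @export
load_edge_list <- function(path, directed_to_undirected = TRUE) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- trimws(lines[keep])
  ln <- ln[keep]
  if (length(body) == 0L) {
    return(netgraph(integer(0), NULL, id_map = integer(0)))
  }
  toks <- strsplit(body, "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- which(nt < 2L)[1L]
    stop(sprintf("cannot parse edge on line %d of '%s'", ln[bad], path),
         call. = FALSE)
  }
  a <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 1L)))
  b <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 2L)))
  if (anyNA(a) || anyNA(b)) {
    bad <- which(is.na(a) | is.na(b))[1L]
    stop(sprintf("non-integer node id on line %d of '%s'", ln[bad], path),
         call. = FALSE)
  }
  ids <- sort(unique(c(a, b)))
  ai <- match(a, ids); bi <- match(b, ids)
  noself <- ai != bi
  edges <- if (any(noself)) cbind(ai[noself], bi[noself]) else NULL
  netgraph(seq_along(ids), edges, id_map = ids)
}

#' Write a graph as a SNAP-dialect edge list
#'
#' One `from to` pair per line, preceded by optional `#` comment lines.  If
#' the graph carries an `id_map`, the original identifiers are written.
#'
#' @param g a `netgraph`.
#' @param path output file path.
#' @param comments character vector written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, comments = NULL) {
  out <- character(0)
  if (!is.null(comments)) out <- paste0("# ", comments)
  if (n_edges(g) > 0L) {
    e <- g$edges
    if (!is.null(g$id_map)) {
      e <- cbind(g$id_map[e[, 1L]], g$id_map[e[, 2L]])
    }
    out <- c(out, paste(e[, 1L], e[, 2L]))
  }
  writeLines(out, path)
  invisible(path)
}
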