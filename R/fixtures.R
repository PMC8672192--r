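# Small example graphs used in documentation and tests.

#' Write example fixture graphs
#'
#' * `"shared-example"`: the six-node shared-neighbour worked example in two variants
#'   (with and without the direct 1-2 edge; the shared-neighbour proportion
#'   ignores that edge, so both give proportion 1.0 for the pair 1, 2).
#' * `"tiny-er"`: a 20-node, 40-edge fixed-seed random graph for round-trip
#'   tests.
#' * `"snap-sample"`: a SNAP-dialect sample with comment lines, a third
#'   (sign) column, a duplicate reversed edge and a self-loop; it loads to
#'   4 nodes and 4 edges.
#'
#' @param kind one of `"shared-example"`, `"tiny-er"`, `"snap-sample"`.
#' @param path output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
make_fixture <- function(kind = c("shared-example", "tiny-er", "snap-sample"),
                         path = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- switch(kind,
    `shared-example` = {
      base_edges <- rbind(c(1, 3), c(1, 4), c(1, 5), c(1, 6),
                          c(2, 3), c(2, 4))
      p1 <- file.path(path, "shared_example_without_direct_edge.txt")
      p2 <- file.path(path, "shared_example_with_direct_edge.txt")
      write_edge_list(netgraph(1:6, base_edges), p1,
                      comments = "shared-neighbour worked example, no 1-2 edge")
      write_edge_list(netgraph(1:6, rbind(base_edges, c(1, 2))), p2,
                      comments = "shared-neighbour worked example, with 1-2 edge")
      c(p1, p2)
    },
    `tiny-er` = {
      p <- file.path(path, "tiny_er.txt")
      write_edge_list(generate_er(20, 40, seed = 20L), p,
                      comments = "20-node, 40-edge test graph (seed 20)")
      p
    },
    `snap-sample` = {
      p <- file.path(path, "snap_sample.txt")
      writeLines(c(
        "# Directed graph (each unordered pair of nodes is saved once)",
        "# FromNodeId ToNodeId Sign",
        "1 2 -1",
        "2 1 1",
        "1 1 1",
        "2 3 -1",
        "3 4 1",
        "4 2 1"), p)
      p
    })
  invisible(paths)
}
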