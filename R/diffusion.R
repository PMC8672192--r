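# Discrete-time diffusion engines: stochastic SIR and the deterministic
# Threshold cascade, both on a `netgraph`.

#' SIR parameters
#'
#' @param beta per-contact, per-step infection probability.
#' @param gamma per-step recovery probability.
#' @param init_frac fraction of nodes initially infected; the seed count is
#'   `round(init_frac * N)` on the current (possibly degraded) graph.
#' @param max_iters iteration cap (default 2,500; runs normally end earlier,
#'   at extinction).
#' @return an object of class `sir_params`.
#' @export
sir_params <- function(beta, gamma, init_frac, max_iters = 2500L) {
  stopifnot(beta >= 0, beta <= 1, gamma >= 0, gamma <= 1,
            init_frac >= 0, init_frac <= 1, max_iters >= 1)
  structure(list(beta = beta, gamma = gamma, init_frac = init_frac,
                 max_iters = as.integer(max_iters)),
            class = "sir_params")
}

#' Threshold-cascade parameters
#'
#' @param threshold activation fraction applied to every node (default 0.5):
#'   a susceptible node activates when strictly more than this fraction of
#'   its neighbours is infected.
#' @param init_frac fraction of nodes initially infected.
#' @param max_iters iteration cap (default 30).
#' @return an object of class `threshold_params`.
#' @export
threshold_params <- function(threshold = 0.5, init_frac, max_iters = 30L) {
  stopifnot(threshold >= 0, threshold <= 1,
            init_frac >= 0, init_frac <= 1, max_iters >= 1)
  structure(list(threshold = threshold, init_frac = init_frac,
                 max_iters = as.integer(max_iters)),
            class = "threshold_params")
}

new_diffusion_result <- function(model, S, I, R, n_initial, stabilized_at,
                                 n_nodes, max_iters, states = NULL) {
  counts <- data.frame(t = seq_along(S) - 1L, S = S, I = I, R = R)
  structure(list(counts = counts, n_initial_infected = n_initial,
                 stabilized_at = stabilized_at, n_nodes = n_nodes,
                 max_iters = max_iters, model = model, states = states),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  last <- nrow(x$counts)
  cat(sprintf(
    "<diffusion_result:%s> N=%d, seeds=%d, %d steps, final S/I/R = %d/%d/%d\n",
    x$model, x$n_nodes, x$n_initial_infected, last - 1L,
    x$counts$S[last], x$counts$I[last], x$counts$R[last]))
  invisible(x)
}

#' Per-timestep counts of a diffusion run
#'
#' @param x a `diffusion_result`.
#' @param ... unused.
#' @return data frame with columns `t`, `S`, `I`, `R` (`R` is always 0 for
#'   the Threshold model).  Suitable for `write.csv()`.
#' @export
as.data.frame.diffusion_result <- function(x, ...) x$counts

seed_nodes <- function(N, init_frac) {
  n_init <- as.integer(round(init_frac * N))
  if (n_init == 0L) integer(0) else sample.int(N, n_init)
}

explicit_or_random_seeds <- function(g, init_frac, initial_infected) {
  if (is.null(initial_infected)) {
    return(seed_nodes(n_nodes(g), init_frac))
  }
  idx <- match(as.integer(initial_infected), g$nodes)
  if (anyNA(idx)) stop("initial_infected contains unknown nodes",
                       call. = FALSE)
  as.integer(idx)
}

#' Run the discrete-time SIR model
#'
#' `round(init_frac * N)` seed nodes are chosen uniformly without
#' replacement.  Each iteration uses the infected set snapshotted at the
#' iteration start: every snapshot-infected node attempts an independent
#' Bernoulli(`beta`) infection on each currently susceptible neighbour and
#' then recovers with probability `gamma`.  Nodes infected within an
#' iteration transmit (and may recover) only from the next iteration.  The
#' run ends at extinction or after `max_iters` iterations.
#'
#' @param g a `netgraph`.
#' @param params a [sir_params()] object.
#' @param seed optional RNG seed.
#' @param record_states if `TRUE`, keep the full per-node state trajectory
#'   (0 = S, 1 = I, 2 = R; one vector per timestep) in the result -- meant
#'   for small graphs.
#' @param initial_infected optional vector of node labels to seed instead of
#'   random seeding (used for deterministic checks).
#' @return a `diffusion_result`.
#' @export
run_sir <- function(g, params, seed = NULL, record_states = FALSE,
                    initial_infected = NULL) {
  stopifnot(inherits(params, "sir_params"))
  N <- n_nodes(g)
  stopifnot(N >= 1L)
  if (!is.null(seed)) set.seed(seed)
  init <- explicit_or_random_seeds(g, params$init_frac, initial_infected)
  res <- cpp_run_sir(N, edge_index(g), init, params$beta, params$gamma,
                     params$max_iters, record_states)
  new_diffusion_result("sir", res$S, res$I, res$R, length(init),
                       res$stabilized_at, N, params$max_iters,
                       states = res$states)
}

#' Run the Threshold cascade
#'
#' Seeds are chosen as in [run_sir()].  Each iteration, synchronously, every
#' susceptible node whose infected-neighbour fraction (against the
#' iteration-start infected set) strictly exceeds `threshold` becomes
#' infected; zero-degree nodes never activate.  The process is deterministic
#' given the seed set and stops at the first iteration with no change (or at
#' `max_iters`).
#'
#' @inheritParams run_sir
#' @param params a [threshold_params()] object.
#' @return a `diffusion_result` (with `R` identically 0).
#' @export
run_threshold <- function(g, params, seed = NULL, record_states = FALSE,
                          initial_infected = NULL) {
  stopifnot(inherits(params, "threshold_params"))
  N <- n_nodes(g)
  stopifnot(N >= 1L)
  if (!is.null(seed)) set.seed(seed)
  init <- explicit_or_random_seeds(g, params$init_frac, initial_infected)
  res <- cpp_run_threshold(N, edge_index(g), init, params$threshold,
                           params$max_iters, record_states)
  new_diffusion_result("threshold", res$S, res$I, rep(0L, length(res$S)),
                       length(init), res$stabilized_at, N, params$max_iters,
                       states = res$states)
}

#' Summary metrics of a diffusion run
#'
#' * `total_infected_frac`: (final infected + removed) / N, the attack rate.
#' * `additional_infected_frac`: ever-infected beyond the seeds, normalized
#'   by the initially susceptible count: `(I_final + R_final - seeds) /
#'   (N - seeds)`.
#' * `peak_infected_frac`: `max_t I(t) / N`.
#' * `time_to_peak`: first timestep attaining the peak.
#' * `time_to_stability`: `stabilized_at`, or `max_iters` if the run never
#'   stabilized.
#'
#' @param result a `diffusion_result`.
#' @param metric one of the five metric names above.
#' @return a single number.
#' @export
summarize_diffusion <- function(result,
    metric = c("total_infected_frac", "additional_infected_frac",
               "peak_infected_frac", "time_to_peak", "time_to_stability")) {
  metric <- match.arg(metric)
  cnt <- result$counts
  last <- nrow(cnt)
  N <- result$n_nodes
  switch(metric,
    total_infected_frac = (cnt$I[last] + cnt$R[last]) / N,
    additional_infected_frac = {
      n0 <- result$n_initial_infected
      if (n0 >= N) {
        stop("additional_infected_frac is undefined when all nodes are seeds",
             call. = FALSE)
      }
      (cnt$I[last] + cnt$R[last] - n0) / (N - n0)
    },
    peak_infected_frac = max(cnt$I) / N,
    time_to_peak = cnt$t[which.max(cnt$I)],
    time_to_stability = if (is.na(result$stabilized_at)) result$max_iters
                        else result$stabilized_at)
}

diffusion_metrics <- c("total_infected_frac", "additional_infected_frac",
                       "peak_infected_frac", "time_to_peak",
                       "time_to_stability")

# All five metrics of one run as a named numeric vector.
summarize_all <- function(result) {
  vapply(diffusion_metrics, function(m) summarize_diffusion(result, m),
         numeric(1))
}
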