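#' Single SIR realization on a temporal network
#'
#' Runs one discrete-time susceptible-infected-recovered epidemic over the
#' snapshot sequence, seeded at `source`, and returns the ever-infected
#' count `N_v(L)` (the infected scale). Per snapshot `t`, every node
#' infectious during `t` attempts independently, with probability `beta`, to
#' infect each currently susceptible neighbor in `G_t`; newly infected nodes
#' become infectious at snapshot `t+1`; nodes infectious during `t` recover
#' with probability `mu` at the end of `t`. With `mu = 1` every node is
#' infectious for exactly one snapshot, and at `beta = 1` the infected
#' scale deterministically equals the spreading-front reachability set size
#' of [temporal_reach_size()].
#'
#' @param net a [temporal_network()].
#' @param source seed node in `1..N`, infectious from snapshot 1.
#' @param beta infection probability per contact per snapshot, in `[0, 1]`.
#' @param mu recovery probability per snapshot, in `[0, 1]`.
#' @return Integer infected scale in `1..N`.
#' @export
#' @examples
#' set.seed(1)
#' sir_single_run(toy_chain_network(), source = 1, beta = 1, mu = 1)  # 4
sir_single_run <- function(net, source, beta, mu = 1) {
  check_sir_args(net, source, beta, mu)
  sir_runs_cpp(net$snapshots, net$n_nodes, as.integer(source),
               beta, mu, 1L)[1L]
}

#' Mean infected scale of one source node
#'
#' Averages the infected scale `N_v(L)` over `runs` independent SIR
#' realizations from `source`, with a seeded random stream.
#'
#' @inheritParams sir_single_run
#' @param runs number of Monte-Carlo repetitions.
#' @param seed integer seed; the same seed reproduces all runs.
#' @return An object of class `spread_result`: list with `source`, `scales`
#'   (integer vector of per-run infected scales) and `mean`.
#' @export
#' @examples
#' mean_infected_scale(toy_chain_network(), source = 1, beta = 0.5,
#'                     runs = 200, seed = 42)
mean_infected_scale <- function(net, source, beta, mu = 1, runs = 1000L,
                                seed = 1L) {
  check_sir_args(net, source, beta, mu)
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("`runs` must be >= 1")
  scales <- withr::with_seed(seed,
    sir_runs_cpp(net$snapshots, net$n_nodes, as.integer(source),
                 beta, mu, runs))
  structure(list(source = as.integer(source), scales = scales,
                 mean = mean(scales)),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("SIR spread from node %d: mean infected scale %.3f over %d runs\n",
              x$source, x$mean, length(x$scales)))
  invisible(x)
}

#' Per-node SIR influence (ground truth or training labels)
#'
#' Runs [mean_infected_scale()] for every node and assembles the means into
#' a score vector. This is both the ground-truth influence (typically
#' `runs = 1000`) and, at the training infection rate `beta_t` with
#' `mu = 1`, the label vector for the MLI regressor (typically
#' `runs = 100`, then normalized by `N` before optimization). A master seed
#' derives one independent substream per node, so the result does not depend
#' on evaluation order.
#'
#' @inheritParams mean_infected_scale
#' @param normalize divide the mean scales by `N` (used for training
#'   labels; ranking is unaffected).
#' @return Numeric vector of length `N`: mean infected scale per source
#'   node.
#' @export
#' @examples
#' spreading_influence(toy_chain_network(), beta = 0.5, runs = 50, seed = 7)
spreading_influence <- function(net, beta, mu = 1, runs = 1000L, seed = 1L,
                                normalize = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  out <- vapply(seq_len(n), function(v)
    mean_infected_scale(net, v, beta, mu, runs,
                        seed = derive_seed(seed, v))$mean,
    numeric(1))
  if (normalize) out / n else out
}

#' Spreading-front reachability set size
#'
#' Number of nodes (including the source) reachable from `source` by a
#' chain that crosses one edge in each consecutive snapshot starting at
#' snapshot 1 (`(x0, x1) in E_1`, `(x1, x2) in E_2`, ...). This is exactly
#' the set an SIR epidemic at `beta = 1`, `mu = 1` infects: with `mu = 1`
#' every node transmits during precisely the snapshot after its infection,
#' so the infection front cannot wait. Note that it is therefore smaller,
#' in general, than reachability by the waiting-allowed foremost paths of
#' [earliest_arrival()] that underlie the closeness and betweenness scores.
#'
#' @inheritParams sir_single_run
#' @return Integer count in `1..N`.
#' @export
temporal_reach_size <- function(net, source) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  reached <- logical(n)
  reached[source] <- TRUE
  frontier <- as.integer(source)
  for (tau in seq_len(net$n_snapshots)) {
    if (length(frontier) == 0L) break
    e <- net$snapshots[[tau]]
    if (nrow(e) == 0L) { frontier <- integer(0); next }
    f1 <- e[, 1L] %in% frontier
    f2 <- e[, 2L] %in% frontier
    newly <- unique(c(e[f1, 2L], e[f2, 1L]))
    newly <- newly[!reached[newly]]
    reached[newly] <- TRUE
    frontier <- newly
  }
  sum(reached)
}

check_sir_args <- function(net, source, beta, mu) {
  stopifnot(inherits(net, "temporal_network"))
  source <- as.integer(source)
  if (is.na(source) || source < 1L || source > net$n_nodes)
    stop("`source` outside 1..N")
  if (is.na(beta) || beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  if (is.na(mu) || mu < 0 || mu > 1) stop("`mu` must be in [0, 1]")
  invisible(TRUE)
}

#' Read / write score vectors as CSV
#'
#' Plain `node,score` CSV with a header; the on-disk interchange format for
#' labels, ground truth and centrality scores.
#'
#' @param scores numeric vector of per-node scores.
#' @param path file path.
#' @return `read_scores()` returns a numeric vector ordered by node index;
#'   `write_scores()` invisibly returns `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(data.frame(node = seq_along(scores), score = scores),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("node", "score") %in% names(df)))
    stop("score CSV needs columns 'node' and 'score'")
  df$score[order(df$node)]
}
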