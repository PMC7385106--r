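#' Temporal closeness centrality
#'
#' Sums reciprocal temporal distances over every start offset and every
#' target: `TC(v) = sum_{0 <= t < L} sum_{u != v} 1 / Delta_{t,T}(v, u)`,
#' where `Delta_{t,T}(v, u)` is the foremost time-respecting distance from
#' `v` to `u` using snapshots `t+1..L` (see [earliest_arrival()]);
#' unreachable targets contribute 0.
#'
#' @param net a [temporal_network()].
#' @return Numeric vector of length `N` of scores.
#' @export
#' @examples
#' temporal_closeness(toy_chain_network())
temporal_closeness <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  L <- net$n_snapshots
  tc <- numeric(n)
  for (start in 0:(L - 1L)) {
    for (v in seq_len(n)) {
      delta <- earliest_arrival(net, v, start)
      delta[v] <- Inf  # exclude the self term
      tc[v] <- tc[v] + sum(1 / delta)
    }
  }
  tc
}

#' Temporal betweenness centrality
#'
#' For every start offset `t` and every ordered pair `(s, d)` with at least
#' one time-respecting path, accumulates the fraction of foremost
#' trajectories from `s` to `d` whose interior contains `v`:
#' `TB(v) = sum_t sum_{s != v != d, sigma > 0} sigma_{t,T}(s,d,v) /
#' sigma_{t,T}(s,d)`. Path semantics are those of
#' [count_shortest_paths()]; pairs are ordered because temporal reachability
#' is asymmetric even on undirected snapshots.
#'
#' @param net a [temporal_network()].
#' @return Numeric vector of length `N` of scores.
#' @export
#' @examples
#' temporal_betweenness(toy_chain_network())
temporal_betweenness <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  temporal_betweenness_cpp(net$snapshots, net$n_nodes)
}

#' Temporal k-shell centrality
#'
#' Scores each node by summing, over its neighbors `u` in the aggregated
#' union graph and over snapshots, the smaller of the two per-snapshot core
#' numbers: `TK(v) = sum_{u in Gamma_v} sum_t min(k_s^t(v), k_s^t(u))`.
#' `k_s^t` is the classic k-shell (core) number of snapshot `t`, with
#' isolated nodes scored 0.
#'
#' @param net a [temporal_network()].
#' @return Numeric vector of length `N` of scores.
#' @export
temporal_kshell <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  L <- net$n_snapshots
  core <- matrix(0L, nrow = n, ncol = L)
  for (t in seq_len(L)) {
    e <- net$snapshots[[t]]
    if (nrow(e) == 0L) next
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    core[, t] <- igraph::coreness(g)
  }
  agg <- aggregate_network(net)
  tk <- numeric(n)
  if (nrow(agg$pairs) > 0L) {
    for (i in seq_len(nrow(agg$pairs))) {
      u <- agg$pairs[i, 1L]
      v <- agg$pairs[i, 2L]
      contrib <- sum(pmin(core[u, ], core[v, ]))
      tk[u] <- tk[u] + contrib
      tk[v] <- tk[v] + contrib
    }
  }
  tk
}

#' Temporal degree deviation centrality
#'
#' The population standard deviation of a node's per-snapshot degree
#' sequence around its own mean:
#' `TDD(v) = sqrt( (1/L) sum_t (D_t(v) - D(v))^2 )`. Nodes whose degree is
#' constant across snapshots score 0.
#'
#' @param net a [temporal_network()].
#' @return Numeric vector of length `N` of scores.
#' @export
temporal_degree_deviation <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  dg <- degree_matrix(net)
  sqrt(rowMeans((dg - rowMeans(dg))^2))
}

# per-snapshot degree matrix, N x L
degree_matrix <- function(net) {
  n <- net$n_nodes
  vapply(net$snapshots, function(e)
    tabulate(c(e[, 1L], e[, 2L]), n), integer(n))
}

#' Temporal dynamics-sensitive centrality
#'
#' Analytic SIR spreading influence under a linearized discrete-time model:
#' `S = sum_{r=0}^{L-1} beta * H^r A(r+1) V` with the propagator
#' `H^t = [beta A(t) + (1-mu) I] ... [beta A(1) + (1-mu) I]`, `H^0 = I`,
#' where `A(t)` is the adjacency matrix of snapshot `t` and `V` the all-ones
#' vector. Each term is evaluated by sparse matrix-vector recursion, so no
#' dense `N x N` product is formed. At `L = 1` the score reduces to
#' `beta * A(1) V`, i.e. `beta` times the degree vector.
#'
#' @param net a [temporal_network()].
#' @param beta infection probability per contact per snapshot.
#' @param mu recovery probability per snapshot (1 matches the SIR ground
#'   truth used elsewhere in the package).
#' @return Numeric vector of length `N` of scores.
#' @export
#' @examples
#' temporal_dynamics_sensitive(toy_chain_network(), beta = 0.1)
temporal_dynamics_sensitive <- function(net, beta, mu = 1) {
  stopifnot(inherits(net, "temporal_network"))
  if (beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]")
  n <- net$n_nodes
  L <- net$n_snapshots
  A <- lapply(net$snapshots, function(e) {
    if (nrow(e) == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(n, n)))
    Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                         j = c(e[, 2L], e[, 1L]),
                         x = 1, dims = c(n, n))
  })
  ones <- rep(1, n)
  S <- numeric(n)
  for (r in 0:(L - 1L)) {
    x <- as.numeric(A[[r + 1L]] %*% ones)
    for (alpha in seq_len(r))  # apply [beta A(alpha) + (1-mu) I], alpha = 1..r
      x <- beta * as.numeric(A[[alpha]] %*% x) + (1 - mu) * x
    S <- S + beta * x
  }
  S
}

#' Compute any benchmark centrality by name
#'
#' Dispatcher over the five benchmark temporal centralities and the MLI
#' score. Method tags: `"tc"` (closeness), `"tb"` (betweenness), `"tk"`
#' (k-shell), `"tdd"` (degree deviation), `"tdc"` (dynamics-sensitive,
#' needs `beta`), `"mli"` (needs a trained `model`).
#'
#' @param net a [temporal_network()].
#' @param method one of `"tc"`, `"tb"`, `"tk"`, `"tdd"`, `"tdc"`, `"mli"`.
#' @param beta infection rate, used by `"tdc"` only.
#' @param mu recovery rate, used by `"tdc"` only.
#' @param model a trained [mli_train()] model, used by `"mli"` only.
#' @return Numeric vector of length `N` of scores.
#' @export
centrality_scores <- function(net, method, beta = 0.1, mu = 1, model = NULL) {
  switch(method,
    tc = temporal_closeness(net),
    tb = temporal_betweenness(net),
    tk = temporal_kshell(net),
    tdd = temporal_degree_deviation(net),
    tdc = temporal_dynamics_sensitive(net, beta = beta, mu = mu),
    mli = {
      if (is.null(model)) stop("method 'mli' needs a trained `model`")
      mli_score(model, net)
    },
    stop("unknown method tag: ", method))
}
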