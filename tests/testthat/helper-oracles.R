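# Independent oracles and fixture builders used across the suite. The
# oracles deliberately avoid the package's algorithms: path statistics come
# from exhaustive enumeration of position trajectories, reachability from a
# dense-matrix front simulation, and TDC from a literal dense evaluation of
# its defining matrix sums.

toy4 <- function() toy_chain_network()

# random snapshot sequence: each snapshot an independent G(n, p)
random_temporal_net <- function(n, L, p, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    snaps <- lapply(seq_len(L), function(t)
      pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
    temporal_network(snaps, n_nodes = n)
  })
}

# Exhaustive enumeration of time-respecting position trajectories from s
# starting at offset `start`. For every target d, records each distinct
# trajectory prefix at its first visit to d; foremost statistics follow.
# Only feasible for tiny networks (N <= ~6, L <= ~4).
enum_path_stats <- function(net, s, start = 0L) {
  n <- net$n_nodes
  L <- net$n_snapshots
  nbrs <- lapply(net$snapshots, function(e) {
    a <- rep(list(integer(0)), n)
    for (r in seq_len(nrow(e))) {
      a[[e[r, 1L]]] <- c(a[[e[r, 1L]]], e[r, 2L])
      a[[e[r, 2L]]] <- c(a[[e[r, 2L]]], e[r, 1L])
    }
    a
  })
  rec <- lapply(seq_len(n), function(d) new.env(parent = emptyenv()))
  walk <- function(seqv, tau) {
    if (tau > L) return(invisible(NULL))
    cur <- seqv[length(seqv)]
    for (nx in unique(c(cur, nbrs[[tau]][[cur]]))) {
      newseq <- c(seqv, nx)
      if (nx != s && !(nx %in% seqv)) {
        key <- paste(newseq, collapse = ",")
        if (is.null(rec[[nx]][[key]]))
          rec[[nx]][[key]] <- list(
            arrival = tau,
            interior = setdiff(unique(seqv), s))
      }
      walk(newseq, tau + 1L)
    }
  }
  walk(s, start + 1L)
  lapply(seq_len(n), function(d) {
    entries <- as.list(rec[[d]])
    if (length(entries) == 0L)
      return(list(arrival = Inf, sigma = 0, through = numeric(n)))
    arrs <- vapply(entries, `[[`, numeric(1), "arrival")
    tstar <- min(arrs)
    best <- entries[arrs == tstar]
    through <- numeric(n)
    for (b in best) through[b$interior] <- through[b$interior] + 1
    list(arrival = tstar, sigma = length(best), through = through)
  })
}

oracle_earliest <- function(net, s, start = 0L) {
  stats <- enum_path_stats(net, s, start)
  delta <- vapply(stats, function(x) x$arrival, numeric(1)) - start
  delta[s] <- 0
  delta
}

oracle_tc <- function(net) {
  n <- net$n_nodes
  out <- numeric(n)
  for (start in 0:(net$n_snapshots - 1L)) {
    for (v in seq_len(n)) {
      delta <- oracle_earliest(net, v, start)
      out[v] <- out[v] + sum(1 / delta[-v])
    }
  }
  out
}

oracle_tb <- function(net) {
  n <- net$n_nodes
  out <- numeric(n)
  for (start in 0:(net$n_snapshots - 1L)) {
    for (s in seq_len(n)) {
      stats <- enum_path_stats(net, s, start)
      for (d in seq_len(n)) {
        if (d == s || stats[[d]]$sigma == 0) next
        out <- out + stats[[d]]$through / stats[[d]]$sigma
      }
    }
  }
  out
}

# Spreading-front reachability by dense matrix propagation: the front at
# step t is A_t applied to the previous front, restricted to unseen nodes.
oracle_front_reach <- function(net, source) {
  n <- net$n_nodes
  reached <- logical(n)
  reached[source] <- TRUE
  front <- as.numeric(reached)
  for (t in seq_len(net$n_snapshots)) {
    e <- net$snapshots[[t]]
    A <- matrix(0, n, n)
    if (nrow(e) > 0L) {
      A[e] <- 1
      A[e[, c(2L, 1L), drop = FALSE]] <- 1
    }
    nf <- as.numeric(A %*% front) > 0 & !reached
    reached <- reached | nf
    front <- as.numeric(nf)
  }
  sum(reached)
}

# Literal dense evaluation of the dynamics-sensitive score: explicit
# propagator products H^r = M(r) ... M(1) with M(t) = beta A(t) + (1-mu) I.
oracle_tdc <- function(net, beta, mu) {
  n <- net$n_nodes
  A <- lapply(net$snapshots, function(e) {
    M <- matrix(0, n, n)
    if (nrow(e) > 0L) {
      M[e] <- 1
      M[e[, c(2L, 1L), drop = FALSE]] <- 1
    }
    M
  })
  S <- numeric(n)
  for (r in 0:(net$n_snapshots - 1L)) {
    H <- diag(n)
    if (r >= 1L)
      for (a in r:1) H <- H %*% (beta * A[[a]] + (1 - mu) * diag(n))
    S <- S + beta * as.numeric(H %*% A[[r + 1L]] %*% rep(1, n))
  }
  S
}
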