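#' Generate a synthetic temporal scale-free network
#'
#' Builds `L` independent Barabási–Albert preferential-attachment graphs on
#' the same node set `1..n` and stacks them as snapshots. Each snapshot
#' starts from `m` isolated seed nodes; each of the remaining `n - m` nodes
#' arrives in index order and attaches `m` edges to distinct existing nodes
#' chosen preferentially by degree (the first arrival attaches to the seeds).
#' Every snapshot therefore has exactly `m * (n - m)` edges and the network
#' `L * m * (n - m)` in total; with `n = 500`, `m = 1`, `L = 30` this is the
#' 14970-edge temporal scale-free benchmark configuration.
#'
#' Because arrival order is the same in every snapshot, low-index nodes tend
#' to be hubs in all snapshots, giving the persistent heterogeneity that the
#' influence-regression task relies on.
#'
#' @param n number of nodes (`n > m`).
#' @param m edges attached by each arriving node.
#' @param n_snapshots number of snapshots `L`.
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @return A [temporal_network()] with `interval = NA` (no physical
#'   timescale).
#' @export
#' @examples
#' net <- generate_temporal_ba(50, m = 1, n_snapshots = 5, seed = 1)
#' n_edges(net)  # 5 * 49
generate_temporal_ba <- function(n, m = 1L, n_snapshots = 30L, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m); L <- as.integer(n_snapshots)
  if (is.na(m) || m < 1L) stop("`m` must be >= 1")
  if (is.na(n) || n <= m) stop("`n` must exceed `m`")
  if (is.na(L) || L < 1L) stop("`n_snapshots` must be >= 1")
  snaps <- withr::with_seed(seed,
    lapply(seq_len(L), function(t) ba_snapshot_edges(n, m)))
  temporal_network(snaps, n_nodes = n)
}

# One BA realization: m isolated seeds, arrivals m+1..n each wiring m edges
# to distinct targets sampled proportionally to degree (uniform over the
# seeds for the first arrival). Classic "repeated nodes" sampling.
ba_snapshot_edges <- function(n, m) {
  eu <- integer(m * (n - m))
  ev <- integer(m * (n - m))
  # each endpoint of each edge appears once; preferential sampling by
  # drawing uniformly from the list of edge endpoints
  repeated <- integer(2L * m * (n - m))
  n_rep <- 0L
  targets <- seq_len(m)
  k <- 0L
  for (v in (m + 1L):n) {
    for (tgt in targets) {
      k <- k + 1L
      eu[k] <- v; ev[k] <- tgt
    }
    repeated[n_rep + seq_len(m)] <- targets
    repeated[n_rep + m + seq_len(m)] <- rep.int(v, m)
    n_rep <- n_rep + 2L * m
    if (v < n) {
      if (m == 1L) {
        targets <- repeated[sample.int(n_rep, 1L)]
      } else {
        targets <- integer(0)
        while (length(targets) < m) {
          draw <- repeated[sample.int(n_rep, m - length(targets),
                                      replace = TRUE)]
          targets <- unique(c(targets, draw))
        }
      }
    }
  }
  cbind(eu, ev)
}

# Derive a reproducible sub-seed from a master seed and a stream index.
# Keeps results independent of evaluation order (e.g. per-node label runs)
# while staying inside 32-bit integer range.
derive_seed <- function(master, index) {
  a <- (as.double(master) %% 2147483647) + 1
  x <- (a * 48271 + as.double(index) * 3141593) %% 2147483629
  as.integer(x) + 1L
}
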