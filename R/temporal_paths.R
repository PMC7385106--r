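#' Earliest-arrival temporal distances from one node
#'
#' Computes time-respecting shortest-path (foremost) distances on the
#' time-ordered graph: starting from `source` at snapshot offset `start`
#' (0-based, i.e. before snapshot `start + 1`), the frontier may, at each
#' subsequent snapshot, wait in place or traverse one edge of that snapshot.
#' The temporal distance to `u` is `Delta = arrival snapshot - start`, the
#' number of snapshots needed; unreachable nodes get `Inf` and
#' `Delta(source) = 0`.
#'
#' @param net a [temporal_network()].
#' @param source node index in `1..N`.
#' @param start 0-based start offset in `0..L-1`; `start = 0` uses the full
#'   snapshot sequence.
#' @return Numeric vector of length `N` of temporal distances.
#' @seealso [count_shortest_paths()], [temporal_closeness()]
#' @export
#' @examples
#' earliest_arrival(toy_chain_network(), source = 1, start = 0)
earliest_arrival <- function(net, source, start = 0L) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  L <- net$n_snapshots
  source <- as.integer(source)
  start <- as.integer(start)
  if (is.na(source) || source < 1L || source > n)
    stop("`source` outside 1..N")
  if (is.na(start) || start < 0L || start >= L)
    stop("`start` outside 0..L-1")
  reached <- logical(n)
  reached[source] <- TRUE
  arrival <- rep(Inf, n)
  arrival[source] <- start
  if (start + 1L <= L) {
    for (tau in (start + 1L):L) {
      e <- net$snapshots[[tau]]
      if (nrow(e) == 0L) next
      r1 <- reached[e[, 1L]]
      r2 <- reached[e[, 2L]]
      newly <- unique(c(e[r1 & !r2, 2L], e[r2 & !r1, 1L]))
      if (length(newly) > 0L) {
        arrival[newly] <- tau
        reached[newly] <- TRUE
        if (all(reached)) break
      }
    }
  }
  arrival - start
}

#' Count temporal shortest paths and their interior nodes
#'
#' Counts the foremost trajectories from `s` to `d`: position sequences
#' (which node is occupied at each snapshot after `start`, waiting allowed,
#' at most one edge traversal per snapshot) that first reach `d` at the
#' minimal arrival snapshot. Trajectories differing only in where they wait
#' are distinct, matching path counting in the time-ordered graph;
#' trajectories stop on reaching `d`. For every other node `v` the function
#' also reports how many of these trajectories occupy `v` at some interior
#' snapshot (each trajectory counted once, however often it visits `v`),
#' computed as the count minus the count with `v` forbidden.
#'
#' @param net a [temporal_network()].
#' @param s,d distinct source and destination nodes.
#' @param start 0-based start offset.
#' @return List with `sigma` (number of foremost trajectories, 0 when `d` is
#'   unreachable), `arrival` (earliest arrival snapshot, `Inf` if
#'   unreachable) and `through` (length-`N` vector of interior counts;
#'   zero at `s` and `d`).
#' @export
#' @examples
#' count_shortest_paths(toy_chain_network(), s = 1, d = 4, start = 0)
count_shortest_paths <- function(net, s, d, start = 0L) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  L <- net$n_snapshots
  s <- as.integer(s); d <- as.integer(d); start <- as.integer(start)
  if (s == d) stop("`s` and `d` must differ")
  if (any(c(s, d) < 1L) || any(c(s, d) > n)) stop("node outside 1..N")
  if (start < 0L || start >= L) stop("`start` outside 0..L-1")
  through <- numeric(n)
  arr <- path_count_forward(net, s, start, avoid = 0L)
  if (is.infinite(arr$arrival[d]))
    return(list(sigma = 0, arrival = Inf, through = through))
  tstar <- arr$arrival[d]
  sigma <- arr$count[d]
  for (v in seq_len(n)) {
    if (v == s || v == d) next
    if (is.infinite(arr$arrival[v]) || arr$arrival[v] >= tstar) next
    av <- path_count_forward(net, s, start, avoid = v, stop_at = tstar)
    through[v] <- sigma - av$count[d]
  }
  list(sigma = sigma, arrival = tstar, through = through)
}

# Forward trajectory-count dynamic program. Returns, for every node d, the
# earliest arrival snapshot and the number of trajectories first reaching d
# then (the inflow at the arrival snapshot). `avoid` > 0 forbids occupying
# that node. Since arrivals are minimal, trajectories counted at arrival(d)
# cannot have visited d earlier; no absorption bookkeeping is needed.
path_count_forward <- function(net, s, start, avoid = 0L, stop_at = NULL) {
  n <- net$n_nodes
  L <- if (is.null(stop_at)) net$n_snapshots else stop_at
  f <- numeric(n)
  f[s] <- 1
  arrival <- rep(Inf, n)
  count <- numeric(n)
  if (start + 1L <= L) {
    for (tau in (start + 1L):L) {
      e <- net$snapshots[[tau]]
      inflow <- numeric(n)
      if (nrow(e) > 0L) {
        vals <- c(f[e[, 2L]], f[e[, 1L]])
        idx <- c(e[, 1L], e[, 2L])
        nz <- vals != 0
        if (any(nz)) {
          agg <- rowsum(vals[nz], idx[nz])
          inflow[as.integer(rownames(agg))] <- agg[, 1L]
        }
      }
      first <- is.infinite(arrival) & inflow > 0 & seq_len(n) != s
      arrival[first] <- tau
      count[first] <- inflow[first]
      f <- f + inflow
      if (avoid > 0L) f[avoid] <- 0
    }
  }
  list(arrival = arrival, count = count)
}
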