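#' Construct a temporal network from per-snapshot edge lists
#'
#' A temporal network with `N` nodes and horizon `T` is stored as an ordered
#' sequence of `L` static snapshot graphs `G_1, ..., G_L`, each of width
#' `delta = T / L`. All snapshots share the node set `1..N`; a node may be
#' isolated in any snapshot. Edges are undirected and unweighted; self-loops
#' are dropped and duplicate edges within a snapshot are merged.
#'
#' @param snapshots list of length `L`; each element an edge list for one
#'   snapshot, given as a two-column matrix (or data frame) of node indices in
#'   `1..n_nodes`, or `NULL`/zero-row for an edgeless snapshot.
#' @param n_nodes number of nodes `N`; nodes are the integers `1..N`.
#' @param interval snapshot width `delta` in time units, or `NA` when the
#'   network has no physical timescale (e.g. synthetic snapshot sequences).
#' @param labels optional character vector of length `n_nodes` giving external
#'   node labels; internal indices are always `1..N`.
#'
#' @return An object of class `temporal_network` with fields `n_nodes`,
#'   `n_snapshots`, `interval`, `snapshots` (list of sorted, deduplicated
#'   two-column integer matrices) and `labels`.
#' @seealso [bin_edge_stream()], [generate_temporal_ba()], [read_snapshots()]
#' @export
#' @examples
#' net <- temporal_network(list(cbind(1, 2), cbind(2, 3)), n_nodes = 3)
#' net$n_snapshots
temporal_network <- function(snapshots, n_nodes, interval = NA_real_,
                             labels = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 1L)
    stop("`snapshots` must be a non-empty list of edge lists")
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("`n_nodes` must be a positive integer")
  snaps <- lapply(snapshots, clean_edges, n_nodes = n_nodes)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n_nodes)
      stop("`labels` must have length `n_nodes`")
  }
  structure(
    list(n_nodes = n_nodes,
         n_snapshots = length(snaps),
         interval = as.numeric(interval),
         snapshots = snaps,
         labels = labels),
    class = "temporal_network")
}

# Canonicalize one snapshot edge list: integer matrix, u < v, no self-loops,
# no duplicates, rows sorted. Self-loops are silently dropped (the networks
# modelled here are simple graphs).
clean_edges <- function(edges, n_nodes) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("u", "v"))))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("each snapshot edge list must have exactly two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L) || any(edges > n_nodes))
    stop("edge endpoints must be node indices in 1..", n_nodes)
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  key <- (as.double(u) - 1) * n_nodes + as.double(v)
  ord <- order(key)
  u <- u[ord]; v <- v[ord]; key <- key[ord]
  dup <- duplicated(key)
  matrix(c(u[!dup], v[!dup]), ncol = 2L,
         dimnames = list(NULL, c("u", "v")))
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("temporal_network: %d nodes, %d snapshots, %d edges%s\n",
              x$n_nodes, x$n_snapshots, n_edges(x),
              if (is.na(x$interval)) "" else
                sprintf(", interval %g", x$interval)))
  invisible(x)
}

#' Total number of edges across all snapshots
#'
#' @param net a [temporal_network()].
#' @return Integer: `sum_t |E_t|`.
#' @export
n_edges <- function(net) {
  sum(vapply(net$snapshots, nrow, integer(1)))
}

#' Aggregate a temporal network over time
#'
#' Collapses the snapshot sequence into (i) an edge multiplicity table (how
#' many snapshots contain each node pair) and (ii) each node's temporal
#' degree, the sum of its per-snapshot degrees. The aggregated (union) graph
#' underlies neighborhood selection for the feature embedding and the
#' neighbor set of the temporal k-shell score.
#'
#' @param net a [temporal_network()].
#' @return An object of class `aggregated_view`: list with `pairs` (two-column
#'   matrix of distinct node pairs, `u < v`), `multiplicity` (per-pair snapshot
#'   count, in `1..L`), `temporal_degree` (length-`N` vector) and `adjacency`
#'   (union-graph adjacency list, one integer vector per node).
#' @export
#' @examples
#' net <- toy_chain_network()
#' aggregate_network(net)$temporal_degree
aggregate_network <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  n <- net$n_nodes
  all_u <- unlist(lapply(net$snapshots, function(e) e[, 1L]))
  all_v <- unlist(lapply(net$snapshots, function(e) e[, 2L]))
  if (length(all_u) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("u", "v")))
    mult <- integer(0)
  } else {
    key <- (as.double(all_u) - 1) * n + as.double(all_v)
    tab <- table(key)
    ukey <- as.double(names(tab))
    pairs <- matrix(c(as.integer((ukey - 1) %/% n) + 1L,
                      as.integer((ukey - 1) %% n) + 1L),
                    ncol = 2L, dimnames = list(NULL, c("u", "v")))
    mult <- as.integer(tab)
  }
  tdeg <- integer(n)
  if (nrow(pairs) > 0L) {
    inc <- tabulate(c(rep(pairs[, 1L], mult), rep(pairs[, 2L], mult)), n)
    tdeg <- inc
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(pairs) > 0L) {
    adj <- split(c(pairs[, 2L], pairs[, 1L]),
                 factor(c(pairs[, 1L], pairs[, 2L]), levels = seq_len(n)))
    adj <- lapply(adj, function(x) sort(as.integer(x)))
  }
  structure(list(pairs = pairs, multiplicity = mult,
                 temporal_degree = tdeg, adjacency = adj,
                 n_nodes = n),
            class = "aggregated_view")
}

#' Bin a timestamped edge stream into snapshots
#'
#' Divides the observation window `[t_min, t_max]` into `L` equal bins of
#' width `delta = (t_max - t_min) / L` and assigns each contact event to the
#' snapshot covering its timestamp. Bins are half-open `[delta (t-1),
#' delta t)` with the final bin closed so that `t_max` itself lands in
#' snapshot `L`.
#'
#' @param events data frame or matrix with three columns: node, node,
#'   timestamp. Node identifiers may be arbitrary (integers, strings); they
#'   are mapped to internal indices `1..N` in sorted order and the original
#'   labels kept in the result.
#' @param n_snapshots number of snapshots `L`.
#' @param t_min,t_max observation window; defaults to the range of the event
#'   timestamps. Events outside the window are an error.
#' @return A [temporal_network()] with `interval = (t_max - t_min) / L`.
#' @export
#' @examples
#' ev <- data.frame(u = c(1, 2), v = c(2, 3), t = c(0.5, 1.5))
#' bin_edge_stream(ev, n_snapshots = 2, t_min = 0, t_max = 2)
bin_edge_stream <- function(events, n_snapshots, t_min = NULL, t_max = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) stop("empty event list")
  if (ncol(events) < 3L)
    stop("`events` needs three columns: node, node, timestamp")
  L <- as.integer(n_snapshots)
  if (is.na(L) || L < 1L) stop("`n_snapshots` must be >= 1")
  ts <- as.numeric(events[[3L]])
  if (anyNA(ts)) stop("non-numeric timestamp in event stream")
  if (is.null(t_min)) t_min <- min(ts)
  if (is.null(t_max)) t_max <- max(ts)
  if (!(t_min < t_max)) stop("`t_min` must be strictly less than `t_max`")
  bad <- which(ts < t_min | ts > t_max)
  if (length(bad) > 0L)
    stop(sprintf(
      "event %d (%s, %s, t=%g) has timestamp outside [%g, %g]",
      bad[1L], as.character(events[[1L]][bad[1L]]),
      as.character(events[[2L]][bad[1L]]), ts[bad[1L]], t_min, t_max))
  labs <- sort(unique(c(as.character(events[[1L]]),
                        as.character(events[[2L]]))))
  # sort numerically when every label parses as a number
  nums <- suppressWarnings(as.numeric(labs))
  if (!anyNA(nums)) labs <- labs[order(nums)]
  u <- match(as.character(events[[1L]]), labs)
  v <- match(as.character(events[[2L]]), labs)
  delta <- (t_max - t_min) / L
  bin <- pmin(1L + as.integer(floor((ts - t_min) / delta)), L)
  snaps <- lapply(seq_len(L), function(t) {
    sel <- bin == t
    cbind(u[sel], v[sel])
  })
  temporal_network(snaps, n_nodes = length(labs), interval = delta,
                   labels = labs)
}

#' Read a timestamped event file
#'
#' Parses a whitespace-separated edge stream with one `u v t` triple per
#' line; `#`/`%`-prefixed comment lines are skipped and columns beyond the
#' third (e.g. edge weights in KONECT `out.*` files) are ignored.
#'
#' @param path file path.
#' @return Data frame with columns `u`, `v`, `t`, suitable for
#'   [bin_edge_stream()].
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|%)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no events in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L))
    stop("line with fewer than 3 fields in ", path)
  data.frame(u = vapply(fields, `[[`, character(1), 1L),
             v = vapply(fields, `[[`, character(1), 2L),
             t = as.numeric(vapply(fields, `[[`, character(1), 3L)))
}

#' Read / write a temporal network in the snapshot format
#'
#' The snapshot file is plain text: a header line `N L`, then one line
#' `t u v` per edge with snapshot index `t` in `1..L` and node indices in
#' `1..N`. Lines may appear in any order; snapshots are reassembled by
#' index. `write_snapshots()` followed by `read_snapshots()` reproduces the
#' network exactly (up to the unstored `interval` and labels).
#'
#' @param path file path.
#' @param net a [temporal_network()].
#' @return `read_snapshots()` returns a [temporal_network()];
#'   `write_snapshots()` invisibly returns `path`.
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty snapshot file: ", path)
  head_fields <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_fields) != 2L)
    stop("line 1: header must be 'N L'")
  n <- suppressWarnings(as.integer(head_fields[1L]))
  L <- suppressWarnings(as.integer(head_fields[2L]))
  if (anyNA(c(n, L)) || n < 1L || L < 1L)
    stop("line 1: invalid header 'N L'")
  body <- lines[-1L]
  snaps <- rep(list(NULL), L)
  if (length(body) > 0L) {
    fields <- strsplit(trimws(body), "\\s+")
    for (i in seq_along(fields)) {
      f <- suppressWarnings(as.integer(fields[[i]]))
      if (length(f) != 3L || anyNA(f))
        stop(sprintf("line %d: expected 't u v' integers", i + 1L))
      if (f[1L] < 1L || f[1L] > L)
        stop(sprintf("line %d: snapshot index %d outside 1..%d",
                     i + 1L, f[1L], L))
      if (any(f[2:3] < 1L) || any(f[2:3] > n))
        stop(sprintf("line %d: node index outside 1..%d", i + 1L, n))
      fields[[i]] <- f
    }
    m <- do.call(rbind, fields)
    for (t in seq_len(L)) {
      sel <- m[, 1L] == t
      if (any(sel)) snaps[[t]] <- m[sel, 2:3, drop = FALSE]
    }
  }
  temporal_network(snaps, n_nodes = n)
}

#' @rdname read_snapshots
#' @export
write_snapshots <- function(net, path) {
  stopifnot(inherits(net, "temporal_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", net$n_nodes, net$n_snapshots), con)
  for (t in seq_len(net$n_snapshots)) {
    e <- net$snapshots[[t]]
    if (nrow(e) > 0L)
      writeLines(sprintf("%d %d %d", t, e[, 1L], e[, 2L]), con)
  }
  invisible(path)
}

#' Toy four-node temporal chain
#'
#' The minimal worked example used throughout the documentation and tests:
#' four nodes, three snapshots, one edge per snapshot forming a chain that
#' advances one hop per snapshot (`1-2` at `t=1`, `2-3` at `t=2`, `3-4` at
#' `t=3`).
#'
#' @return A [temporal_network()] with `N = 4`, `L = 3`.
#' @export
toy_chain_network <- function() {
  temporal_network(list(cbind(1L, 2L), cbind(2L, 3L), cbind(3L, 4L)),
                   n_nodes = 4L, interval = 1)
}

#' Relabel the nodes of a temporal network
#'
#' Applies a permutation to the node indices; used to check that scores and
#' embeddings are equivariant under relabeling.
#'
#' @param net a [temporal_network()].
#' @param perm integer permutation of `1..N`; node `i` becomes `perm[i]`.
#' @return The relabeled [temporal_network()].
#' @export
permute_nodes <- function(net, perm) {
  stopifnot(inherits(net, "temporal_network"))
  perm <- as.integer(perm)
  if (length(perm) != net$n_nodes || !setequal(perm, seq_len(net$n_nodes)))
    stop("`perm` must be a permutation of 1..N")
  snaps <- lapply(net$snapshots, function(e)
    cbind(perm[e[, 1L]], perm[e[, 2L]]))
  labels <- net$labels
  if (!is.null(labels)) labels[perm] <- net$labels
  temporal_network(snaps, n_nodes = net$n_nodes, interval = net$interval,
                   labels = labels)
}
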