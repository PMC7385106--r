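#' Select a node's temporal neighborhood slots
#'
#' Chooses the `D` nodes whose mutual temporal structure forms a node's
#' feature matrix: the anchor itself in slot 1, then its neighbors in
#' breadth-first layers on the aggregated union graph — nearer layers first
#' (1-hop before 2-hop), within a layer by descending temporal degree, ties
#' by ascending node index — truncated or padded to `D - 1` companions.
#'
#' @param net a [temporal_network()].
#' @param v anchor node.
#' @param D neighborhood size (slot count).
#' @param agg optional precomputed [aggregate_network()] view.
#' @return Integer vector of length `D`; absent slots are `NA`.
#' @export
#' @examples
#' select_neighborhood(toy_chain_network(), v = 2, D = 4)  # 2 3 1 4
select_neighborhood <- function(net, v, D, agg = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop("`D` must be >= 1")
  v <- as.integer(v)
  if (is.na(v) || v < 1L || v > net$n_nodes) stop("`v` outside 1..N")
  if (is.null(agg)) agg <- aggregate_network(net)
  tdeg <- agg$temporal_degree
  slots <- v
  visited <- logical(net$n_nodes)
  visited[v] <- TRUE
  frontier <- v
  while (length(slots) < D && length(frontier) > 0L) {
    layer <- unique(unlist(agg$adjacency[frontier], use.names = FALSE))
    layer <- layer[!visited[layer]]
    if (length(layer) == 0L) break
    layer <- layer[order(-tdeg[layer], layer)]
    visited[layer] <- TRUE
    slots <- c(slots, layer)
    frontier <- layer
  }
  length(slots) <- D  # truncate or NA-pad
  slots[seq_len(D)]
}

# Shared per-network quantities for feature construction: snapshot weights
# w_t = alpha^(t - 1), decay-weighted temporal degrees, and the
# decay-weighted co-occurrence of every node pair across snapshots.
precompute_embedding <- function(net, alpha) {
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]")
  n <- net$n_nodes
  L <- net$n_snapshots
  w <- alpha^(seq_len(L) - 1)
  wdeg <- as.numeric(degree_matrix(net) %*% w)
  keys <- unlist(lapply(seq_len(L), function(t) {
    e <- net$snapshots[[t]]
    (as.double(e[, 1L]) - 1) * n + as.double(e[, 2L])
  }))
  wts <- unlist(lapply(seq_len(L), function(t)
    rep(w[t], nrow(net$snapshots[[t]]))))
  if (length(keys) > 0L) {
    agg_w <- rowsum(wts, keys)
    pair_keys <- as.double(rownames(agg_w))
    pair_w <- agg_w[, 1L]
  } else {
    pair_keys <- double(0)
    pair_w <- double(0)
  }
  list(agg = aggregate_network(net), weights = w, wdeg = wdeg,
       pair_keys = pair_keys, pair_w = pair_w, n = n)
}

#' Temporal-neighborhood feature matrix of one node
#'
#' Embeds a node's temporal neighborhood into a `D x D` matrix. With
#' snapshot weights `w_t = alpha^(t - 1)` (the first snapshot has weight 1,
#' later snapshots decay), slot `i` and slot `j` of the
#' [select_neighborhood()] list give the off-diagonal entry
#' `M[i, j] = sum_t w_t * [ (s_i, s_j) in E_t ]`, the decay-weighted
#' co-occurrence of the pair, and the diagonal entry
#' `M[i, i] = sum_t w_t * deg_t(s_i)`, the decay-weighted degree. Rows and
#' columns of padded slots are zero, so the matrix is symmetric and
#' non-negative. Early snapshots dominate because spreading is seeded at
#' time zero: contacts available to the initial infection front determine
#' influence far more than late ones. At `alpha = 1` the entries collapse
#' to raw co-occurrence counts and temporal degrees (plain aggregation).
#'
#' @param net a [temporal_network()].
#' @param v anchor node.
#' @param D feature-matrix side length.
#' @param alpha recency decay in `(0, 1]`; smaller values concentrate the
#'   embedding on late snapshots.
#' @param pre optional shared precomputation (internal use).
#' @return `D x D` numeric matrix.
#' @export
#' @examples
#' feature_matrix(toy_chain_network(), v = 2, D = 2, alpha = 0.5)
feature_matrix <- function(net, v, D, alpha = 0.2, pre = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  if (is.null(pre)) pre <- precompute_embedding(net, alpha)
  slots <- select_neighborhood(net, v, D, agg = pre$agg)
  M <- matrix(0, D, D)
  filled <- which(!is.na(slots))
  for (i in filled) M[i, i] <- pre$wdeg[slots[i]]
  if (length(filled) > 1L) {
    for (a in seq_len(length(filled) - 1L)) {
      i <- filled[a]
      for (b in (a + 1L):length(filled)) {
        j <- filled[b]
        u <- min(slots[i], slots[j])
        uu <- max(slots[i], slots[j])
        key <- (as.double(u) - 1) * pre$n + as.double(uu)
        hit <- match(key, pre$pair_keys)
        if (!is.na(hit)) M[i, j] <- M[j, i] <- pre$pair_w[hit]
      }
    }
  }
  M
}

#' Feature matrices of every node
#'
#' @inheritParams feature_matrix
#' @return Numeric array `N x D x D`.
#' @export
feature_matrices <- function(net, D, alpha = 0.2) {
  pre <- precompute_embedding(net, alpha)
  n <- net$n_nodes
  out <- array(0, dim = c(n, D, D))
  for (v in seq_len(n))
    out[v, , ] <- feature_matrix(net, v, D, alpha, pre = pre)
  out
}

#' Train the MLI influence model on a temporal network
#'
#' The full training pipeline of the machine-learning index: embed every
#' node of the training network into a `D x D` temporal-neighborhood feature
#' matrix ([feature_matrices()]), normalize the matrices by their global
#' maximum, label every node with its mean SIR infected scale at the
#' training infection rate `beta_t` (recovery rate `mu_t`; labels are
#' divided by `N` and z-scored before optimization — both affine and hence
#' rank-neutral, inverted again at scoring time), and fit the convolutional
#' regressor by seeded mini-batch Adam. The trained model can
#' score any other temporal network with [mli_score()].
#'
#' @param net training [temporal_network()] (typically a synthetic temporal
#'   scale-free network from [generate_temporal_ba()]).
#' @param D feature-matrix side length (divisible by 4).
#' @param alpha recency decay of the embedding, in `(0, 1]`.
#' @param beta_t training infection rate.
#' @param mu_t training recovery rate.
#' @param label_runs SIR realizations averaged per node label.
#' @param epochs,batch_size,lr training hyperparameters (see
#'   [train_regressor()]).
#' @param seed master seed; labels, initialization and shuffling all derive
#'   their streams from it.
#' @return An object of class `mli_model`: the trained regressor, the
#'   training configuration and the per-epoch loss history.
#' @export
#' @examples
#' \donttest{
#' net <- generate_temporal_ba(100, 1, 10, seed = 5)
#' model <- mli_train(net, label_runs = 20, epochs = 30, seed = 5)
#' head(mli_score(model, net))
#' }
mli_train <- function(net, D = 8L, alpha = 0.2, beta_t = 0.1, mu_t = 1,
                      label_runs = 100L, epochs = 200L, batch_size = 32L,
                      lr = 1e-3, seed = 1L) {
  stopifnot(inherits(net, "temporal_network"))
  if (beta_t < 0 || beta_t > 1) stop("`beta_t` must be in [0, 1]")
  feats <- feature_matrices(net, D, alpha)
  mx <- max(feats)
  if (mx > 0) feats <- feats / mx
  labels <- spreading_influence(net, beta = beta_t, mu = mu_t,
                                runs = label_runs,
                                seed = derive_seed(seed, 1L),
                                normalize = TRUE)
  # z-score the regression targets for optimization conditioning (the /N
  # labels live on a scale of ~1/N); the affine map is rank-preserving and
  # is inverted at scoring time
  label_center <- mean(labels)
  label_scale <- stats::sd(labels)
  if (!is.finite(label_scale) || label_scale == 0) label_scale <- 1
  y <- (labels - label_center) / label_scale
  reg <- build_regressor(D, seed = derive_seed(seed, 2L))
  fit <- train_regressor(reg, feats, y, epochs = epochs,
                         batch_size = batch_size, lr = lr,
                         seed = derive_seed(seed, 3L))
  structure(
    list(regressor = fit$model, history = fit$history,
         label_center = label_center, label_scale = label_scale,
         config = list(D = as.integer(D), alpha = alpha, beta_t = beta_t,
                       mu_t = mu_t, label_runs = as.integer(label_runs),
                       epochs = as.integer(epochs),
                       batch_size = as.integer(batch_size), lr = lr,
                       seed = as.integer(seed))),
    class = "mli_model")
}

#' @export
print.mli_model <- function(x, ...) {
  cat(sprintf(
    "mli_model: D=%d, alpha=%g, beta_t=%g, final training MSE %.3g\n",
    x$config$D, x$config$alpha, x$config$beta_t,
    x$history[length(x$history)]))
  invisible(x)
}

#' Score the nodes of a temporal network with a trained MLI model
#'
#' Embeds every node of `net` with the model's `D` and `alpha`, normalizes
#' the feature matrices by the network's own global maximum (so networks of
#' different density share the input scale), and runs one forward pass per
#' node.
#'
#' @param model a trained [mli_train()] object.
#' @param net a [temporal_network()] to score.
#' @return Numeric vector of length `N` of influence scores.
#' @export
mli_score <- function(model, net) {
  stopifnot(inherits(model, "mli_model"), inherits(net, "temporal_network"))
  feats <- feature_matrices(net, model$config$D, model$config$alpha)
  mx <- max(feats)
  if (mx > 0) feats <- feats / mx
  predict_regressor(model$regressor, feats) * model$label_scale +
    model$label_center
}

#' Rank nodes by score
#'
#' @param scores numeric vector of per-node scores.
#' @return Integer vector of node indices in ranking order: descending
#'   score, ties broken by ascending node index.
#' @export
#' @examples
#' rank_nodes(c(0.3, 0.9, 0.9, 0.1))  # 2 3 1 4
rank_nodes <- function(scores) {
  order(-scores, seq_along(scores))
}

#' Save / load a trained MLI model
#'
#' Serializes the weights together with the architecture record and
#' training configuration; loading validates the class and the declared
#' feature size, and [mli_score()] then scores only with the matching `D`.
#'
#' @param model a trained [mli_train()] object.
#' @param path file path.
#' @return `load_mli_model()` returns the `mli_model`; `save_mli_model()`
#'   invisibly returns `path`.
#' @export
save_mli_model <- function(model, path) {
  stopifnot(inherits(model, "mli_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mli_model
#' @export
load_mli_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mli_model"))
    stop("file does not contain an mli_model")
  if (!identical(model$config$D, model$regressor$spec$D))
    stop("model file is inconsistent: config D != regressor D")
  model
}
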