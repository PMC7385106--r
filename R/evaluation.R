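#' Kendall rank correlation between two score vectors
#'
#' Tie-corrected Kendall tau (tau-b) between paired per-node scores, the
#' agreement measure between a ranking method and simulated influence.
#' Returns `NA` when either vector is constant (tau is then undefined).
#'
#' @param x,y numeric score vectors over the same node set.
#' @return Tau in `[-1, 1]`, or `NA` for a constant input.
#' @export
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 2, 4, 3))  # 2/3
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 nodes")
  suppressWarnings(stats::cor(x, y, method = "kendall"))
}

#' Hitting rate of the true top-k nodes
#'
#' `HR = |C intersect R| / |R|`, where `C` and `R` are the top
#' `k = ceiling(fraction * N)` nodes of the predicted and the true score
#' vector (descending score, ties broken by ascending node index).
#'
#' @param pred predicted scores.
#' @param truth ground-truth scores (e.g. [spreading_influence()]).
#' @param fraction top fraction in `(0, 1]`; 0.1 gives the top-10% rate.
#' @return Hitting rate in `[0, 1]`.
#' @export
#' @examples
#' hitting_rate(c(4, 3, 2, 1), c(4, 3, 1, 2), fraction = 0.5)  # 1
hitting_rate <- function(pred, truth, fraction = 0.1) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length")
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  k <- as.integer(ceiling(fraction * length(pred)))
  top_c <- rank_nodes(pred)[seq_len(k)]
  top_r <- rank_nodes(truth)[seq_len(k)]
  length(intersect(top_c, top_r)) / k
}

#' Kendall-tau grid over infection and training infection rates
#'
#' For every training rate `beta_t`, trains one MLI model (on `train_net`)
#' and scores `net`; for every evaluation rate `beta`, computes the SIR
#' ground truth once (shared across all rows) and records the tau between
#' the model's scores and the truth. This is the heat-map protocol for
#' checking how sensitive the method is to the training infection rate.
#' Cells where tau is undefined (e.g. `beta = 0`, all-tied truth) are `NA`.
#'
#' @param net test [temporal_network()].
#' @param betas evaluation infection rates.
#' @param beta_ts training infection rates.
#' @param train_net training network; defaults to `net` itself.
#' @param truth_runs SIR realizations per node for the ground truth.
#' @param seed master seed.
#' @param ... further arguments passed to [mli_train()] (e.g. `D`, `alpha`,
#'   `label_runs`, `epochs`).
#' @return Numeric matrix of tau values, rows indexed by `beta_t`, columns
#'   by `beta`.
#' @export
beta_grid <- function(net, betas, beta_ts, train_net = net,
                      truth_runs = 1000L, seed = 1L, ...) {
  stopifnot(inherits(net, "temporal_network"))
  if (any(betas < 0 | betas > 1) || any(beta_ts < 0 | beta_ts > 1))
    stop("rates must be in [0, 1]")
  truths <- lapply(seq_along(betas), function(i)
    spreading_influence(net, beta = betas[i], mu = 1, runs = truth_runs,
                        seed = derive_seed(seed, 1000L + i)))
  tau <- matrix(NA_real_, length(beta_ts), length(betas),
                dimnames = list(beta_t = format(beta_ts),
                                beta = format(betas)))
  for (r in seq_along(beta_ts)) {
    model <- mli_train(train_net, beta_t = beta_ts[r],
                       seed = derive_seed(seed, r), ...)
    scores <- mli_score(model, net)
    for (cc in seq_along(betas))
      tau[r, cc] <- kendall_tau(scores, truths[[cc]])
  }
  tau
}

#' Compare ranking methods against SIR ground truth
#'
#' For each infection rate `beta` and each method, computes Kendall tau and
#' the top-`fraction` hitting rate against the same cached SIR ground truth
#' (mean infected scale over `truth_runs` realizations at rate `beta`,
#' `mu = 1`). Method scores that do not depend on `beta` (tc, tb, tk, tdd,
#' mli) are computed once; the dynamics-sensitive centrality is refreshed
#' with the current `beta`.
#'
#' @param net test [temporal_network()].
#' @param betas evaluation infection rates.
#' @param methods subset of `c("mli", "tc", "tb", "tk", "tdd", "tdc")`.
#' @param model trained [mli_train()] model; required when `"mli"` is among
#'   the methods.
#' @param truth_runs SIR realizations per node for the ground truth.
#' @param fraction top fraction for the hitting rate.
#' @param seed master seed for the ground-truth simulations.
#' @param network_id label recorded in the report.
#' @return Data frame with one row per (beta, method): columns `network`,
#'   `method`, `beta`, `beta_t` (the model's training rate for mli, `NA`
#'   otherwise), `tau`, `hr`, `k`, `truth_runs`.
#' @export
compare_methods <- function(net, betas = seq(0.01, 0.1, by = 0.01),
                            methods = c("mli", "tc", "tb", "tk", "tdd", "tdc"),
                            model = NULL, truth_runs = 1000L, fraction = 0.1,
                            seed = 1L, network_id = "net") {
  stopifnot(inherits(net, "temporal_network"))
  known <- c("mli", "tc", "tb", "tk", "tdd", "tdc")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L)
    stop("unknown method tag: ", paste(bad, collapse = ", "))
  if ("mli" %in% methods && is.null(model))
    stop("method 'mli' needs a trained `model`")
  static <- setdiff(methods, "tdc")
  static_scores <- lapply(static, function(m)
    centrality_scores(net, m, model = model))
  names(static_scores) <- static
  k <- as.integer(ceiling(fraction * net$n_nodes))
  rows <- vector("list", length(betas) * length(methods))
  r <- 0L
  for (i in seq_along(betas)) {
    beta <- betas[i]
    truth <- spreading_influence(net, beta = beta, mu = 1, runs = truth_runs,
                                 seed = derive_seed(seed, 1000L + i))
    for (m in methods) {
      scores <- if (m == "tdc")
        temporal_dynamics_sensitive(net, beta = beta, mu = 1)
      else static_scores[[m]]
      r <- r + 1L
      rows[[r]] <- data.frame(
        network = network_id, method = m, beta = beta,
        beta_t = if (m == "mli") model$config$beta_t else NA_real_,
        tau = kendall_tau(scores, truth),
        hr = hitting_rate(scores, truth, fraction),
        k = k, truth_runs = as.integer(truth_runs))
    }
  }
  do.call(rbind, rows)
}
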