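# mlinet

Identifying influential spreaders (super-spreaders) in **temporal
networks**. A temporal network is a sequence of `L` undirected snapshot
graphs `G_1, ..., G_L` on `N` nodes; the influence of a node `v` is its
*infected scale* `N_v(L)` — the expected number of ever-infected nodes when
a discrete-time SIR epidemic (infection rate `β` per contact per snapshot,
recovery rate `μ = 1`) starts at `v`. `mlinet` is for researchers in
network epidemiology and temporal network analysis who need to rank nodes
by spreading ability without simulating every candidate seed.

The core method, **MLI** (machine-learning index), turns ranking into
regression:

1. each node's temporal neighborhood is embedded into a `D × D` feature
   matrix over its `D` nearest neighbors (1-hop before 2-hop, higher
   temporal degree first): off-diagonals hold decay-weighted edge
   co-occurrence `Σ_t α^(t−1) · 1[(s_i,s_j) ∈ E_t]`, the diagonal holds
   decay-weighted degrees;
2. a small convolutional regressor (conv 1→16, 5×5, pad 2 → 2×2 max-pool →
   conv 16→32 → 2×2 max-pool → fully connected `32·(D/4)² → 1`, squared
   loss) is trained on SIR infected scales simulated at a training rate
   `β_t` on a cheap synthetic network;
3. the trained model scores the nodes of any other temporal network in one
   forward pass per node.

Defaults follow the original setting: `D = 8`, `α = 0.2`, `β_t = 0.1`.

Also included: the temporal SIR simulator defining ground truth, five
benchmark temporal centralities — closeness (TC) and betweenness (TB) on
foremost time-respecting paths, k-shell (TK), degree deviation (TDD),
dynamics-sensitive centrality (TDC) — a seeded temporal scale-free
(snapshot-wise Barabási–Albert) generator, KONECT-style edge-stream I/O,
and a Kendall-tau / top-k hitting-rate evaluation protocol. See the
vignette `vignettes/temporal-spreaders.Rmd` for the model details and
design choices.

## Worked example

```r
library(mlinet)

# train on one synthetic temporal scale-free network...
train_net <- generate_temporal_ba(300, m = 1, n_snapshots = 10, seed = 1101)
model <- mli_train(train_net, D = 8, alpha = 0.2, beta_t = 0.1,
                   label_runs = 100, epochs = 200, seed = 1)

# ...and rank the nodes of an independent one
test_net <- generate_temporal_ba(300, m = 1, n_snapshots = 10, seed = 2202)
scores <- mli_score(model, test_net)
head(rank_nodes(scores))

# how good is the ranking? compare with SIR ground truth
truth <- spreading_influence(test_net, beta = 0.1, runs = 500, seed = 3303)
kendall_tau(scores, truth)
hitting_rate(scores, truth, fraction = 0.1)
kendall_tau(temporal_degree_deviation(test_net), truth)  # baseline
```

which prints (exact values depend on the seeds):

```
> head(rank_nodes(scores))
[1]  1  2  8  3 11 25
> kendall_tau(scores, truth)
[1] 0.4562146
> hitting_rate(scores, truth, fraction = 0.1)
[1] 0.6666667
> kendall_tau(temporal_degree_deviation(test_net), truth)
[1] 0.2936091
```

The low node indices at the top are expected: snapshot-wise BA generation
with shared arrival order makes early nodes persistent hubs. MLI's rank
correlation with the simulated infected scales (0.46) clearly exceeds the
temporal-degree-deviation baseline (0.29), and 20 of the true top-30
spreaders appear in MLI's top 30.

A thin CLI wraps the same functions, e.g.
`Rscript exec/tns generate --n 500 --m 1 --snapshots 30 --seed 1 --out net.tsv`.

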