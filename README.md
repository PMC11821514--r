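# cargohub

Selective autophagy starts on the cargo itself: autophagy receptors on the
cargo surface recruit the scaffold of the initiation machinery (Atg11 in
yeast, FIP200 in mammals), and many individually weak receptor–scaffold
contacts act together — avidity — to nucleate phase-separated "initiation
hubs" where phagophore formation begins. `cargohub` packages the
computational side of this biology for people who simulate or quantify it:

* **`simcore` / `simmetrics`** — a Brownian-dynamics model of
  receptor–scaffold subcomplex particles around a static cargo. Particles
  interact through a truncated-shifted Morse well; the cargo-surface well
  depth for particle *i* is avidity-scaled,
  `eps_AC * (1 + beta * min(n_i, n_max))`, with `n_i` its current
  neighbour count. Cluster detection (contact-graph components), an
  angular coefficient-of-variation of the cargo coating, and a classifier
  mapping each run to `OFF_CARGO_CLUSTERS`, `ON_CARGO_HUBS`, or
  `UNIFORM_COATING`. Three shipped presets (`very_low`, `low`, `high`
  cargo affinity) reproduce the three regimes.
* **`imaging`** — ring coefficient-of-variation clustering metric
  (s.d./mean of intensity sampled around a structure), line profiles,
  sub-pixel peak positions, and ER-proximity statistics for three-channel
  images.
* **`frap`** — FRAP double normalization
  `N(t) = [(I−B)/(T−B)] / pre-bleach mean` and single-exponential recovery
  fitting with mobile fraction `A/(1−N0)`.
* **`flowkeima`** — mKeima mitophagy flux: per-event acidic/neutral
  ratios, per-sample arithmetic means, and the min–max reference scaling
  `x_sc = (x − x̄_low)/(x̄_high − x̄_low) × (100 − 2) + 2`.
* **`proxprot`** — label-free proximity-proteomics pipeline: quality
  filters (≥2 peptides, raw ≥ 1000, quantified in ≥2 replicates of a
  group), pairwise-ratio mode normalization, Gaussian imputation
  (N(9.96, 0.75²) on log2), signal-over-control, pooled t-tests with
  Benjamini–Hochberg correction, strict target selection
  (log2 ratio > 1, adj. p < 0.01) and a knockdown contrast.
* **`synthgen`** — seeded generators (ring images, FRAP traces, flow
  events, quantification tables) with ground truth attached, so the whole
  package builds and tests without any data download.

## Worked example

Run the low-affinity preset — weak monomeric cargo binding, avidity gain
switched on — and classify the outcome:

```r
library(cargohub)
cfg <- sim_preset("low", seed = 1)   # 250 particles, 2e5 steps, ~10 s
tr  <- run_simulation(cfg)
s   <- summarize_regime(tr)
classify_regime(s)
```

```
bound_fraction            0.112
clustered_fraction        0.946
on_cargo_cluster_fraction 0.776
largest_cluster_size      62.9
angular_cov               0.82
classify: ON_CARGO_HUBS
```

95% of particles have condensed, and 78% of that condensed mass sits in
clusters touching the cargo: avidity has anchored the condensates to the
surface — initiation hubs. With `sim_preset("very_low")` the same
condensates form but drift free of the cargo; with `sim_preset("high")`
particles coat the cargo evenly without condensing.

A FRAP trace with known truth, normalized and fitted:

```r
g   <- gen_frap_trace(f = 0.6, k = 0.1, noise = 0.02, seed = 42)
nn  <- double_normalize(g$trace)
fit_recovery(nn$times, nn$N, nn$bleach_index)
#> <recovery_fit> mobile fraction 0.582, k = 0.09308 /s (t1/2 = 7.45 s)
```

The planted mobile fraction 0.6 and rate 0.1/s are recovered within the
noise.

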