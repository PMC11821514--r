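# Independent oracles and small constructors shared across test files.

# particle_state constructor for hand-built configurations
make_state <- function(positions, cargo_bound = rep(FALSE, nrow(positions)),
                       time = 0) {
  structure(list(time = time, positions = positions,
                 neighbour_count = rep(0L, nrow(positions)),
                 cargo_bound = cargo_bound),
            class = "particle_state")
}

# brute-force connected components on the full distance matrix (igraph)
oracle_clusters <- function(pos, r_contact, min_size) {
  n <- nrow(pos)
  adj <- as.matrix(stats::dist(pos)) <= r_contact
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  sets <- split(seq_len(n), memb)
  Filter(function(s) length(s) >= min_size, sets)
}

# cluster assignment -> list of member sets (ignoring noise)
cluster_sets <- function(cl) {
  labs <- setdiff(unique(cl$labels), 0L)
  lapply(sort(labs), function(l) which(cl$labels == l))
}

# canonical form for comparing partitions regardless of label order
canon_sets <- function(sets) {
  sets <- lapply(unname(sets), sort)
  sets[order(vapply(sets, min, integer(1)))]
}

# Analytic expected recall of the planted-enrichment pipeline: noncentral-t
# power at the self-consistent BH step-up threshold (nulls contribute
# negligibly below it).
oracle_bh_recall <- function(effect, sigma, n_rep, n_proteins, n_enriched,
                             alpha = 0.01) {
  ncp <- effect / (sigma * sqrt(2 / n_rep))
  df <- 2 * (n_rep - 1)
  R <- 1
  for (i in 1:200) {
    tau <- alpha * (n_enriched * R) / n_proteins
    tc <- stats::qt(1 - tau / 2, df)
    R <- 1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
  }
  R
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# pooled-variance two-sided t-test p value, closed form
oracle_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), na + nb - 2)
}
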