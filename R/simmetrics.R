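#' Neighbour counts at a given radius
#'
#' Number of other particles within distance `r_nb` of each particle
#' (symmetric: i counts j iff j counts i).
#'
#' @param state A `particle_state` or positions matrix.
#' @param r_nb Counting radius (> 0).
#' @return Integer vector of counts.
#' @export
neighbour_counts <- function(state, r_nb) {
  if (r_nb <= 0) stop("r_nb must be > 0")
  pos <- if (is.matrix(state)) state else state$positions
  n <- nrow(pos)
  if (n == 1L) return(0L)
  d <- as.matrix(stats::dist(pos))
  as.integer(colSums(d <= r_nb) - 1L)
}

#' Contact-graph cluster detection
#'
#' Particles are connected when their distance is at most `r_contact`;
#' clusters are the connected components, found by union--find over
#' candidate pairs from a spatial cell binning. Components smaller than
#' `min_size` are relabelled as noise (label 0). Cluster labels are assigned
#' in order of each cluster's lowest member index.
#'
#' @param state A `particle_state` or positions matrix.
#' @param r_contact Contact distance (> 0).
#' @param min_size Minimum cluster size (>= 2).
#' @param cargo_bound Optional logical vector marking cargo-bound particles
#'   (taken from `state` if present); a cluster is "on cargo" when at least
#'   one member is bound.
#' @return A `cluster_assignment`: list with `labels` (0 = noise), `sizes`
#'   (named by label), and `on_cargo` (named logical, present when bound
#'   flags are available).
#' @export
find_clusters <- function(state, r_contact, min_size = 3L,
                          cargo_bound = NULL) {
  if (r_contact <= 0) stop("r_contact must be > 0")
  if (min_size < 2) stop("min_size must be >= 2")
  pos <- if (is.matrix(state)) state else state$positions
  if (is.null(cargo_bound) && !is.matrix(state)) cargo_bound <- state$cargo_bound
  n <- nrow(pos)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # candidate pairs from cell binning (cells of edge r_contact)
  cell <- floor(sweep(pos, 2, apply(pos, 2, min)) / r_contact)
  key <- apply(cell, 1, paste, collapse = ",")
  bins <- split(seq_len(n), key)
  coords <- lapply(strsplit(names(bins), ","), as.numeric)
  offsets <- as.matrix(expand.grid(rep(list(-1:1), ncol(pos))))
  for (b in seq_along(bins)) {
    mine <- bins[[b]]
    for (k in seq_len(nrow(offsets))) {
      nb_key <- paste(coords[[b]] + offsets[k, ], collapse = ",")
      other <- bins[[nb_key]]
      if (is.null(other)) next
      for (i in mine) for (j in other) {
        if (j <= i) next
        if (sum((pos[i, ] - pos[j, ])^2) <= r_contact^2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes_all <- table(roots)
  keep <- as.integer(names(sizes_all))[sizes_all >= min_size]
  labels <- integer(n)
  if (length(keep)) {
    keep <- sort(keep)  # lowest member index first
    for (k in seq_along(keep)) labels[roots == keep[k]] <- k
  }
  sizes <- if (length(keep)) {
    s <- as.integer(sizes_all[as.character(keep)])
    names(s) <- seq_along(keep)
    s
  } else integer(0)
  on_cargo <- if (!is.null(cargo_bound) && length(keep)) {
    oc <- vapply(seq_along(keep),
                 function(k) any(cargo_bound[labels == k]), logical(1))
    names(oc) <- seq_along(keep)
    oc
  } else NULL
  structure(list(labels = labels, sizes = sizes, on_cargo = on_cargo),
            class = "cluster_assignment")
}

#' Angular coefficient of variation of the cargo coating
#'
#' Cargo-bound particles are binned by angle around the cargo centre (2D) or
#' into equal-area surface patches (3D: equal-width bands in z times equal
#' azimuthal sectors), and the sample standard deviation (n-1 denominator) of
#' the bin counts divided by their mean is returned. This mirrors the
#' imaging clustering metric ([ring_cov()]): high values mean focal coating,
#' 0 means a perfectly even coat.
#'
#' @param state A `particle_state` (must carry `cargo_bound` flags).
#' @param config The `sim_config` of the run (for the cargo centre).
#' @param n_bins Number of bins (>= 4). In 3D the actual patch count is the
#'   nearest product of band and sector counts.
#' @return Dimensionless CoV of the bin counts.
#' @export
angular_cov <- function(state, config, n_bins = 12L) {
  if (n_bins < 4) stop("n_bins must be >= 4")
  bound <- state$positions[state$cargo_bound, , drop = FALSE]
  if (nrow(bound) == 0) stop("no coating to quantify: no cargo-bound particles")
  rel <- sweep(bound, 2, config$cargo_center)
  if (config$dim == 2L) {
    ang <- atan2(rel[, 2], rel[, 1])  # (-pi, pi]
    bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins), n_bins - 1)
    counts <- tabulate(bin + 1L, nbins = n_bins)
  } else {
    n_band <- max(2L, round(sqrt(n_bins / 2)))
    n_sect <- max(2L, round(n_bins / n_band))
    r <- sqrt(rowSums(rel^2))
    z <- rel[, 3] / r                      # area element uniform in z
    band <- pmin(floor((z + 1) / 2 * n_band), n_band - 1)
    phi <- atan2(rel[, 2], rel[, 1])
    sect <- pmin(floor((phi + pi) / (2 * pi) * n_sect), n_sect - 1)
    counts <- tabulate(band * n_sect + sect + 1L, nbins = n_band * n_sect)
  }
  stats::sd(counts) / mean(counts)
}

#' Summarize a trajectory over its steady-state tail
#'
#' Averages the regime metrics over the final `tail_fraction` of frames:
#' fraction of particles cargo-bound, fraction in clusters of at least
#' `min_size`, fraction of clustered particles whose cluster touches the
#' cargo, largest cluster size, and angular CoV of the coating (frames with
#' no bound particle contribute `NA` to the CoV and are skipped in its mean).
#'
#' @param trajectory A `trajectory` (>= 2 frames).
#' @param r_contact Contact distance for clustering (default `1.15 * r0`,
#'   the first coordination shell; at moderate gas densities the interaction
#'   cutoff `r_cut` would connect unbound neighbours).
#' @param r_nb Unused placeholder for symmetry with the simulator config.
#' @param min_size Minimum cluster size.
#' @param n_bins Angular bins for the CoV.
#' @param tail_fraction Fraction of final frames to average over.
#' @return A `regime_summary` list: `bound_fraction`, `clustered_fraction`,
#'   `on_cargo_cluster_fraction`, `largest_cluster_size`, `angular_cov`,
#'   plus `n_particles` and the parameters used.
#' @export
summarize_regime <- function(trajectory, r_contact = NULL, r_nb = NULL,
                             min_size = 3L, n_bins = 12L,
                             tail_fraction = 0.25) {
  stopifnot(inherits(trajectory, "trajectory"),
            length(trajectory$frames) >= 2)
  cfg <- trajectory$config
  if (is.null(r_contact)) r_contact <- 1.15 * cfg$r0
  nf <- length(trajectory$frames)
  first <- max(1L, nf - ceiling(tail_fraction * nf) + 1L)
  frames <- trajectory$frames[first:nf]
  n <- cfg$n_particles
  per <- lapply(frames, function(f) {
    cl <- find_clusters(f, r_contact, min_size)
    clustered <- sum(cl$sizes)
    on_cargo_members <- if (clustered > 0)
      sum(cl$sizes[names(which(cl$on_cargo))]) else 0L
    c(bound = mean(f$cargo_bound),
      clustered = clustered / n,
      on_cargo = if (clustered > 0) on_cargo_members / clustered else NA_real_,
      largest = if (length(cl$sizes)) max(cl$sizes) else 0,
      cov = if (any(f$cargo_bound)) angular_cov(f, cfg, n_bins) else NA_real_)
  })
  m <- do.call(rbind, per)
  structure(list(bound_fraction = mean(m[, "bound"]),
                 clustered_fraction = mean(m[, "clustered"]),
                 on_cargo_cluster_fraction =
                   if (all(is.na(m[, "on_cargo"]))) 0
                   else mean(m[, "on_cargo"], na.rm = TRUE),
                 largest_cluster_size = mean(m[, "largest"]),
                 angular_cov =
                   if (all(is.na(m[, "cov"]))) NA_real_
                   else mean(m[, "cov"], na.rm = TRUE),
                 n_particles = n,
                 params = list(r_contact = r_contact, min_size = min_size,
                               n_bins = n_bins,
                               tail_fraction = tail_fraction)),
            class = "regime_summary")
}

#' Default regime-classification cutoffs
#'
#' Calibrated artifact constants, exposed so they can be overridden:
#' `clustered_hi` (a regime counts as condensed when at least this fraction
#' of particles sit in clusters), `on_cargo_hi`/`on_cargo_lo` (split of
#' condensed regimes into on- vs off-cargo), `bound_hi`, `largest_frac_max`
#' and `cov_max` (uniform-coating rule: many bound particles, no large
#' cluster, even angular distribution).
#'
#' @return Named list of cutoffs.
#' @export
regime_thresholds <- function() {
  list(clustered_hi = 0.4, on_cargo_hi = 0.5, on_cargo_lo = 0.5,
       bound_hi = 0.05, largest_frac_max = 0.08, cov_max = 1.0)
}

#' Classify the cargo-binding regime
#'
#' Maps a [summarize_regime()] summary to one of the three qualitative
#' outcomes: `OFF_CARGO_CLUSTERS` (condensates away from the cargo, very low
#' affinity), `ON_CARGO_HUBS` (condensates stabilized on the cargo surface,
#' low affinity + avidity), `UNIFORM_COATING` (strong monomeric binding,
#' high affinity). A summary matching no rule returns `UNCLASSIFIED`.
#'
#' @param summary A `regime_summary`.
#' @param thresholds Named cutoffs; see [regime_thresholds()].
#' @return One of `"OFF_CARGO_CLUSTERS"`, `"ON_CARGO_HUBS"`,
#'   `"UNIFORM_COATING"`, `"UNCLASSIFIED"`.
#' @export
classify_regime <- function(summary, thresholds = regime_thresholds()) {
  th <- utils::modifyList(regime_thresholds(), as.list(thresholds))
  s <- summary
  if (s$clustered_fraction >= th$clustered_hi) {
    if (s$on_cargo_cluster_fraction >= th$on_cargo_hi) return("ON_CARGO_HUBS")
    if (s$on_cargo_cluster_fraction <= th$on_cargo_lo)
      return("OFF_CARGO_CLUSTERS")
    return("UNCLASSIFIED")
  }
  if (s$bound_fraction >= th$bound_hi &&
      s$largest_cluster_size <= th$largest_frac_max * s$n_particles &&
      !is.na(s$angular_cov) && s$angular_cov <= th$cov_max)
    return("UNIFORM_COATING")
  "UNCLASSIFIED"
}
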