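#' Simulation configuration
#'
#' Builds and validates the configuration of the Brownian-dynamics model of
#' receptor--scaffold subcomplex particles around a single static cargo body.
#' Units are reduced: the particle diameter is 1 length unit, thermal energy
#' kT is 1 energy unit, and the unit of time is (diameter^2)/D.
#'
#' Subcomplex particles attract each other through a truncated-shifted Morse
#' well of depth `eps_AA`. Coupling of a particle to the cargo surface uses
#' the same well form on the surface gap, with a depth that grows with the
#' particle's current neighbour count (avidity):
#' `eps_AC * (1 + avidity_gain * min(n_i, avidity_cap))`.
#'
#' @param dim Spatial dimension, 2 (default) or 3.
#' @param box_size Edge length of the cubic simulation box `[0, box_size]^dim`.
#' @param n_particles Number of subcomplex particles.
#' @param particle_radius Particle radius (default 0.5, i.e. diameter 1).
#' @param cargo_radius Radius of the static cargo disc/sphere.
#' @param cargo_center Cargo centre; defaults to the box centre.
#' @param eps_AA Subcomplex--subcomplex well depth (kT).
#' @param eps_AC Base (monomeric) cargo--subcomplex well depth (kT).
#' @param avidity_gain Per-neighbour multiplier beta of the cargo coupling.
#' @param avidity_cap Neighbour count at which the avidity boost saturates.
#' @param r0 Pair-potential minimum distance (default 1, touching particles).
#' @param a Morse steepness (inverse length) of the pair interaction.
#' @param a_cargo Morse steepness of the cargo-surface well (default `a/2`:
#'   a broader, softer well for the extended cargo surface).
#' @param r_cut Interaction cutoff; energy and force are exactly 0 beyond it.
#' @param r_nb Neighbour-counting radius used for the avidity boost
#'   (default `r_cut`).
#' @param r_bind Surface gap below which a particle counts as cargo-bound.
#' @param D Diffusion coefficient (reduced units, default 1).
#' @param dt Time step.
#' @param n_steps Number of integration steps.
#' @param save_every Save a frame every this many steps.
#' @param seed Integer RNG seed.
#' @param boundary Boundary condition; only `"reflecting"` is supported.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [run_simulation()], [sim_preset()]
#' @export
sim_config <- function(dim = 2L, box_size = 50, n_particles = 400L,
                       particle_radius = 0.5, cargo_radius = 15,
                       cargo_center = NULL,
                       eps_AA = 0, eps_AC = 0, avidity_gain = 0,
                       avidity_cap = 6L, r0 = 1, a = 6, a_cargo = a / 2,
                       r_cut = 1.6,
                       r_nb = r_cut, r_bind = 1, D = 1, dt = 4e-4,
                       n_steps = 10000L, save_every = 1000L, seed = 1L,
                       boundary = "reflecting") {
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3")
  if (is.null(cargo_center)) cargo_center <- rep(box_size / 2, dim)
  stopifnot(length(cargo_center) == dim)
  if (dt <= 0) stop("dt must be > 0")
  if (eps_AA < 0 || eps_AC < 0 || avidity_gain < 0)
    stop("eps_AA, eps_AC and avidity_gain must be >= 0")
  if (avidity_cap < 0) stop("avidity_cap must be >= 0")
  if (!(particle_radius > 0 && particle_radius < cargo_radius))
    stop("need 0 < particle_radius < cargo_radius")
  if (!(r_cut >= r0 && r0 > 0)) stop("need r_cut >= r0 > 0")
  if (any(cargo_center - cargo_radius < 0) ||
      any(cargo_center + cargo_radius > box_size))
    stop("cargo body must lie fully inside the box")
  if (!identical(boundary, "reflecting"))
    stop("only reflecting boundaries are supported")
  cfg <- list(dim = dim, box_size = box_size,
              n_particles = as.integer(n_particles),
              particle_radius = particle_radius, cargo_radius = cargo_radius,
              cargo_center = as.numeric(cargo_center),
              eps_AA = eps_AA, eps_AC = eps_AC, avidity_gain = avidity_gain,
              avidity_cap = as.integer(avidity_cap), r0 = r0, a = a,
              a_cargo = a_cargo,
              r_cut = r_cut, r_nb = r_nb, r_bind = r_bind, D = D, dt = dt,
              n_steps = as.integer(n_steps),
              save_every = as.integer(save_every), seed = as.integer(seed),
              boundary = boundary)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the fields of [sim_config()] one to one; missing fields
#' take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Truncated-shifted Morse pair potential
#'
#' `U(r) = eps * ((1 - exp(-a (r - r0)))^2 - 1)`, shifted so that the energy
#' is continuous (zero) at `r_cut`, with `U = 0` and zero force for
#' `r >= r_cut`. The returned force is the negative radial derivative of the
#' energy; positive values are repulsive.
#'
#' @param r Distances (> 0); vectorized.
#' @param eps Well depth (kT).
#' @param r0 Location of the minimum.
#' @param a Steepness (inverse length).
#' @param r_cut Cutoff distance.
#' @return A list with numeric vectors `energy` and `force`.
#' @export
pair_potential <- function(r, eps, r0, a, r_cut) {
  if (any(r <= 0)) stop("r must be > 0")
  out <- cpp_morse(as.numeric(r), eps, r0, a, r_cut)
  n <- length(r)
  list(energy = out[seq_len(n)], force = out[n + seq_len(n)])
}

#' Avidity-scaled cargo coupling depth
#'
#' Effective cargo--subcomplex well depth for a particle with `n_i`
#' neighbours: `eps_AC * (1 + beta * min(n_i, n_max))`. More neighbours mean
#' stronger coupling, saturating at `n_max`.
#'
#' @param n_i Neighbour count(s), non-negative integers; vectorized.
#' @param eps_AC Base monomeric depth (kT).
#' @param beta Per-neighbour gain (dimensionless).
#' @param n_max Saturation cap.
#' @return Effective depth(s) in kT.
#' @export
effective_cargo_depth <- function(n_i, eps_AC, beta, n_max) {
  if (any(n_i < 0) || eps_AC < 0 || beta < 0 || n_max < 0)
    stop("all inputs must be non-negative")
  eps_AC * (1 + beta * pmin(n_i, n_max))
}

#' Forces on all particles
#'
#' Assembles pairwise subcomplex--subcomplex forces plus the avidity-scaled
#' cargo-surface force for each particle (using its current neighbour count).
#' The cargo is static and receives no force. Pair forces are antisymmetric,
#' so the pairwise contribution sums to zero over all particles.
#'
#' @param state A `particle_state` (see [run_simulation()]) or a numeric
#'   positions matrix (`n_particles` x `dim`).
#' @param config A `sim_config`.
#' @param method `"cell_list"` (default) or `"all_pairs"`; both give
#'   identical results, the cell list is O(n) for short-ranged interactions.
#' @return A list with `forces` (n x dim), `neighbour_count` and `gap`
#'   (surface gap per particle).
#' @export
compute_forces <- function(state, config,
                           method = c("cell_list", "all_pairs")) {
  method <- match.arg(method)
  pos <- if (is.matrix(state)) state else state$positions
  stopifnot(ncol(pos) == config$dim)
  cpp_forces(pos, unclass(config), if (method == "all_pairs") 1L else 0L)
}

new_particle_state <- function(time, positions, neighbour_count, cargo_bound) {
  structure(list(time = time, positions = positions,
                 neighbour_count = neighbour_count,
                 cargo_bound = cargo_bound),
            class = "particle_state")
}

#' Advance the simulation by a number of steps
#'
#' Euler--Maruyama update `x <- x + D * F * dt + sqrt(2 D dt) * xi` with
#' standard-normal `xi` per coordinate (kT = 1), reflecting walls and a
#' reflecting cargo hard core. Draws from R's global RNG stream; call
#' `set.seed()` for reproducibility. Warns if more than 1% of per-particle
#' steps move farther than `r0` (time step too large).
#'
#' @param state A `particle_state`.
#' @param config A `sim_config`.
#' @param n_steps Number of steps to take (default 1).
#' @return The updated `particle_state` (neighbour counts and cargo-bound
#'   flags recomputed).
#' @export
sim_step <- function(state, config, n_steps = 1L) {
  res <- cpp_run(state$positions, unclass(config), as.integer(n_steps),
                 as.integer(n_steps), 0L)
  if (res$big_move_fraction > 0.01)
    warning(sprintf(
      "%.1f%% of particle steps moved farther than r0: time step too large",
      100 * res$big_move_fraction))
  k <- 2L  # last frame
  pos <- t(matrix(res$positions[, , k], nrow = config$dim))
  new_particle_state(state$time + n_steps * config$dt, pos,
                     res$neighbour_count[, k], res$cargo_bound[, k])
}

init_positions <- function(config) {
  n <- config$n_particles
  free_area <- config$box_size^config$dim -
    (if (config$dim == 2L) pi * config$cargo_radius^2
     else 4 / 3 * pi * config$cargo_radius^3)
  occ <- n * (if (config$dim == 2L) pi * config$particle_radius^2
              else 4 / 3 * pi * config$particle_radius^3)
  if (occ > 0.6 * free_area)
    stop("infeasible packing: particles do not fit outside the cargo")
  # sequential rejection sampling: outside the cargo, min spacing 0.85 r0
  gap2 <- (0.85 * config$r0)^2
  pos <- matrix(NA_real_, n, config$dim)
  filled <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (filled < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place particles outside the cargo")
    cand <- stats::runif(config$dim, 0, config$box_size)
    if (sum((cand - config$cargo_center)^2) <
        (config$cargo_radius + config$particle_radius)^2) next
    if (filled > 0L) {
      prev <- pos[seq_len(filled), , drop = FALSE]
      if (any(rowSums(sweep(prev, 2, cand)^2) < gap2)) next
    }
    filled <- filled + 1L
    pos[filled, ] <- cand
  }
  pos
}

#' Run a cargo-binding simulation
#'
#' Initial positions are uniform at random outside the cargo; the trajectory
#' is saved every `save_every` steps (the initial state is frame 1). The run
#' is bit-reproducible given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `trajectory`: list with `frames` (list of `particle_state`),
#'   `config`, and `seed`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pos <- init_positions(config)
  res <- cpp_run(pos, unclass(config), config$n_steps, config$save_every, 0L)
  if (res$big_move_fraction > 0.01)
    warning(sprintf(
      "%.1f%% of particle steps moved farther than r0: time step too large",
      100 * res$big_move_fraction))
  n_frames <- length(res$times)
  frames <- lapply(seq_len(n_frames), function(k) {
    new_particle_state(res$times[k],
                       t(matrix(res$positions[, , k], nrow = config$dim)),
                       res$neighbour_count[, k], res$cargo_bound[, k])
  })
  structure(list(frames = frames, config = config, seed = config$seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d particles, dim %d, t = 0..%g\n",
              length(x$frames), x$config$n_particles, x$config$dim,
              x$frames[[length(x$frames)]]$time))
  invisible(x)
}

#' Named affinity presets
#'
#' Three calibrated parameter sets reproducing the qualitative cargo-binding
#' regimes: `"very_low"` (receptor condensates form but do not stay on the
#' cargo), `"low"` (avidity stabilizes condensates on the cargo surface:
#' initiation hubs), and `"high"` (strong monomeric binding coats the cargo
#' uniformly without large clusters). Preset values are calibrated artifact
#' constants (see the package vignette), not published parameters.
#'
#' @param name One of `"very_low"`, `"low"`, `"high"`.
#' @param seed RNG seed for the run.
#' @param n_steps,save_every Override the preset duration (e.g. for quick
#'   smoke tests).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("very_low", "low", "high"), seed = 1L,
                       n_steps = NULL, save_every = NULL) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".yaml"), package = "cargohub",
                      mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- seed
  if (!is.null(n_steps)) cfg$n_steps <- n_steps
  if (!is.null(save_every)) cfg$save_every <- save_every
  do.call(sim_config, cfg)
}

#' Receptor--receptor well depth above which condensation occurs
#'
#' Calibrated constant: at the preset density, `eps_AA` at or above this
#' value (with cargo coupling off) yields a largest cluster above 10% of all
#' particles at steady state; `eps_AA = 0` does not.
#'
#' @return Depth in kT.
#' @export
clustering_eps_threshold <- function() 3.5

#' Write / read a trajectory as columnar text
#'
#' One row per particle per saved frame (`frame`, `time`, `particle`,
#' coordinates, `neighbour_count`, `cargo_bound`) plus a JSON sidecar
#' (`<stem>.json`) holding the configuration and seed. Numeric fields are
#' serialized at full double precision, so a read-back is bit-exact.
#'
#' @param traj A `trajectory`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return `write_trajectory`: the stem, invisibly. `read_trajectory`: the
#'   reconstructed `trajectory`.
#' @export
write_trajectory <- function(traj, stem) {
  coords <- c("x", "y", "z")[seq_len(traj$config$dim)]
  tab <- do.call(rbind, lapply(seq_along(traj$frames), function(k) {
    f <- traj$frames[[k]]
    pos <- f$positions
    colnames(pos) <- coords
    data.frame(frame = k, time = f$time,
               particle = seq_len(nrow(pos)), pos,
               neighbour_count = f$neighbour_count,
               cargo_bound = f$cargo_bound)
  }))
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config = unclass(traj$config), seed = traj$seed),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- do.call(sim_config, side$config[names(formals(sim_config))[
    names(formals(sim_config)) %in% names(side$config)]])
  tab <- utils::read.csv(paste0(stem, ".csv"))
  coords <- c("x", "y", "z")[seq_len(cfg$dim)]
  frames <- lapply(split(tab, tab$frame), function(f) {
    f <- f[order(f$particle), ]
    pos <- as.matrix(f[coords])
    dimnames(pos) <- NULL
    new_particle_state(f$time[1], pos,
                       f$neighbour_count, as.logical(f$cargo_bound))
  })
  names(frames) <- NULL
  structure(list(frames = frames, config = cfg, seed = side$seed),
            class = "trajectory")
}
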