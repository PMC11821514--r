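test_that("Morse pair potential has its minimum at r0 and vanishes beyond the cutoff", {
  pp <- pair_potential(1.0, eps = 2, r0 = 1, a = 6, r_cut = 2)
  expect_equal(pp$force, 0)
  expect_lt(pp$energy, 0)

  # interaction off
  off <- pair_potential(c(0.5, 1, 1.5), eps = 0, r0 = 1, a = 6, r_cut = 2)
  expect_equal(off$energy, rep(0, 3))
  expect_equal(off$force, rep(0, 3))

  # untruncated Morse at e^{-a(r - r0)} = 1/2: energy = eps * ((1/2)^2 - 1)
  a <- 6
  pp <- pair_potential(1 + log(2) / a, eps = 1, r0 = 1, a = a, r_cut = Inf)
  expect_equal(pp$energy, -0.75, tolerance = 1e-12)

  # zero beyond the cutoff, continuous at it
  pp <- pair_potential(c(1.79999, 1.8, 2.5), eps = 3, r0 = 1, a = 6,
                       r_cut = 1.8)
  expect_equal(pp$energy[2:3], c(0, 0))
  expect_equal(pp$force[2:3], c(0, 0))
  expect_lt(abs(pp$energy[1]), 1e-3)

  # force is the negative derivative of the (shifted) energy
  r <- seq(0.8, 1.7, by = 0.01)
  h <- 1e-6
  up <- pair_potential(r + h, 2.5, 1, 6, 1.8)$energy
  dn <- pair_potential(r - h, 2.5, 1, 6, 1.8)$energy
  expect_equal(pair_potential(r, 2.5, 1, 6, 1.8)$force, -(up - dn) / (2 * h),
               tolerance = 1e-6)

  expect_error(pair_potential(0, 1, 1, 6, 2), "r must be > 0")
  expect_error(pair_potential(-1, 1, 1, 6, 2), "r must be > 0")
})

test_that("avidity-scaled cargo depth follows eps_AC (1 + beta min(n, n_max))", {
  expect_equal(effective_cargo_depth(0, eps_AC = 1.3, beta = 2, n_max = 6), 1.3)
  expect_equal(effective_cargo_depth(0:10, eps_AC = 2, beta = 0, n_max = 6),
               rep(2, 11))
  expect_equal(effective_cargo_depth(3, eps_AC = 1, beta = 0.5, n_max = 6), 2.5)
  # monotone non-decreasing, saturating at n_max
  d <- effective_cargo_depth(0:12, eps_AC = 0.5, beta = 1, n_max = 6)
  expect_true(all(diff(d) >= 0))
  expect_equal(d[7:13], rep(d[7], 7))
  expect_error(effective_cargo_depth(-1, 1, 1, 6), "non-negative")
})

test_that("force assembly is antisymmetric and cargo-aware", {
  cfg <- sim_config(box_size = 40, n_particles = 1, cargo_radius = 5,
                    eps_AA = 2, eps_AC = 0, n_steps = 1L, save_every = 1L)
  # single particle far from everything: zero force
  f <- compute_forces(matrix(c(35, 35), 1), cfg)
  expect_equal(f$forces, matrix(0, 1, 2))

  # pair at the minimum: zero force
  f <- compute_forces(rbind(c(30, 30), c(31, 30)), cfg)
  expect_equal(f$forces, matrix(0, 2, 2), tolerance = 1e-14)

  # equilateral triangle: net force zero by pairwise antisymmetry
  tri <- rbind(c(30, 30), c(31.2, 30), c(30.6, 30 + 1.2 * sqrt(3) / 2))
  f <- compute_forces(tri, cfg)
  expect_equal(colSums(f$forces), c(0, 0), tolerance = 1e-12)

  # overlapping coordinates are regularized, never NaN
  f <- compute_forces(rbind(c(30, 30), c(30, 30)), cfg)
  expect_true(all(is.finite(f$forces)))

  # cargo pull appears only within the cutoff and scales with neighbours
  cfg2 <- sim_config(box_size = 40, n_particles = 2, cargo_radius = 5,
                     eps_AA = 0, eps_AC = 1, avidity_gain = 1,
                     avidity_cap = 6)
  lone <- compute_forces(matrix(c(20, 26), 1), cfg2)  # gap 1 < r_cut
  expect_lt(lone$forces[1, 2], 0)  # pulled toward the cargo centre
  paired <- compute_forces(rbind(c(20, 26), c(21, 26)), cfg2)
  expect_gt(abs(paired$forces[1, 2]), abs(lone$forces[1, 2]))
})

test_that("cell-list and all-pairs forces agree on random configurations", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    cfg <- sim_config(box_size = 30, n_particles = n, cargo_radius = 8,
                      eps_AA = 3, eps_AC = 0.8, avidity_gain = 1)
    pos <- matrix(runif(n * 2, 0, 30), n)
    f1 <- compute_forces(pos, cfg, method = "cell_list")
    f2 <- compute_forces(pos, cfg, method = "all_pairs")
    expect_equal(f1$neighbour_count, f2$neighbour_count)
    expect_equal(f1$forces, f2$forces, tolerance = 1e-12)
  }
})

test_that("stepping conserves particles, respects boundaries, and is seeded-deterministic", {
  cfg <- sim_config(box_size = 20, n_particles = 60, cargo_radius = 4,
                    eps_AA = 2, eps_AC = 0.5, n_steps = 400L,
                    save_every = 100L, seed = 7L)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$frames, tr2$frames)  # bit-identical given the seed

  expect_length(tr1$frames, cfg$n_steps / cfg$save_every + 1)
  times <- vapply(tr1$frames, `[[`, numeric(1), "time")
  expect_true(all(diff(times) > 0))
  for (f in tr1$frames) {
    expect_equal(nrow(f$positions), cfg$n_particles)
    expect_true(all(f$positions >= 0 & f$positions <= cfg$box_size))
    d <- sqrt(rowSums(sweep(f$positions, 2, cfg$cargo_center)^2))
    expect_true(all(d >= cfg$cargo_radius - 1e-9))
  }

  # no noise, no force: positions unchanged
  cfg0 <- sim_config(box_size = 20, n_particles = 10, cargo_radius = 4,
                     eps_AA = 0, eps_AC = 0, D = 0, n_steps = 5L,
                     save_every = 5L, seed = 1L)
  set.seed(1)
  st <- make_state(matrix(runif(20, 12, 18), 10))
  out <- sim_step(st, cfg0, n_steps = 5L)
  expect_equal(out$positions, st$positions)
})

test_that("free diffusion reproduces MSD = 2 dim D t", {
  set.seed(99)
  msd_hat <- replicate(5, {
    cfg <- sim_config(box_size = 200, n_particles = 120, cargo_radius = 1,
                      cargo_center = c(3, 3), eps_AA = 0, eps_AC = 0,
                      dt = 1e-3, n_steps = 500L, save_every = 500L,
                      seed = sample.int(1e6, 1))
    tr <- run_simulation(cfg)
    disp <- tr$frames[[2]]$positions - tr$frames[[1]]$positions
    mean(rowSums(disp^2)) / tr$frames[[2]]$time
  })
  # slope estimate vs 2 * dim * D = 4; each run averages 120 particles
  expect_equal(median(msd_hat), 4, tolerance = 0.15)
})

test_that("a too-large time step triggers the displacement warning", {
  cfg <- sim_config(box_size = 20, n_particles = 2, cargo_radius = 2,
                    cargo_center = c(4, 4), eps_AA = 60, eps_AC = 0,
                    dt = 0.05, n_steps = 10L, save_every = 10L)
  st <- make_state(rbind(c(10, 10), c(10.55, 10)))  # deep in the soft core
  set.seed(1)
  expect_warning(sim_step(st, cfg, n_steps = 10L), "time step too large")
})

test_that("infeasible packing is rejected before stepping", {
  expect_error(
    run_simulation(sim_config(box_size = 8, n_particles = 500,
                              cargo_radius = 3, n_steps = 10L,
                              save_every = 10L)),
    "infeasible packing")
})

test_that("config validation catches bad geometry and parameters", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(eps_AA = -1), "eps_AA")
  expect_error(sim_config(particle_radius = 3, cargo_radius = 2),
               "particle_radius")
  expect_error(sim_config(box_size = 20, cargo_radius = 15), "inside the box")
  expect_error(sim_config(r_cut = 0.5, r0 = 1), "r_cut")
  expect_error(sim_config(boundary = "periodic"), "reflecting")
})

test_that("trajectory text round-trip is bit-exact", {
  cfg <- sim_config(box_size = 20, n_particles = 25, cargo_radius = 4,
                    eps_AA = 3, eps_AC = 0.5, n_steps = 200L,
                    save_every = 100L, seed = 3L)
  tr <- run_simulation(cfg)
  stem <- file.path(withr::local_tempdir(), "traj")
  write_trajectory(tr, stem)
  rt <- read_trajectory(stem)
  expect_equal(length(rt$frames), length(tr$frames))
  for (k in seq_along(tr$frames)) {
    expect_identical(rt$frames[[k]]$positions,
                     unname(tr$frames[[k]]$positions))
    expect_identical(as.integer(rt$frames[[k]]$neighbour_count),
                     as.integer(tr$frames[[k]]$neighbour_count))
    expect_identical(rt$frames[[k]]$cargo_bound, tr$frames[[k]]$cargo_bound)
  }
  expect_equal(rt$config$eps_AA, cfg$eps_AA)
  expect_identical(rt$seed, tr$seed)
})

test_that("YAML config mirrors sim_config field-for-field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dim: 2", "box_size: 30", "n_particles: 50",
               "cargo_radius: 6", "eps_AA: 2.5", "seed: 11"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$eps_AA, 2.5)
  expect_equal(cfg$n_particles, 50L)
  writeLines("not_a_field: 3", path)
  expect_error(read_sim_config(path), "unknown config fields")
})
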