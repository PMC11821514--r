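#' @title Seeded synthetic-data generators
#' @description Each generator returns the dataset in the container its
#'   analysis module consumes plus a `ground_truth` record (generator name,
#'   seed, all generative parameters, and closed-form expectations where
#'   available). Regeneration from the same seed and parameters is
#'   bit-identical.
#' @name synthgen
NULL

new_ground_truth <- function(generator, seed, params, ...) {
  structure(c(list(generator = generator, seed = seed, params = params),
              list(...)),
            class = "ground_truth")
}

#' Write a ground-truth record as JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Synthetic ring-shaped cargo image
#'
#' Emulates a fluorescent protein coating a round cargo: a uniform ring of
#' amplitude `uniform_amp` plus `n_foci` point-like foci of amplitude
#' `focus_amp` at random angles on the ring, blurred with a Gaussian PSF
#' and corrupted with Poisson shot noise (expected counts =
#' `poisson_scale * signal`, rescaled back) and Gaussian read noise.
#' Set `poisson_scale = 0` and `read_noise = 0` for a noiseless image.
#'
#' @param n_foci Number of foci (0 for a uniform coat).
#' @param radius Ring radius (px).
#' @param band Ring half-thickness (px).
#' @param focus_amp Focus amplitude (per focus, added to the ring).
#' @param uniform_amp Ring amplitude.
#' @param psf_sigma Gaussian PSF sigma (px); 0 disables blurring.
#' @param poisson_scale Photon scale of shot noise; 0 disables.
#' @param read_noise Gaussian read-noise s.d.; 0 disables.
#' @param size Image edge (px).
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed.
#' @return List with `image` (a [hub_image()], channel `"ring"`) and
#'   `truth` (focus angles and amplitudes, ring geometry).
#' @export
gen_ring_image <- function(n_foci = 3, radius = 20, band = 2,
                           focus_amp = 150, uniform_amp = 100,
                           psf_sigma = 1.5, poisson_scale = 1,
                           read_noise = 2, size = 96L, pixel_size = 0.1,
                           seed = 1L) {
  set.seed(seed)
  c0 <- (size + 1) / 2
  if (radius + band + 3 * max(psf_sigma, 1) >= size / 2)
    stop("ring does not fit in the image")
  X <- matrix(seq_len(size), size, size, byrow = TRUE)  # X[y, x] = x
  Y <- matrix(seq_len(size), size, size)                # Y[y, x] = y
  r <- sqrt((X - c0)^2 + (Y - c0)^2)
  img <- uniform_amp * (abs(r - radius) <= band)
  angles <- stats::runif(n_foci, 0, 2 * pi)
  if (n_foci > 0) {
    fs <- max(band / 1.5, 0.8)  # focus footprint before PSF blur
    for (a in angles) {
      fx <- c0 + radius * cos(a)
      fy <- c0 + radius * sin(a)
      img <- img + focus_amp *
        exp(-((X - fx)^2 + (Y - fy)^2) / (2 * fs^2))
    }
  }
  if (psf_sigma > 0) img <- EBImage::gblur(img, sigma = psf_sigma)
  img[img < 0] <- 0
  if (poisson_scale > 0)
    img <- stats::rpois(length(img), poisson_scale * img) / poisson_scale
  if (read_noise > 0) img <- img + stats::rnorm(length(img), 0, read_noise)
  img <- matrix(pmax(img, 0), size, size)
  truth <- new_ground_truth(
    "ring_image", seed,
    list(n_foci = n_foci, radius = radius, band = band,
         focus_amp = focus_amp, uniform_amp = uniform_amp,
         psf_sigma = psf_sigma, poisson_scale = poisson_scale,
         read_noise = read_noise, size = size, pixel_size = pixel_size),
    center = c(c0, c0), focus_angles = angles)
  list(image = hub_image(list(ring = img), pixel_size = pixel_size),
       truth = truth)
}

#' Synthetic three-channel line-profile image
#'
#' Three channels, each a Gaussian peak at a known offset along a
#' horizontal line, for testing profile extraction and ER-proximity logic.
#'
#' @param offsets_px Named numeric vector of peak x-offsets (px) from the
#'   line start, one per channel.
#' @param peak_sigma Peak sigma (px).
#' @param amp Peak amplitude.
#' @param size Image edge (px).
#' @param noise Gaussian noise s.d.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed.
#' @return List with `image`, `p0`, `p1` (the probe line) and `truth`.
#' @export
gen_profile_image <- function(offsets_px = c(er = 20, fip200 = 26, p62 = 34),
                              peak_sigma = 2, amp = 100, size = 64L,
                              noise = 0, pixel_size = 0.1, seed = 1L) {
  set.seed(seed)
  y0 <- (size + 1) / 2
  x0 <- 8
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  chans <- lapply(offsets_px, function(off) {
    m <- amp * exp(-((X - (x0 + off))^2 + (Y - y0)^2) / (2 * peak_sigma^2))
    if (noise > 0) m <- pmax(m + stats::rnorm(length(m), 0, noise), 0)
    m
  })
  truth <- new_ground_truth("profile_image", seed,
                            list(offsets_px = as.list(offsets_px),
                                 peak_sigma = peak_sigma, amp = amp,
                                 noise = noise, pixel_size = pixel_size),
                            p0 = c(x0, y0), p1 = c(size - 4, y0))
  list(image = hub_image(chans, pixel_size = pixel_size),
       p0 = c(x0, y0), p1 = c(size - 4, y0), truth = truth)
}

#' Synthetic FRAP trace with known kinetics
#'
#' Ground-truth normalized curve: 1 before the bleach and
#' `N*(t) = (1 - d) + d * f * (1 - exp(-k t))` after it (`d` = bleach
#' depth, `f` = mobile fraction, `t` from the first post-bleach frame).
#' The curve is mapped to raw ROI/reference/background intensities with an
#' acquisition-bleaching decay shared by ROI and reference (which double
#' normalization removes exactly) plus Gaussian noise on the ROI.
#'
#' @param f Mobile fraction in `[0, 1]`.
#' @param k Recovery rate (1/s), > 0.
#' @param depth Bleach depth in `(0, 1]`.
#' @param n_pre,n_post Pre-/post-bleach frame counts.
#' @param interval Frame interval (s).
#' @param noise Gaussian s.d. added to the normalized ROI signal.
#' @param acq_bleach Acquisition-bleaching rate (1/s) of ROI and reference.
#' @param seed Integer seed.
#' @return List with `trace` (a [frap_trace()]) and `truth` (including the
#'   noiseless normalized curve `N_star`).
#' @export
gen_frap_trace <- function(f = 0.6, k = 0.1, depth = 0.8, n_pre = 5L,
                           n_post = 60L, interval = 1, noise = 0,
                           acq_bleach = 0.002, seed = 1L) {
  if (f < 0 || f > 1) stop("mobile fraction must lie in [0, 1]")
  if (k <= 0) stop("recovery rate must be > 0")
  if (depth <= 0 || depth > 1) stop("bleach depth must lie in (0, 1]")
  set.seed(seed)
  n <- n_pre + n_post
  times <- (seq_len(n) - 1) * interval
  bleach_index <- n_pre + 1L
  t_rel <- times - times[bleach_index]
  N_star <- ifelse(t_rel < 0, 1, (1 - depth) + depth * f * (1 - exp(-k * t_rel)))
  B <- 50
  T0 <- 1200
  ref <- B + (T0 - B) * exp(-acq_bleach * times)
  ratio_pre <- 0.8  # ROI-to-structure intensity ratio before the bleach
  Nn <- N_star + if (noise > 0) stats::rnorm(n, 0, noise) else 0
  roi <- B + (ref - B) * ratio_pre * Nn
  trace <- frap_trace(times, roi, ref, B, bleach_index)
  truth <- new_ground_truth("frap_trace", seed,
                            list(f = f, k = k, depth = depth, n_pre = n_pre,
                                 n_post = n_post, interval = interval,
                                 noise = noise, acq_bleach = acq_bleach),
                            N_star = N_star)
  list(trace = trace, truth = truth)
}

#' Synthetic two-population mKeima event table
#'
#' Each event is cytosolic (low acidic/neutral ratio) with probability
#' `1 - pi_lys` or lysosomal (high ratio) with probability `pi_lys`.
#' Neutral intensities and per-population ratios are log-normal; the acidic
#' intensity is ratio times neutral. The mixture mean ratio
#' `(1 - pi) * E[r_cyto] + pi * E[r_lys]` is recorded in the truth.
#'
#' @param n Number of events.
#' @param pi_lys Lysosomal fraction in `[0, 1]`.
#' @param cyto_meanlog,cyto_sdlog Log-normal ratio parameters, cytosolic
#'   population (defaults give mean ratio ~0.26).
#' @param lys_meanlog,lys_sdlog Same for the lysosomal population
#'   (defaults give mean ratio ~2.9).
#' @param neutral_meanlog,neutral_sdlog Log-normal neutral intensity.
#' @param sample,condition,replicate Metadata labels for the table.
#' @param seed Integer seed.
#' @return List with `table` (a [flow_event_table()]) and `truth`.
#' @export
gen_flow_events <- function(n = 20000L, pi_lys = 0.3,
                            cyto_meanlog = -1.4, cyto_sdlog = 0.25,
                            lys_meanlog = 1.0, lys_sdlog = 0.35,
                            neutral_meanlog = 7, neutral_sdlog = 0.5,
                            sample = "s1", condition = NA, replicate = 1L,
                            seed = 1L) {
  if (pi_lys < 0 || pi_lys > 1) stop("pi_lys must lie in [0, 1]")
  set.seed(seed)
  lys <- stats::runif(n) < pi_lys
  ratio <- ifelse(lys,
                  stats::rlnorm(n, lys_meanlog, lys_sdlog),
                  stats::rlnorm(n, cyto_meanlog, cyto_sdlog))
  neutral <- stats::rlnorm(n, neutral_meanlog, neutral_sdlog)
  tab <- flow_event_table(neutral = neutral, acidic = ratio * neutral,
                          sample = sample, condition = condition,
                          replicate = replicate)
  mean_cyto <- exp(cyto_meanlog + cyto_sdlog^2 / 2)
  mean_lys <- exp(lys_meanlog + lys_sdlog^2 / 2)
  truth <- new_ground_truth(
    "flow_events", seed,
    list(n = n, pi_lys = pi_lys, cyto_meanlog = cyto_meanlog,
         cyto_sdlog = cyto_sdlog, lys_meanlog = lys_meanlog,
         lys_sdlog = lys_sdlog, neutral_meanlog = neutral_meanlog,
         neutral_sdlog = neutral_sdlog),
    mean_ratio_cyto = mean_cyto, mean_ratio_lys = mean_lys,
    mixture_mean_ratio = (1 - pi_lys) * mean_cyto + pi_lys * mean_lys,
    is_lysosomal = lys)
  list(table = tab, truth = truth)
}

#' Synthetic protein quantification table
#'
#' Baseline log2 intensities are Gaussian per protein with replicate noise;
#' a planted subset of proteins gains `effect` log2 units in the bait
#' samples; per-sample shifts emulate loading differences (recoverable by
#' [mode_normalize()]); low-intensity cells are censored by a logistic
#' missingness curve; peptide counts and contaminant flags complete the
#' table. With two genotypes, a subset of the enriched proteins is
#' knockdown-sensitive: their bait enrichment is reduced by `kd_effect` in
#' the knockdown genotype.
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of planted bait-enriched proteins.
#' @param effect Planted enrichment (log2 units).
#' @param rep_sd Replicate noise s.d. (log2).
#' @param shifts Per-sample shifts (recycled/padded with 0).
#' @param n_rep Replicates per condition group.
#' @param genotypes `"WT"` or `c("WT", "KD")`.
#' @param kd_fraction Fraction of enriched proteins that lose enrichment on
#'   knockdown.
#' @param kd_effect Log2 reduction of bait enrichment in the knockdown.
#' @param baseline_mean,baseline_sd Protein baseline distribution (log2).
#' @param missing_mid,missing_scale Logistic censoring: P(missing) =
#'   `plogis((missing_mid - x) / missing_scale)`; `missing_scale = 0`
#'   disables censoring.
#' @param contaminant_fraction Fraction of proteins flagged contaminant.
#' @param seed Integer seed.
#' @return List with `table` (a [quant_table()]) and `truth` (enriched and
#'   knockdown-sensitive protein ids, shifts).
#' @export
gen_quant_table <- function(n_proteins = 600L, n_enriched = 30L, effect = 3,
                            rep_sd = 0.3, shifts = 0, n_rep = 3L,
                            genotypes = "WT", kd_fraction = 0.5,
                            kd_effect = 3, baseline_mean = 13,
                            baseline_sd = 1.5, missing_mid = 9.8,
                            missing_scale = 0.4,
                            contaminant_fraction = 0, seed = 1L) {
  if (n_enriched > n_proteins) stop("n_enriched must be <= n_proteins")
  set.seed(seed)
  meta <- expand.grid(replicate = seq_len(n_rep), genotype = genotypes,
                      construct = c("control", "bait"),
                      stringsAsFactors = FALSE)[3:1]
  meta$sample <- paste(meta$construct, meta$genotype, meta$replicate,
                       sep = "_")
  ns <- nrow(meta)
  shifts <- rep_len(c(shifts, rep(0, ns)), ns)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  enriched <- proteins[seq_len(n_enriched)]
  kd_sensitive <- if (length(genotypes) > 1 && n_enriched > 0)
    enriched[seq_len(ceiling(kd_fraction * n_enriched))] else character(0)
  base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
  m <- matrix(stats::rnorm(n_proteins * ns, 0, rep_sd), n_proteins, ns) + base
  for (ci in seq_len(ns)) {
    if (meta$construct[ci] == "bait") {
      idx <- match(enriched, proteins)
      m[idx, ci] <- m[idx, ci] + effect
      if (meta$genotype[ci] != genotypes[1] && length(kd_sensitive)) {
        kidx <- match(kd_sensitive, proteins)
        m[kidx, ci] <- m[kidx, ci] - kd_effect
      }
    }
    m[, ci] <- m[, ci] + shifts[ci]
  }
  if (missing_scale > 0) {
    pmis <- stats::plogis((missing_mid - m) / missing_scale)
    m[stats::runif(length(m)) < pmis] <- NA
  }
  peptides <- 2L + stats::rpois(n_proteins, 6)
  contaminant <- stats::runif(n_proteins) < contaminant_fraction
  rownames(m) <- proteins
  tab <- quant_table(m, peptides, contaminant, meta)
  truth <- new_ground_truth(
    "quant_table", seed,
    list(n_proteins = n_proteins, n_enriched = n_enriched, effect = effect,
         rep_sd = rep_sd, shifts = shifts, n_rep = n_rep,
         genotypes = genotypes, kd_fraction = kd_fraction,
         kd_effect = kd_effect, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, missing_mid = missing_mid,
         missing_scale = missing_scale,
         contaminant_fraction = contaminant_fraction),
    enriched = enriched, kd_sensitive = kd_sensitive)
  list(table = tab, truth = truth)
}
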