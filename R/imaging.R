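#' Multi-channel image container
#'
#' A light wrapper around a named list of non-negative 2D intensity
#' matrices sharing one shape. Pixel centres sit at integer coordinates
#' (column = x, row = y), origin at the top-left pixel (1, 1); physical
#' distances are obtained through `pixel_size` (micrometres per pixel).
#'
#' @param channels Named list of numeric matrices (same dimensions).
#' @param pixel_size Pixel edge in micrometres.
#' @return An object of class `hub_image`.
#' @export
hub_image <- function(channels, pixel_size = 0.1) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must have the same shape")
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "hub_image")
}

#' Read a multi-channel TIFF as a `hub_image`
#'
#' Multi-page TIFFs are interpreted as one page per channel.
#'
#' @param path Path to a TIFF file.
#' @param channel_names Optional channel names (default `ch1`, `ch2`, ...).
#' @param pixel_size Micrometres per pixel.
#' @return A `hub_image`.
#' @export
read_image_tiff <- function(path, channel_names = NULL, pixel_size = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(pages))
  names(pages) <- channel_names
  hub_image(pages, pixel_size = pixel_size)
}

# Bilinear interpolation of matrix m at (x = column, y = row) positions.
# Out-of-range queries are an error for the callers below, which pre-check.
bilinear <- function(m, x, y) {
  x0 <- pmax(1, pmin(ncol(m) - 1, floor(x)))
  y0 <- pmax(1, pmin(nrow(m) - 1, floor(y)))
  fx <- x - x0
  fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    m[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Ring specification
#'
#' Sampling locus for [ring_cov()]: a circle of `radius` around `center`
#' (pixel coordinates), radially averaged over a band of half-width `band`,
#' at `n_samples` equally spaced angles.
#'
#' @param center Numeric length-2 (x, y) in pixels.
#' @param radius Ring radius in pixels (> band).
#' @param band Band half-width in pixels (>= 0).
#' @param n_samples Number of angular samples (default 50).
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(center, radius, band = 0, n_samples = 50L) {
  stopifnot(length(center) == 2, radius > band, band >= 0, n_samples >= 4)
  structure(list(center = as.numeric(center), radius = radius, band = band,
                 n_samples = as.integer(n_samples)),
            class = "ring_spec")
}

#' Ring coefficient of variation (clustering metric)
#'
#' Samples the fluorescence intensity at `n_samples` equally spaced angles
#' on a ring around a structure (bilinear interpolation, radially averaged
#' across the band) and returns the sample standard deviation (n-1) divided
#' by the mean. Focal accumulations around the structure give high values;
#' an even coat gives values near zero. The statistic is invariant under
#' uniform intensity scaling.
#'
#' @param image A `hub_image`.
#' @param channel Channel name.
#' @param ring A `ring_spec`.
#' @return Dimensionless CoV.
#' @export
ring_cov <- function(image, channel, ring) {
  stopifnot(inherits(image, "hub_image"), inherits(ring, "ring_spec"))
  m <- image$channels[[channel]]
  if (is.null(m)) stop("unknown channel: ", channel)
  rmax <- ring$radius + ring$band
  if (ring$center[1] - rmax < 1 || ring$center[1] + rmax > ncol(m) ||
      ring$center[2] - rmax < 1 || ring$center[2] + rmax > nrow(m))
    stop("ring (including band) extends outside the image")
  theta <- 2 * pi * (seq_len(ring$n_samples) - 1) / ring$n_samples
  radii <- if (ring$band > 0) seq(ring$radius - ring$band,
                                  ring$radius + ring$band, by = 1)
           else ring$radius
  vals <- vapply(theta, function(t) {
    mean(bilinear(m, ring$center[1] + radii * cos(t),
                  ring$center[2] + radii * sin(t)))
  }, numeric(1))
  mu <- mean(vals)
  if (mu <= 0) stop("mean ring intensity must be > 0")
  stats::sd(vals) / mu
}

#' Intensity profile along a line segment
#'
#' Bilinear samples at approximately 1 px spacing from `p0` to `p1`,
#' averaged across `width` perpendicular offsets (unit spacing, centred on
#' the line). Positions are reported in micrometres from `p0`.
#'
#' @param image A `hub_image`.
#' @param p0,p1 Segment endpoints, (x, y) in pixels.
#' @param width Odd number of perpendicular samples to average (default 1).
#' @param channels Channels to extract (default all).
#' @return A `line_profile`: list with `positions` (um) and `intensity`
#'   (named list of numeric vectors).
#' @export
line_profile <- function(image, p0, p1, width = 1L, channels = NULL) {
  stopifnot(inherits(image, "hub_image"), length(p0) == 2, length(p1) == 2)
  if (width < 1 || width %% 2 == 0) stop("width must be a positive odd count")
  if (is.null(channels)) channels <- names(image$channels)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("p0 and p1 coincide")
  n <- ceiling(len) + 1L
  tfrac <- seq(0, 1, length.out = n)
  u <- (p1 - p0) / len          # unit along
  v <- c(-u[2], u[1])           # unit perpendicular
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  dims <- dim(image$channels[[1]])
  xs <- outer(p0[1] + tfrac * (p1[1] - p0[1]), offs * v[1], `+`)
  ys <- outer(p0[2] + tfrac * (p1[2] - p0[2]), offs * v[2], `+`)
  if (any(xs < 1 | xs > dims[2] | ys < 1 | ys > dims[1]))
    stop("line segment (with width) extends outside the image")
  intensity <- lapply(image$channels[channels], function(m) {
    rowMeans(matrix(bilinear(m, as.vector(xs), as.vector(ys)), nrow = n))
  })
  structure(list(positions = tfrac * len * image$pixel_size,
                 intensity = intensity,
                 pixel_size = image$pixel_size),
            class = "line_profile")
}

#' Peak position along a profile
#'
#' Position of the global intensity maximum, refined by a three-point
#' parabolic fit through the maximum and its neighbours. Ties between equal
#' maxima are broken toward the start of the line (`p0`).
#'
#' @param profile A `line_profile`.
#' @param channel Channel name.
#' @return Peak position in micrometres from the start of the line.
#' @export
peak_position <- function(profile, channel) {
  y <- profile$intensity[[channel]]
  if (is.null(y)) stop("unknown channel: ", channel)
  if (max(y) == min(y)) stop("no peak: profile is constant")
  i <- which.max(y)  # first index on ties -> nearer p0
  pos <- profile$positions
  if (i == 1L || i == length(y)) return(pos[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  pos[i] + delta * (pos[i + 1] - pos[i])
}

#' ER-proximity difference of two markers
#'
#' `delta = |peak(p62) - peak(er)| - |peak(fip200) - peak(er)|` on a
#' three-channel profile; positive values mean the FIP200 channel peaks
#' closer to the ER channel than the p62 channel does.
#'
#' @param profile A `line_profile` with all three channels.
#' @param fip200,p62,er Channel names.
#' @return Signed distance in micrometres.
#' @export
er_proximity_difference <- function(profile, fip200 = "fip200",
                                    p62 = "p62", er = "er") {
  pe <- peak_position(profile, er)
  abs(peak_position(profile, p62) - pe) -
    abs(peak_position(profile, fip200) - pe)
}

#' Frequency of FIP200-closer-to-ER events
#'
#' Fraction of profiles with a strictly positive proximity difference
#' (ties count against).
#'
#' @param deltas Numeric vector of [er_proximity_difference()] values.
#' @return Fraction in `[0, 1]`.
#' @export
proximity_frequency <- function(deltas) {
  if (length(deltas) == 0) stop("empty list of proximity differences")
  mean(deltas > 0)
}
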