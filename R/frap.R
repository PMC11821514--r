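#' FRAP trace container
#'
#' Holds a fluorescence-recovery-after-photobleaching measurement: the
#' bleached-region intensity `roi`, a whole-structure `reference` that
#' tracks acquisition bleaching, and a cell-free `background` (per frame or
#' a scalar). `bleach_index` is the index of the first post-bleach frame;
#' frames `1:(bleach_index - 1)` are pre-bleach (frames acquired during the
#' bleach pulse itself should not be included).
#'
#' @param times Acquisition times (s), strictly increasing.
#' @param roi Bleached-region mean intensity per frame.
#' @param reference Whole-structure mean intensity per frame.
#' @param background Background intensity, scalar or per frame.
#' @param bleach_index Index of the first post-bleach frame (>= 2).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi, reference, background, bleach_index) {
  n <- length(times)
  stopifnot(length(roi) == n, length(reference) == n,
            length(background) %in% c(1L, n))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (bleach_index < 2 || bleach_index > n)
    stop("bleach_index must lie in 2..length(times)")
  b <- if (length(background) == 1L) rep(background, n) else background
  bad <- which(reference - b <= 0)
  if (length(bad))
    stop("non-positive reference minus background at frame(s) ",
         paste(bad, collapse = ", "))
  structure(list(times = as.numeric(times), roi = as.numeric(roi),
                 reference = as.numeric(reference), background = b,
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `time`, `roi`, `reference`, `background` (the last may be
#' constant).
#'
#' @param path CSV path.
#' @param bleach_index Index of the first post-bleach frame.
#' @return A `frap_trace`.
#' @export
read_frap_csv <- function(path, bleach_index) {
  d <- utils::read.csv(path)
  frap_trace(d$time, d$roi, d$reference, d$background, bleach_index)
}

#' Double normalization of a FRAP trace
#'
#' Background-corrects the bleached-region intensity by the whole-structure
#' reference, `R(t) = (I(t) - B(t)) / (T(t) - B(t))`, which removes
#' acquisition bleaching, then divides by the pre-bleach mean of `R` so the
#' pre-bleach level is exactly 1. Invariant under a common rescaling of
#' `I`, `T` and `B`.
#'
#' @param trace A `frap_trace`.
#' @return A list with `times`, `N` (normalized curve), and `bleach_index`.
#' @export
double_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  R <- (trace$roi - trace$background) / (trace$reference - trace$background)
  pre <- seq_len(trace$bleach_index - 1L)
  N <- R / mean(R[pre])
  list(times = trace$times, N = N, bleach_index = trace$bleach_index)
}

#' Fit single-exponential recovery kinetics
#'
#' Least-squares fit of `N(t) = N0 + A * (1 - exp(-k * (t - t_bleach)))`
#' over the post-bleach frames, the minimal standard recovery model.
#' The mobile fraction is `A / (1 - N0)` (fraction of the bleached signal
#' that recovers); `t_half = log(2) / k`. Start values: `N0` = first
#' post-bleach value, `A` = last minus first, `k = 3 / span`.
#'
#' @param times Frame times (s).
#' @param N Normalized intensities (e.g. from [double_normalize()]).
#' @param bleach_index Index of the first post-bleach frame.
#' @return A `recovery_fit` list: `N0`, `A`, `k`, `t_half`, `plateau`
#'   (`N0 + A`), `mobile_fraction` (raw value; clamp to `[0, 1]` reported
#'   separately as `mobile_fraction_clamped`), and `converged`.
#' @export
fit_recovery <- function(times, N, bleach_index) {
  post <- bleach_index:length(times)
  if (length(post) < 5) stop("need at least 5 post-bleach frames")
  t_rel <- times[post] - times[bleach_index]
  y <- N[post]
  start <- list(N0 = y[1], A = y[length(y)] - y[1],
                k = 3 / max(t_rel[length(t_rel)], .Machine$double.eps))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ N0 + A * (1 - exp(-k * t_rel)),
                      start = start,
                      lower = c(N0 = -Inf, A = -Inf, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(N0 = start$N0, A = start$A, k = NA_real_, t_half = NA_real_,
                plateau = start$N0 + start$A,
                mobile_fraction = start$A / (1 - start$N0),
                mobile_fraction_clamped = NA_real_, converged = FALSE)
    out$mobile_fraction_clamped <- min(1, max(0, out$mobile_fraction))
    class(out) <- "recovery_fit"
    return(out)
  }
  p <- as.list(stats::coef(fit))
  mf <- p$A / (1 - p$N0)
  out <- list(N0 = p$N0, A = p$A, k = p$k, t_half = log(2) / p$k,
              plateau = p$N0 + p$A, mobile_fraction = mf,
              mobile_fraction_clamped = min(1, max(0, mf)),
              converged = fit$convInfo$isConv %||% TRUE)
  class(out) <- "recovery_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> mobile fraction %.3f, k = %.4g /s (t1/2 = %.3g s)%s\n",
    x$mobile_fraction, x$k, x$t_half,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
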