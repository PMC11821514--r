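#' Flow-cytometry event table for the mKeima assay
#'
#' One row per (post-gating) event with the neutral-excitation (405 nm) and
#' acidic-excitation (561 nm) mKeima intensities, plus sample metadata.
#' Gating (live cells, singlets, reporter-positive) is assumed done
#' upstream; the only eligibility rule applied here is `neutral > 0`.
#'
#' @param neutral Neutral-form intensity per event (405 nm excitation).
#' @param acidic Acidic-form intensity per event (561 nm excitation).
#' @param sample Sample identifier per event.
#' @param condition Condition label per event (or per sample).
#' @param replicate Replicate label.
#' @param gfp Optional reporter-gate intensity (488 nm), carried through.
#' @return A `flow_event_table` (data frame).
#' @export
flow_event_table <- function(neutral, acidic, sample, condition = NA,
                             replicate = NA, gfp = NA) {
  stopifnot(length(neutral) == length(acidic),
            length(sample) %in% c(1L, length(neutral)))
  if (any(!is.finite(neutral)) || any(!is.finite(acidic)))
    stop("intensities must be finite")
  d <- data.frame(neutral = neutral, acidic = acidic, sample = sample,
                  condition = condition, replicate = replicate, gfp = gfp)
  class(d) <- c("flow_event_table", "data.frame")
  d
}

#' Per-event mKeima ratios
#'
#' The mKeima ratio of each event is the acidic-excitation signal divided by
#' the neutral-excitation signal. Events with `neutral <= 0` are excluded
#' and counted.
#'
#' @param table A `flow_event_table`.
#' @return The eligible subset with a `ratio` column; the number of excluded
#'   events is attached as `attr(, "n_excluded")`.
#' @export
event_ratios <- function(table) {
  eligible <- table$neutral > 0
  out <- table[eligible, , drop = FALSE]
  out$ratio <- out$acidic / out$neutral
  attr(out, "n_excluded") <- sum(!eligible)
  out
}

#' Mean mKeima ratio of one sample
#'
#' Arithmetic mean of the per-event ratios (not the ratio of mean
#' intensities) over eligible events of the sample.
#'
#' @param table A `flow_event_table`.
#' @param sample Sample identifier.
#' @return Mean ratio.
#' @export
sample_mean_ratio <- function(table, sample) {
  rows <- event_ratios(table[table$sample == sample, , drop = FALSE])
  if (nrow(rows) == 0) stop("no eligible events for sample ", sample)
  mean(rows$ratio)
}

#' Scaling references for mKeima flux
#'
#' Anchors of the min--max flux scaling: the replicate-averaged mean ratio
#' of the low-reference condition (lysosomal acidification blocked with
#' bafilomycin) and of the high-reference condition (strongest induction,
#' highest rapalogue dose). The low anchor maps to 2 and the high anchor
#' to 100.
#'
#' @param x_low Replicate average of the low-reference condition.
#' @param x_high Replicate average of the high-reference condition.
#' @return A `scaling_refs` list with anchors `lo = 2`, `hi = 100`.
#' @export
scaling_refs <- function(x_low, x_high) {
  if (x_high == x_low) stop("x_high must differ from x_low")
  structure(list(x_low = x_low, x_high = x_high, lo = 2, hi = 100),
            class = "scaling_refs")
}

#' Min--max scaling of sample mean ratios
#'
#' Affine, order-preserving map
#' `x_sc = (x - x_low) / (x_high - x_low) * (100 - 2) + 2`,
#' sending the low-reference average to 2 and the high-reference average
#' to 100.
#'
#' @param sample_means Numeric vector of per-sample mean ratios.
#' @param refs A `scaling_refs`.
#' @return Scaled values.
#' @export
scale_ratios <- function(sample_means, refs) {
  stopifnot(inherits(refs, "scaling_refs"))
  (sample_means - refs$x_low) / (refs$x_high - refs$x_low) *
    (refs$hi - refs$lo) + refs$lo
}

#' Full mKeima flux computation
#'
#' Computes per-sample mean ratios, derives the scaling references from the
#' designated reference conditions (replicate averages), and returns both
#' per-replicate scaled values and per-condition averages of them.
#'
#' @param table A `flow_event_table` with `condition` filled in.
#' @param low_ref,high_ref Condition labels of the low (bafilomycin) and
#'   high (highest inducer dose) reference conditions.
#' @return A list: `samples` (data frame sample/condition/mean_ratio/
#'   scaled), `conditions` (condition averages of the scaled values),
#'   `refs`, and `n_excluded`.
#' @export
mkeima_flux <- function(table, low_ref, high_ref) {
  if (!all(c(low_ref, high_ref) %in% table$condition))
    stop("reference conditions not present in the table")
  rows <- event_ratios(table)
  agg <- stats::aggregate(ratio ~ sample + condition, rows, mean)
  names(agg)[names(agg) == "ratio"] <- "mean_ratio"
  refs <- scaling_refs(
    mean(agg$mean_ratio[agg$condition == low_ref]),
    mean(agg$mean_ratio[agg$condition == high_ref]))
  agg$scaled <- scale_ratios(agg$mean_ratio, refs)
  cond <- stats::aggregate(scaled ~ condition, agg, mean)
  list(samples = agg, conditions = cond, refs = refs,
       n_excluded = attr(rows, "n_excluded"))
}
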