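#' Distinct-species count versus bond-order cutoff
#'
#' Sweeps a grid of bond-order cutoffs and, for each cutoff, counts the
#' number of distinct chemical formulas seen in a sample of frames of each
#' replicate (pooled over the sampled frames of that replicate), then
#' averages across replicates. Too-low cutoffs inflate the count through
#' spurious near-contact "bonds"; too-high cutoffs inflate it by fragmenting
#' real molecules — the operating cutoff sits in the valley between.
#'
#' @param trajectories A list of replicates, each a list of [bond_frame()]s
#'   (a single replicate may be passed as a bare list of frames).
#' @param cutoffs Strictly increasing grid of thresholds in (0, 2).
#' @param frame_stride Sample every `frame_stride`-th frame (default 10).
#' @return A `data.frame` of class `cutoff_curve` with columns `cutoff`,
#'   `mean_distinct`, `sd_distinct` (sd across replicates; 0 when only one).
#' @export
distinct_species_curve <- function(trajectories,
                                   cutoffs = seq(0.1, 1.2, by = 0.1),
                                   frame_stride = 10L) {
  if (length(trajectories) > 0L && inherits(trajectories[[1L]], "bond_frame")) {
    trajectories <- list(trajectories)
  }
  if (length(trajectories) == 0L || any(!vapply(trajectories, length, 1L))) {
    stop("distinct_species_curve: empty trajectory")
  }
  stopifnot(all(diff(cutoffs) > 0), all(cutoffs > 0), all(cutoffs < 2))
  per_rep <- vapply(trajectories, function(frames) {
    sel <- seq(1L, length(frames), by = frame_stride)
    vapply(cutoffs, function(co) {
      forms <- unlist(lapply(frames[sel], function(fr) {
        unique(partition_frame(fr, co)$formulas)
      }))
      length(unique(forms))
    }, numeric(1))
  }, numeric(length(cutoffs)))
  per_rep <- matrix(per_rep, nrow = length(cutoffs))
  out <- data.frame(
    cutoff = cutoffs,
    mean_distinct = rowMeans(per_rep),
    sd_distinct = if (ncol(per_rep) >= 2L) apply(per_rep, 1L, stats::sd) else
      rep(0, length(cutoffs)))
  class(out) <- c("cutoff_curve", "data.frame")
  out
}

#' Select the operating cutoff from a sweep curve
#'
#' Returns the grid point with the minimal mean number of distinct species;
#' ties are broken toward the smallest cutoff. The selection is purely
#' count-based — chemical plausibility of the surviving species is the
#' analyst's call, and any cutoff can be supplied manually downstream.
#'
#' @param curve A `cutoff_curve` from [distinct_species_curve()].
#' @return The selected cutoff (scalar).
#' @export
select_cutoff <- function(curve) {
  stopifnot(nrow(curve) >= 1L)
  curve$cutoff[which.min(curve$mean_distinct)]
}
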