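#' Linear temperature-ramp schedule
#'
#' Per-frame temperatures of a linear heating protocol. The standard ramp
#' heats from 300 to 3500 K over 800 ps (4 K/ps); dumped at 0.25 ps/frame
#' that is 3200 frames. Temperatures are computed from the schedule, not
#' from thermostat readings, which the bonds dump does not carry.
#'
#' @param n_frames Number of dumped frames.
#' @param interval_ps Dump interval in ps.
#' @param T_start,T_max Start and cap temperature (K).
#' @param rate_K_per_ps Heating rate (K/ps).
#' @return List with `temperatures_K` (per frame, frame f at time
#'   `f * interval_ps`), `time_ps`, and `rate_K_per_ps`.
#' @export
ramp_schedule <- function(n_frames = 3200L, interval_ps = 0.25,
                          T_start = 300, T_max = 3500, rate_K_per_ps = 4) {
  time_ps <- seq_len(n_frames) * interval_ps
  list(temperatures_K = pmin(T_start + rate_K_per_ps * time_ps, T_max),
       time_ps = time_ps, rate_K_per_ps = rate_K_per_ps)
}

#' Heating rate implied by a ramp protocol
#'
#' @param T_start,T_end Temperature span (K).
#' @param duration_ps Ramp duration (ps).
#' @return Rate in K/ps (300 to 3500 K over 800 ps gives 4).
#' @export
heating_rate <- function(T_start = 300, T_end = 3500, duration_ps = 800) {
  (T_end - T_start) / duration_ps
}

#' Count intact reactant molecules along a ramp
#'
#' A molecule counts as intact when some species instance's element-colored
#' bonded graph at the operating cutoff is isomorphic to the template —
#' formula-preserving rearrangements do not count. Returns the per-frame
#' intact counts paired with the ramp temperatures.
#'
#' @param frames List of [bond_frame()]s.
#' @param template The reactant [parse_template()].
#' @param temperatures_K Per-frame temperatures (e.g. from [ramp_schedule()]).
#' @param cutoff Operating bond-order cutoff.
#' @param replicate_id Replicate label.
#' @return An object of class `ramp_series`: `temperatures_K`,
#'   `intact_counts`, `N0`, `replicate_id`.
#' @export
intact_count_series <- function(frames, template, temperatures_K, cutoff = 0.5,
                                replicate_id = "r1") {
  if (length(temperatures_K) != length(frames)) {
    stop("intact_count_series: need one temperature per frame")
  }
  counts <- vapply(frames, function(fr) {
    count_intact(fr, template, cutoff)
  }, integer(1))
  ramp_series(temperatures_K, counts, replicate_id)
}

count_intact <- function(frame, template, cutoff = 0.5) {
  p <- partition_frame(frame, cutoff)
  cand <- which(p$formulas == template$formula)
  if (length(cand) == 0L) return(0L)
  adj <- apply_cutoff(frame, cutoff)
  adj_idx <- cbind(match(adj$i, frame$atoms$id), match(adj$j, frame$atoms$id))
  n <- 0L
  for (ci in cand) {
    comp_idx <- which(p$membership == ci)
    if (!is.null(match_template(template, frame, comp_idx, adj_idx))) n <- n + 1L
  }
  n
}

#' @rdname intact_count_series
#' @param intact_counts Per-frame intact-molecule counts.
#' @export
ramp_series <- function(temperatures_K, intact_counts, replicate_id = "r1") {
  stopifnot(length(temperatures_K) == length(intact_counts),
            all(diff(temperatures_K) >= 0), all(intact_counts >= 0))
  structure(list(temperatures_K = as.numeric(temperatures_K),
                 intact_counts = as.numeric(intact_counts),
                 N0 = intact_counts[1L], replicate_id = replicate_id),
            class = "ramp_series")
}

#' Fit the degradation-onset decay curve
#'
#' Least-squares fit of a flat plateau with shifted exponential decay,
#' `N(T) = N0` for `T <= T0` and `N(T) = N0 * exp(-(T - T0)/scale)` beyond.
#' The functional form carries no physical meaning — it simply follows the
#' shape of intact-count-vs-temperature data and makes the onset read-off
#' well defined. The reported onset is the temperature where the fitted
#' curve equals `N0 - 1`, i.e. where the first molecule loses its intact
#' structure: `onset = T0 + scale * log(N0 / (N0 - 1))`.
#'
#' The objective is minimised by a coarse deterministic grid over
#' `(T0, scale)` followed by Nelder-Mead polishing, which tolerates the
#' non-smooth knot at `T0`.
#'
#' @param series A `ramp_series` whose counts contain a decrease.
#' @return An object of class `onset_fit`: `N0`, `T0_K`, `scale_K`,
#'   `onset_K`, `sse`.
#' @export
fit_decay <- function(series) {
  stopifnot(inherits(series, "ramp_series"))
  T <- series$temperatures_K
  y <- series$intact_counts
  N0 <- series$N0
  if (!any(y < N0)) {
    stop("fit_decay: counts never decrease; nothing to fit (range ",
         paste(range(y), collapse = "-"), ")")
  }
  obj <- function(par) {
    T0 <- par[1L]; s <- exp(par[2L])
    pred <- ifelse(T <= T0, N0, N0 * exp(-(T - T0) / s))
    sum((pred - y)^2)
  }
  drop_idx <- which(y < N0)[1L]
  t0_grid <- unique(stats::quantile(
    T[max(1L, drop_idx - 10L):length(T)], probs = seq(0, 0.6, by = 0.02),
    names = FALSE))
  s_grid <- log(c(5, 10, 25, 50, 100, 150, 250, 500, 1000))
  grid <- expand.grid(T0 = t0_grid, ls = s_grid)
  sse <- vapply(seq_len(nrow(grid)), function(r) {
    obj(c(grid$T0[r], grid$ls[r]))
  }, numeric(1))
  best <- as.numeric(grid[which.min(sse), ])
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  T0 <- fit$par[1L]; s <- exp(fit$par[2L])
  onset <- T0 + s * log(N0 / (N0 - 1))
  structure(list(N0 = N0, T0_K = T0, scale_K = s, onset_K = onset,
                 sse = fit$value, replicate_id = series$replicate_id),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("onset_fit [%s]: N0=%g, T0=%.1f K, scale=%.1f K, onset=%.1f K (sse %.3g)\n",
              x$replicate_id, x$N0, x$T0_K, x$scale_K, x$onset_K, x$sse))
  invisible(x)
}

#' Pool replicate ramp series for a joint fit
#'
#' Averages the intact counts of replicate ramps over a shared temperature
#' schedule, so one decay curve can be fitted to all replicates jointly
#' (the replicate spread is still reported from per-replicate fits via
#' [aggregate_onsets()]).
#'
#' @param series_list List of `ramp_series` with identical temperature grids.
#' @return A pooled `ramp_series`.
#' @export
pool_ramp_series <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  temps <- series_list[[1L]]$temperatures_K
  for (s in series_list) {
    if (!isTRUE(all.equal(s$temperatures_K, temps))) {
      stop("pool_ramp_series: temperature grids differ")
    }
  }
  counts <- rowMeans(vapply(series_list, `[[`, "intact_counts",
                            FUN.VALUE = numeric(length(temps))))
  ramp_series(temps, counts, replicate_id = "pooled")
}

#' Aggregate onset temperatures across replicates
#'
#' Arithmetic mean and sample standard deviation of the per-replicate onset
#' temperatures; the sd is `NA` with fewer than two fits.
#'
#' @param fits List of `onset_fit` objects (or a single one).
#' @return List with `mean_onset_K`, `sd_onset_K`, `n`, `onsets_K`.
#' @export
aggregate_onsets <- function(fits) {
  if (inherits(fits, "onset_fit")) fits <- list(fits)
  onsets <- vapply(fits, function(f) f$onset_K, numeric(1))
  list(mean_onset_K = mean(onsets),
       sd_onset_K = if (length(onsets) >= 2L) stats::sd(onsets) else NA_real_,
       n = length(onsets), onsets_K = onsets)
}

#' Onset table in the on-disk schema
#'
#' @param fits List of `onset_fit` objects.
#' @return `data.frame` with columns `replicate`, `N0`, `T0_K`, `scale_K`,
#'   `onset_K`.
#' @export
onset_table <- function(fits) {
  if (inherits(fits, "onset_fit")) fits <- list(fits)
  data.frame(replicate = vapply(fits, function(f) f$replicate_id, character(1)),
             N0 = vapply(fits, function(f) f$N0, numeric(1)),
             T0_K = vapply(fits, function(f) f$T0_K, numeric(1)),
             scale_K = vapply(fits, function(f) f$scale_K, numeric(1)),
             onset_K = vapply(fits, function(f) f$onset_K, numeric(1)))
}
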