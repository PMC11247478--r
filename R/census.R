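#' Species timelines across a trajectory
#'
#' Runs the per-frame species identification over a whole trajectory and
#' assembles, per canonical formula, the per-frame instance counts together
#' with per-instance (exact atom-id set) cumulative lifetimes. An instance is
#' identified by its exact atom set: a species that gains or loses any atom
#' starts a new instance. The cumulative lifetime of an instance is the
#' number of frames in which that exact atom set is a species, times the
#' frame interval — total occupancy over the whole trajectory, not the
#' longest contiguous run.
#'
#' @param frames List of [bond_frame()]s with a constant atom set.
#' @param cutoff Bond-order cutoff (default 0.5).
#' @param meta A [trajectory_meta()]; frame interval defaults to 0.25 ps.
#' @return An object of class `species_timelines` with fields
#'   `formulas`, `counts` (formula x frame matrix), `instances` (data.frame:
#'   `key`, `formula`, `n_frames`, `first_frame`, `last_frame`,
#'   `lifetime_ps`), `frame_partitions` (per-frame keys + membership, used by
#'   the pathway tracer), `n_frames`, `frame_interval_ps`, `time_ps`.
#' @export
build_timelines <- function(frames, cutoff = 0.5, meta = trajectory_meta()) {
  if (length(frames) == 0L) stop("build_timelines: no frames")
  ids0 <- frames[[1L]]$atoms$id
  n_frames <- length(frames)
  interval_ps <- frame_interval_ps(meta)
  partitions <- vector("list", n_frames)
  per_frame_tab <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (!identical(frames[[f]]$atoms$id, ids0)) {
      stop("build_timelines: atom set changes at frame ", f,
           " (atom conservation violated)")
    }
    p <- partition_frame(frames[[f]], cutoff)
    partitions[[f]] <- list(keys = p$keys, formulas = p$formulas,
                            membership = p$membership)
    per_frame_tab[[f]] <- p
  }
  all_keys <- unlist(lapply(per_frame_tab, `[[`, "keys"))
  all_forms <- unlist(lapply(per_frame_tab, `[[`, "formulas"))
  frame_of <- rep.int(seq_len(n_frames),
                      vapply(per_frame_tab, function(p) length(p$keys), 1L))
  ku <- !duplicated(all_keys)
  inst <- data.frame(
    key = all_keys[ku],
    formula = all_forms[ku],
    n_frames = as.integer(tapply(frame_of, all_keys, length)[all_keys[ku]]),
    first_frame = as.integer(tapply(frame_of, all_keys, min)[all_keys[ku]]),
    last_frame = as.integer(tapply(frame_of, all_keys, max)[all_keys[ku]]),
    stringsAsFactors = FALSE)
  inst$lifetime_ps <- inst$n_frames * interval_ps
  rownames(inst) <- NULL
  formulas <- sort(unique(all_forms))
  counts <- matrix(0L, nrow = length(formulas), ncol = n_frames,
                   dimnames = list(formulas, NULL))
  fi <- match(all_forms, formulas)
  tab <- table(factor(fi, levels = seq_along(formulas)), factor(frame_of, levels = seq_len(n_frames)))
  counts[] <- as.integer(tab)
  structure(list(formulas = formulas, counts = counts, instances = inst,
                 frame_partitions = partitions, atom_ids = ids0,
                 n_frames = n_frames, frame_interval_ps = interval_ps,
                 time_ps = frames_time_ps(frames, interval_ps),
                 cutoff = cutoff, replicate_id = meta$replicate_id),
            class = "species_timelines")
}

## frame times in ps, from the frames' own timestamps when consistent
frames_time_ps <- function(frames, interval_ps) {
  t <- vapply(frames, function(f) f$time_fs, numeric(1)) / 1000
  if (length(unique(round(diff(t), 9))) > 1L || any(!is.finite(t))) {
    t <- seq_along(frames) * interval_ps
  }
  t
}

#' @export
print.species_timelines <- function(x, ...) {
  cat(sprintf("species_timelines: %d frames (%.4g ps/frame), %d formulas, %d instances\n",
              x$n_frames, x$frame_interval_ps, length(x$formulas), nrow(x$instances)))
  invisible(x)
}

#' Remove short-lived (flicker) species
#'
#' A formula is retained when at least one of its atom-set instances has a
#' cumulative lifetime of at least `threshold_ps` over the whole trajectory.
#' The default of 12.5 ps corresponds to 50 output frames at the standard
#' 0.25 ps dump interval and removes species that appear and disappear
#' repeatedly through bond-order fluctuation around the cutoff. The filter is
#' idempotent and monotone: raising the threshold never adds species.
#'
#' @param timelines A `species_timelines` from [build_timelines()].
#' @param threshold_ps Minimum cumulative lifetime in ps (>= 0).
#' @return A filtered `species_timelines` (counts and instances restricted to
#'   retained formulas; frame partitions kept for tracing).
#' @export
lifetime_filter <- function(timelines, threshold_ps = 12.5) {
  stopifnot(inherits(timelines, "species_timelines"), threshold_ps >= 0)
  inst <- timelines$instances
  ok_form <- unique(inst$formula[inst$lifetime_ps >= threshold_ps])
  keep <- timelines$formulas %in% ok_form
  out <- timelines
  out$formulas <- timelines$formulas[keep]
  out$counts <- timelines$counts[keep, , drop = FALSE]
  out$instances <- inst[inst$formula %in% ok_form, , drop = FALSE]
  rownames(out$instances) <- NULL
  attr(out, "lifetime_threshold_ps") <- threshold_ps
  out
}

#' Rank reaction products by trailing-window prevalence
#'
#' Prevalence of a product is its mean instance count over the last
#' `window_ps` of the trajectory, averaged across replicates. Feed species
#' (the reactant formula, O2) are included by default — dominant-species
#' overviews conventionally show them — and can be excluded for
#' product-focused reports.
#'
#' @param timelines A `species_timelines` or a list of them (replicates).
#' @param window_ps Trailing averaging window in ps (default 100).
#' @param exclude Character vector of formulas to drop (e.g. feed species).
#' @param top_k Number of entries to report (default 10); `Inf` for all.
#' @return A `data.frame` of class `product_ranking` with columns `formula`
#'   and `mean_count`, sorted by descending mean count (ties lexicographic).
#' @export
rank_products <- function(timelines, window_ps = 100, exclude = character(0),
                          top_k = 10L) {
  if (inherits(timelines, "species_timelines")) timelines <- list(timelines)
  stopifnot(length(timelines) >= 1L, window_ps > 0)
  per_rep <- lapply(timelines, function(tl) {
    n_win <- as.integer(round(window_ps / tl$frame_interval_ps))
    if (n_win > tl$n_frames) {
      stop("rank_products: window (", window_ps, " ps) longer than trajectory (",
           tl$n_frames * tl$frame_interval_ps, " ps)")
    }
    idx <- seq.int(tl$n_frames - n_win + 1L, tl$n_frames)
    rowMeans(tl$counts[, idx, drop = FALSE])
  })
  formulas <- sort(unique(unlist(lapply(per_rep, names))))
  m <- vapply(per_rep, function(v) {
    out <- stats::setNames(numeric(length(formulas)), formulas)
    out[names(v)] <- v
    out
  }, numeric(length(formulas)))
  m <- matrix(m, nrow = length(formulas), dimnames = list(formulas, NULL))
  mean_count <- rowMeans(m)
  keep <- !(formulas %in% exclude)
  out <- data.frame(formula = formulas[keep], mean_count = mean_count[keep])
  out <- out[order(-out$mean_count, out$formula), , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  class(out) <- c("product_ranking", "data.frame")
  attr(out, "window_ps") <- window_ps
  out
}

#' Intermediates of a product by shared atoms
#'
#' Collects, for every instance of the product present at the final frame,
#' all species instances that at any earlier frame shared at least one atom
#' with that product instance, applies the lifetime filter, and reports the
#' surviving formulas with their first/last appearance times.
#'
#' @param timelines A `species_timelines`.
#' @param product Canonical formula of the product (must be present at the
#'   trajectory's final frame).
#' @param threshold_ps Lifetime threshold applied to candidate intermediates.
#' @return A `data.frame` with columns `formula`, `first_ps`, `last_ps`,
#'   deduplicated by formula.
#' @export
find_intermediates <- function(timelines, product, threshold_ps = 12.5) {
  tl <- timelines
  last <- tl$frame_partitions[[tl$n_frames]]
  prod_idx <- which(last$formulas == product)
  if (length(prod_idx) == 0L) {
    stop("find_intermediates: product ", product, " absent at final frame")
  }
  keys <- character(0)
  for (pi in prod_idx) {
    atoms_idx <- which(last$membership == pi)
    for (f in seq_len(tl$n_frames)) {
      part <- tl$frame_partitions[[f]]
      keys <- c(keys, part$keys[unique(part$membership[atoms_idx])])
    }
  }
  keys <- unique(keys)
  inst <- tl$instances[tl$instances$key %in% keys, , drop = FALSE]
  inst <- inst[inst$lifetime_ps >= threshold_ps, , drop = FALSE]
  if (nrow(inst) == 0L) {
    return(data.frame(formula = character(0), first_ps = numeric(0),
                      last_ps = numeric(0)))
  }
  agg_first <- tapply(inst$first_frame, inst$formula, min)
  agg_last <- tapply(inst$last_frame, inst$formula, max)
  forms <- sort(names(agg_first))
  data.frame(formula = forms,
             first_ps = tl$time_ps[as.integer(agg_first[forms])],
             last_ps = tl$time_ps[as.integer(agg_last[forms])],
             row.names = NULL)
}

#' Census table across frames
#'
#' Long-format census (one row per frame x formula with nonzero count),
#' ready for [write_table()].
#'
#' @param timelines A `species_timelines`.
#' @return `data.frame` with columns `replicate`, `frame`, `time_ps`,
#'   `formula`, `count`.
#' @export
census_table <- function(timelines) {
  tl <- timelines
  idx <- which(tl$counts > 0L, arr.ind = TRUE)
  data.frame(replicate = tl$replicate_id,
             frame = as.integer(idx[, 2L]),
             time_ps = tl$time_ps[idx[, 2L]],
             formula = tl$formulas[idx[, 1L]],
             count = as.integer(tl$counts[idx]),
             row.names = NULL)
}
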