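#' Trace product atoms back through the trajectory
#'
#' For one product instance at the final frame, reports the species instance
#' containing each product atom at every frame — the backbone of tracing a
#' product back to its reactants. The trace is total: every atom is covered
#' in every frame (atom conservation), otherwise an error is raised.
#'
#' @param timelines A `species_timelines` from [build_timelines()].
#' @param product_key Instance key (`"id1-id2-..."`) of the product at the
#'   final frame, or a formula, in which case the first instance with that
#'   formula at the final frame is traced.
#' @return List with `atom_ids` (the product's atoms), `keys` (atoms x frames
#'   matrix of containing-instance keys) and `formulas` (same shape, Hill
#'   formulas of the containing species).
#' @export
product_atom_trace <- function(timelines, product_key) {
  tl <- timelines
  last <- tl$frame_partitions[[tl$n_frames]]
  ci <- which(last$keys == product_key)
  if (length(ci) == 0L) ci <- which(last$formulas == product_key)[1L]
  if (length(ci) == 0L || is.na(ci)) {
    stop("product_atom_trace: no instance '", product_key, "' at final frame")
  }
  atom_pos <- which(last$membership == ci)
  n <- length(atom_pos)
  keys <- matrix(NA_character_, nrow = n, ncol = tl$n_frames)
  forms <- matrix(NA_character_, nrow = n, ncol = tl$n_frames)
  for (f in seq_len(tl$n_frames)) {
    part <- tl$frame_partitions[[f]]
    m <- part$membership[atom_pos]
    if (anyNA(m)) {
      stop("product_atom_trace: atom missing from frame ", f,
           " (conservation violation)")
    }
    keys[, f] <- part$keys[m]
    forms[, f] <- part$formulas[m]
  }
  list(atom_ids = tl$atom_ids[atom_pos], keys = keys, formulas = forms)
}

#' Ordered bond events behind one product instance
#'
#' Selects every committed bond event whose atom pair touches the product's
#' atoms — including donor events such as the hydroxyl H-loss whose H atom
#' later joins ethyl hydroperoxide — and orders them by time (ties broken by
#' label).
#'
#' @param product_atoms Atom ids of the product instance (e.g. the
#'   `atom_ids` of [product_atom_trace()]).
#' @param events Combined events `data.frame` ([detect_events_all()] plus
#'   [detect_new_bonds()]).
#' @return The selected events, time-ordered, with a `descriptor` column
#'   (`"<label> <event_type>"`).
#' @export
event_sequence <- function(product_atoms, events) {
  hit <- events$i %in% product_atoms | events$j %in% product_atoms
  out <- events[hit, , drop = FALSE]
  out <- out[order(out$time_ps, out$label), , drop = FALSE]
  out$descriptor <- paste(out$label, out$event_type)
  rownames(out) <- NULL
  out
}

#' Aggregate event sequences into a dominant pathway
#'
#' Summarises event sequences from many product instances (pooled by product
#' formula across replicates) into one ordered pathway: steps are ordered by
#' the median time of their first occurrence, and each step carries the
#' fraction of instances containing it (support). Because near-simultaneous
#' steps can swap order between instances, the pairwise precedence fractions
#' are also reported, and conflicts between the median order and the
#' precedence majority are flagged rather than forced into a total order.
#'
#' @param sequences List of event sequences ([event_sequence()] outputs); at
#'   least one.
#' @param product Product formula the sequences belong to (label only).
#' @return An object of class `pathway_summary`: `product`, `n_instances`,
#'   `steps` (`descriptor`, `median_time_ps`, `support`), `precedence`
#'   (`first`, `second`, `frac_first_before_second`, `conflicts_median`).
#' @export
dominant_pathway <- function(sequences, product = NA_character_) {
  stopifnot(length(sequences) >= 1L)
  first_times <- lapply(sequences, function(s) {
    if (nrow(s) == 0L) return(stats::setNames(numeric(0), character(0)))
    tapply(s$time_ps, s$descriptor, min)
  })
  descs <- sort(unique(unlist(lapply(first_times, names))))
  if (length(descs) == 0L) {
    return(structure(list(product = product, n_instances = length(sequences),
                          steps = data.frame(descriptor = character(0),
                                             median_time_ps = numeric(0),
                                             support = numeric(0)),
                          precedence = data.frame(first = character(0),
                                                  second = character(0),
                                                  frac_first_before_second = numeric(0),
                                                  conflicts_median = logical(0))),
                     class = "pathway_summary"))
  }
  med <- vapply(descs, function(d) {
    stats::median(unlist(lapply(first_times, function(ft) ft[d])), na.rm = TRUE)
  }, numeric(1))
  supp <- vapply(descs, function(d) {
    mean(vapply(first_times, function(ft) d %in% names(ft), logical(1)))
  }, numeric(1))
  ord <- order(med, descs)
  steps <- data.frame(descriptor = descs[ord], median_time_ps = unname(med[ord]),
                      support = unname(supp[ord]))
  prec <- list(); k <- 0L
  if (length(descs) >= 2L) {
    for (a in seq_len(nrow(steps) - 1L)) {
      for (b in seq.int(a + 1L, nrow(steps))) {
        da <- steps$descriptor[a]; db <- steps$descriptor[b]
        both <- vapply(first_times, function(ft) {
          da %in% names(ft) && db %in% names(ft)
        }, logical(1))
        if (!any(both)) next
        frac <- mean(vapply(first_times[both], function(ft) {
          ft[da] < ft[db]
        }, logical(1)))
        k <- k + 1L
        prec[[k]] <- data.frame(first = da, second = db,
                                frac_first_before_second = frac,
                                conflicts_median = frac < 0.5)
      }
    }
  }
  precedence <- if (k > 0L) do.call(rbind, prec) else
    data.frame(first = character(0), second = character(0),
               frac_first_before_second = numeric(0),
               conflicts_median = logical(0))
  rownames(precedence) <- NULL
  structure(list(product = product, n_instances = length(sequences),
                 steps = steps, precedence = precedence),
            class = "pathway_summary")
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat(sprintf("pathway_summary: %s (%d instance%s)\n",
              x$product, x$n_instances, if (x$n_instances == 1L) "" else "s"))
  if (nrow(x$steps) == 0L) {
    cat("  (no events)\n")
    return(invisible(x))
  }
  for (r in seq_len(nrow(x$steps))) {
    cat(sprintf("  %d. %-28s median %7.2f ps  support %.2f\n", r,
                x$steps$descriptor[r], x$steps$median_time_ps[r],
                x$steps$support[r]))
  }
  confl <- x$precedence[x$precedence$conflicts_median, , drop = FALSE]
  if (nrow(confl) > 0L) {
    cat("  precedence conflicts with median order:\n")
    for (r in seq_len(nrow(confl))) {
      cat(sprintf("    %s before %s in only %.0f%% of instances\n",
                  confl$first[r], confl$second[r],
                  100 * confl$frac_first_before_second[r]))
    }
  }
  invisible(x)
}

#' Pathways for every instance of a product formula
#'
#' Convenience wrapper: finds all final-frame instances of `product` in each
#' replicate, traces them, extracts each instance's event sequence and
#' aggregates the sequences into a dominant pathway.
#'
#' @param timelines A `species_timelines` or list of them (replicates).
#' @param events Matching events `data.frame` or list of them (one per
#'   replicate, same order).
#' @param product Product formula.
#' @return A `pathway_summary`.
#' @export
product_pathway <- function(timelines, events, product) {
  if (inherits(timelines, "species_timelines")) {
    timelines <- list(timelines)
    events <- list(events)
  }
  seqs <- list()
  for (r in seq_along(timelines)) {
    tl <- timelines[[r]]
    last <- tl$frame_partitions[[tl$n_frames]]
    for (ci in which(last$formulas == product)) {
      atoms <- tl$atom_ids[last$membership == ci]
      seqs[[length(seqs) + 1L]] <- event_sequence(atoms, events[[r]])
    }
  }
  if (length(seqs) == 0L) {
    stop("product_pathway: no instance of ", product, " at final frame")
  }
  dominant_pathway(seqs, product = product)
}
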