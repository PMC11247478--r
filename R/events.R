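## ---- element-colored graph isomorphism helpers -----------------------------

## deterministic integer color per element, shared by both graphs
element_colors <- function(...) {
  els <- sort(unique(unlist(list(...))))
  function(e) match(e, els)
}

template_graph <- function(template) {
  n <- nrow(template$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  e <- cbind(match(template$bonds$i, template$atoms$idx),
             match(template$bonds$j, template$atoms$idx))
  igraph::add_edges(g, t(e))
}

## canonical form (edge set + colors under BLISS canonical labeling);
## two element-colored graphs are isomorphic iff their forms are identical
canon_form <- function(g, colors) {
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  gc <- igraph::permute(g, lab)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  col_c <- integer(length(colors)); col_c[lab] <- colors
  list(labeling = lab, edges = el, colors = col_c)
}

## map template atom indices onto one connected component of a frame, or NULL.
## comp_idx: positions (into frame$atoms) of the component's atoms.
## Ambiguity between automorphic matches is resolved by the deterministic
## canonical labeling, anchored on atom order (lowest atom id first).
match_template <- function(template, frame, comp_idx, adj_edges_idx) {
  n <- length(comp_idx)
  if (n != nrow(template$atoms)) return(NULL)
  colfun <- element_colors(template$atoms$element, frame$atoms$element)
  tcol <- colfun(template$atoms$element)
  ccol <- colfun(frame$atoms$element[comp_idx])
  gt <- template_graph(template)
  local <- match(adj_edges_idx[, 1L], comp_idx)
  local2 <- match(adj_edges_idx[, 2L], comp_idx)
  keep <- !is.na(local) & !is.na(local2)
  gc <- igraph::make_empty_graph(n = n, directed = FALSE)
  gc <- igraph::add_edges(gc, t(cbind(local[keep], local2[keep])))
  if (igraph::ecount(gc) != igraph::ecount(gt)) return(NULL)
  ft <- canon_form(gt, tcol)
  fc <- canon_form(gc, ccol)
  if (!identical(ft$edges, fc$edges) || !identical(ft$colors, fc$colors)) {
    return(NULL)
  }
  ## template v at canonical rank ft$labeling[v]; component vertex at same rank
  inv_c <- integer(n); inv_c[fc$labeling] <- seq_len(n)
  map_local <- inv_c[ft$labeling]
  frame$atoms$id[comp_idx[map_local]]
}

## ---- labeled-bond mapping --------------------------------------------------

#' Map template-labeled bonds onto molecule copies in a frame
#'
#' Identifies every intact copy of the template in the frame by
#' element-colored graph matching at the operating cutoff and binds each
#' labeled template bond (e.g. `"1A"`, `"3B'"`) to its concrete atom-id
#' pair in each copy. Copies already reacted at this frame do not match and
#' are reported in a warning. Automorphic ambiguity (e.g. the two equivalent
#' rings of a symmetric dimer) is resolved by the deterministic canonical
#' labeling, so the primed/unprimed assignment is arbitrary but stable.
#'
#' @param frame The reference [bond_frame()] (normally the initial frame).
#' @param template A [parse_template()] molecule with labeled bonds.
#' @param cutoff Operating bond-order cutoff.
#' @param expected_copies If given, warn when the matched copy count differs.
#' @return `data.frame` with columns `label`, `molecule_index` (1-based, in
#'   order of the copy's smallest atom id), `i`, `j` (global atom ids).
#' @export
map_labeled_bonds <- function(frame, template, cutoff = 0.5,
                              expected_copies = NULL) {
  labs <- template$bonds[!is.na(template$bonds$label), , drop = FALSE]
  if (nrow(labs) == 0L) stop("map_labeled_bonds: template has no labeled bonds")
  p <- partition_frame(frame, cutoff)
  adj <- apply_cutoff(frame, cutoff)
  adj_idx <- cbind(match(adj$i, frame$atoms$id), match(adj$j, frame$atoms$id))
  cand <- which(p$formulas == template$formula)
  rows <- list()
  mi <- 0L
  n_fail <- 0L
  for (ci in cand) {
    comp_idx <- which(p$membership == ci)
    map <- match_template(template, frame, comp_idx, adj_idx)
    if (is.null(map)) { n_fail <- n_fail + 1L; next }
    mi <- mi + 1L
    gi <- map[match(labs$i, template$atoms$idx)]
    gj <- map[match(labs$j, template$atoms$idx)]
    rows[[mi]] <- data.frame(label = labs$label, molecule_index = mi,
                             i = pmin(gi, gj), j = pmax(gi, gj))
  }
  if (n_fail > 0L) {
    warning("map_labeled_bonds: ", n_fail, " component(s) with formula ",
            template$formula, " did not match the template graph")
  }
  if (!is.null(expected_copies) && mi != expected_copies) {
    warning("map_labeled_bonds: matched ", mi, " copies, expected ",
            expected_copies)
  }
  if (mi == 0L) {
    return(data.frame(label = character(0), molecule_index = integer(0),
                      i = integer(0), j = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- order series and state classification ---------------------------------

#' Per-frame bond order of one atom pair
#'
#' @param frames List of [bond_frame()]s.
#' @param i,j Atom ids (order irrelevant). A pair absent from a frame's bond
#'   table has order 0 in that frame.
#' @return Numeric vector, one order per frame.
#' @export
order_series <- function(frames, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  vapply(frames, function(fr) {
    hit <- which(fr$bonds$i == lo & fr$bonds$j == hi)
    if (length(hit) == 0L) 0 else fr$bonds$order[hit[1L]]
  }, numeric(1))
}

#' Bond-order series for every labeled bond instance
#'
#' @param frames List of [bond_frame()]s.
#' @param mapping Output of [map_labeled_bonds()].
#' @param meta A [trajectory_meta()] for frame times.
#' @return List of `labeled_bond_instance` objects (fields `label`,
#'   `molecule_index`, `i`, `j`, `orders`, `time_ps`).
#' @export
bond_series <- function(frames, mapping, meta = trajectory_meta()) {
  tp <- frames_time_ps(frames, frame_interval_ps(meta))
  lapply(seq_len(nrow(mapping)), function(r) {
    structure(list(label = mapping$label[r],
                   molecule_index = mapping$molecule_index[r],
                   i = mapping$i[r], j = mapping$j[r],
                   orders = order_series(frames, mapping$i[r], mapping$j[r]),
                   time_ps = tp),
              class = "labeled_bond_instance")
  })
}

#' Classify a bond-order series into bonding states
#'
#' Bond orders of roughly 0, 1 and 2 correspond to no bond, a single bond
#' and a double bond. The state thresholds sit at the midpoints: `absent`
#' below 0.5, `single` in [0.5, 1.5), `double` at or above 1.5. The lower
#' threshold equals the default species cutoff so bonded-graph membership
#' and bond-state tracking agree.
#'
#' @param orders Numeric vector of bond orders.
#' @return Character vector of states (`"absent"`, `"single"`, `"double"`).
#' @export
classify_state_series <- function(orders) {
  stopifnot(length(orders) >= 1L)
  ifelse(orders < 0.5, "absent", ifelse(orders < 1.5, "single", "double"))
}

event_type_for <- function(from, to) {
  if (to == "absent") return("dissociation")
  if (from == "absent") return("formation")
  if (from == "single" && to == "double") return("single_to_double")
  if (from == "double" && to == "single") return("double_to_single")
  stop("unreachable state transition ", from, "->", to)
}

#' Detect committed bond events in one bond's series
#'
#' A state change is committed only when the new state persists for at least
#' `persistence_frames` consecutive frames (hysteresis mirroring the 50-frame
#' lifetime filter); shorter excursions are treated as bond-order vibration
#' and produce no event. The event time is the first frame of the new state.
#'
#' @param instance A `labeled_bond_instance` from [bond_series()], or any
#'   list with fields `orders`, `time_ps` and optionally `label`,
#'   `molecule_index`, `i`, `j`.
#' @param persistence_frames Frames a new state must persist (default 50).
#' @return `data.frame` with columns `label`, `molecule_index`, `event_type`,
#'   `time_ps`, `frame`, `i`, `j` (possibly zero rows).
#' @export
detect_events <- function(instance, persistence_frames = 50L) {
  stopifnot(persistence_frames >= 1L)
  states <- classify_state_series(instance$orders)
  r <- rle(states)
  committed <- r$values[1L]
  first_frame <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  out <- list()
  k <- 0L
  for (run in seq_along(r$values)[-1L]) {
    if (r$lengths[run] >= persistence_frames && r$values[run] != committed) {
      k <- k + 1L
      out[[k]] <- data.frame(
        label = instance$label %||% NA_character_,
        molecule_index = instance$molecule_index %||% NA_integer_,
        event_type = event_type_for(committed, r$values[run]),
        time_ps = instance$time_ps[first_frame[run]],
        frame = first_frame[run],
        i = instance$i %||% NA_integer_, j = instance$j %||% NA_integer_)
      committed <- r$values[run]
    }
  }
  if (k == 0L) {
    return(data.frame(label = character(0), molecule_index = integer(0),
                      event_type = character(0), time_ps = numeric(0),
                      frame = integer(0), i = integer(0), j = integer(0)))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname detect_events
#' @param instances List of `labeled_bond_instance`s.
#' @return For `detect_events_all`: one combined events `data.frame`, sorted
#'   by time then label.
#' @export
detect_events_all <- function(instances, persistence_frames = 50L) {
  evs <- lapply(instances, detect_events, persistence_frames = persistence_frames)
  out <- do.call(rbind, evs)
  if (is.null(out) || nrow(out) == 0L) return(detect_events(list(orders = 1, time_ps = 0)))
  out <- out[order(out$time_ps, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-frame bonded counts per label
#'
#' Counts, for every label, how many of its instances are in a bonded state
#' (single or double) at each frame. With `aggregate_primed = TRUE` the
#' primed/unprimed label pairs of a symmetric dimer (`1B`/`1B'`) are summed
#' under the unprimed name.
#'
#' @param instances List of `labeled_bond_instance`s from [bond_series()].
#' @param aggregate_primed Merge `X` and `X'` labels (default `FALSE`).
#' @return Matrix: rows = labels (sorted), columns = frames.
#' @export
bond_count_series <- function(instances, aggregate_primed = FALSE) {
  stopifnot(length(instances) >= 1L)
  labs <- vapply(instances, function(x) x$label, character(1))
  if (aggregate_primed) labs <- sub("'+$", "", labs)
  n_frames <- length(instances[[1L]]$orders)
  ulabs <- sort(unique(labs))
  m <- matrix(0L, nrow = length(ulabs), ncol = n_frames,
              dimnames = list(ulabs, NULL))
  for (k in seq_along(instances)) {
    bonded <- classify_state_series(instances[[k]]$orders) != "absent"
    m[labs[k], ] <- m[labs[k], ] + as.integer(bonded)
  }
  m
}

#' Detect formation of new (non-template) bonds
#'
#' Scans all atom pairs that were not bonded in the reference frame for
#' committed formation events, restricted to watched element pairs (e.g.
#' the C-O bond formed when an ethyl radical attacks O2, or the HO-H bond of
#' nascent water). The same persistence rule as [detect_events()] applies.
#'
#' @param frames List of [bond_frame()]s.
#' @param watch Element-pair patterns: character like `"C-O"` or a list of
#'   two-element character vectors.
#' @param cutoff Operating cutoff defining "bonded" in the reference frame.
#' @param persistence_frames Commitment persistence (default 50).
#' @param meta A [trajectory_meta()].
#' @param baseline_frame Index of the reference frame (default 1).
#' @return Events `data.frame` as in [detect_events()]; `label` holds the
#'   element-pair descriptor (e.g. `"C-O"`), `molecule_index` is `NA`.
#' @export
detect_new_bonds <- function(frames, watch = list(c("C", "O"), c("H", "O")),
                             cutoff = 0.5, persistence_frames = 50L,
                             meta = trajectory_meta(), baseline_frame = 1L) {
  watch <- vapply(watch, function(w) {
    if (length(w) == 1L) w else paste(sort(w), collapse = "-")
  }, character(1))
  ref <- frames[[baseline_frame]]
  base <- ref$bonds[ref$bonds$order >= cutoff, , drop = FALSE]
  base_key <- paste(base$i, base$j)
  all_pairs <- unique(do.call(rbind, lapply(frames, function(fr) {
    fr$bonds[fr$bonds$order >= 0.5, c("i", "j"), drop = FALSE]
  })))
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) return(empty_events())
  is_new <- !(paste(all_pairs$i, all_pairs$j) %in% base_key)
  cand <- all_pairs[is_new, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_events())
  el <- stats::setNames(ref$atoms$element, as.character(ref$atoms$id))
  pat <- paste(pmin(el[as.character(cand$i)], el[as.character(cand$j)]),
               pmax(el[as.character(cand$i)], el[as.character(cand$j)]),
               sep = "-")
  cand <- cand[pat %in% watch, , drop = FALSE]
  pat <- pat[pat %in% watch]
  if (nrow(cand) == 0L) return(empty_events())
  tp <- frames_time_ps(frames, frame_interval_ps(meta))
  evs <- lapply(seq_len(nrow(cand)), function(r) {
    inst <- list(label = pat[r], molecule_index = NA_integer_,
                 i = cand$i[r], j = cand$j[r],
                 orders = order_series(frames, cand$i[r], cand$j[r]),
                 time_ps = tp)
    ev <- detect_events(inst, persistence_frames)
    ev[ev$event_type == "formation", , drop = FALSE]
  })
  out <- do.call(rbind, evs)
  if (nrow(out) == 0L) return(empty_events())
  out <- out[order(out$time_ps, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(label = character(0), molecule_index = integer(0),
             event_type = character(0), time_ps = numeric(0),
             frame = integer(0), i = integer(0), j = integer(0))
}

#' Events table in the on-disk schema
#'
#' @param events Events `data.frame` (from [detect_events_all()] and/or
#'   [detect_new_bonds()]).
#' @param replicate Replicate label.
#' @return `data.frame` with columns `replicate`, `molecule_index`,
#'   `bond_label_or_pair`, `event_type`, `time_ps`.
#' @export
events_table <- function(events, replicate = "r1") {
  data.frame(replicate = replicate,
             molecule_index = events$molecule_index,
             bond_label_or_pair = ifelse(is.na(events$label),
                                         paste0(events$i, "-", events$j),
                                         events$label),
             event_type = events$event_type,
             time_ps = events$time_ps)
}
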