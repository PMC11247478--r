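## run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

## hand-rolled union-find partition: membership ints for n atoms under edges
## (kept separate from the igraph-based analysis path on purpose: the
## generator's ground-truth bookkeeping must not reuse the code it validates)
uf_partition <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ei)) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Assemble an initial simulation box
#'
#' Places `n_molecules` copies of the template plus `n_O2` oxygen molecules
#' in disjoint 1-based atom-id blocks, every bond at its nominal order.
#' 50 copies of the C19H30O3 monomer with 300 O2 gives 3200 atoms; 50 copies
#' of the C26H34O4 dimer with 300 O2 gives 3800.
#'
#' @param template Reactant [parse_template()].
#' @param n_molecules Number of template copies (>= 0).
#' @param n_O2 Number of O2 molecules (>= 0).
#' @return An object of class `synth_box`: `frame` (the initial
#'   [bond_frame()] at timestep 0), `template`, `copies` (`molecule_index`,
#'   `offset`), `o2` (`index`, `o1`, `o2`), and `bond_table` (global bond
#'   list with nominal orders, copy index and template label).
#' @export
generate_box <- function(template, n_molecules, n_O2 = 0L) {
  stopifnot(n_molecules >= 0L, n_O2 >= 0L)
  n_t <- nrow(template$atoms)
  offs <- (seq_len(n_molecules) - 1L) * n_t
  o2_base <- n_molecules * n_t
  els <- character(0); ids <- integer(0)
  bt <- list(); k <- 0L
  for (c in seq_len(n_molecules)) {
    ids <- c(ids, offs[c] + template$atoms$idx)
    els <- c(els, template$atoms$element)
    k <- k + 1L
    bt[[k]] <- data.frame(i = offs[c] + template$bonds$i,
                          j = offs[c] + template$bonds$j,
                          order = template$bonds$order,
                          copy = c, label = template$bonds$label)
  }
  o2 <- data.frame(index = integer(0), o1 = integer(0), o2 = integer(0))
  if (n_O2 > 0L) {
    o1 <- o2_base + 2L * (seq_len(n_O2) - 1L) + 1L
    o2 <- data.frame(index = seq_len(n_O2), o1 = o1, o2 = o1 + 1L)
    ids <- c(ids, rbind(o2$o1, o2$o2))
    els <- c(els, rep("O", 2L * n_O2))
    k <- k + 1L
    bt[[k]] <- data.frame(i = o2$o1, j = o2$o2, order = 2,
                          copy = NA_integer_, label = NA_character_)
  }
  bond_table <- if (k > 0L) do.call(rbind, bt) else
    data.frame(i = integer(0), j = integer(0), order = numeric(0),
               copy = integer(0), label = character(0))
  atoms <- data.frame(id = ids, element = els)
  atoms <- atoms[order(atoms$id), , drop = FALSE]
  frame <- bond_frame(0L, 0, atoms,
                      bond_table[bond_table$order > 0, c("i", "j", "order")])
  structure(list(frame = frame, template = template,
                 copies = data.frame(molecule_index = seq_len(n_molecules),
                                     offset = offs),
                 o2 = o2, bond_table = bond_table),
            class = "synth_box")
}

#' @export
print.synth_box <- function(x, ...) {
  cat(sprintf("synth_box: %d x %s + %d O2 = %d atoms\n",
              nrow(x$copies), x$template$formula, nrow(x$o2),
              nrow(x$frame$atoms)))
  invisible(x)
}

#' Reaction script for the synthetic generator
#'
#' Declares the scripted bond events of a synthetic run plus its stochastic
#' nuisance processes: Gaussian bond-order noise, short-lived flicker bonds
#' (orders 0.5-0.7, living 1-5 frames — above the cutoff, so they briefly
#' merge species and must be removed by the lifetime filter), and weak
#' transient contacts (orders 0.15-0.45 — below the default cutoff, felt
#' only when sweeping too-low cutoffs).
#'
#' @param events `data.frame` with columns `copy` (template copy index, `NA`
#'   for explicit pairs), `label` (template bond label, or a descriptor for
#'   new bonds), `i`, `j` (explicit global atom ids, `NA` when `label`
#'   resolves them), `type` (`dissociation`, `formation`, `single_to_double`,
#'   `double_to_single`) and `frame` (first frame of the new state).
#' @param noise_sd Bond-order noise sd (default 0.05, small enough that the
#'   0.5 cutoff cleanly separates states).
#' @param flicker_rate Probability per frame of starting a flicker bond.
#' @param contact_rate Probability per frame of starting a weak contact.
#' @param seed RNG seed; the same seed reproduces the run byte for byte.
#' @return An object of class `reaction_script`.
#' @export
make_script <- function(events = NULL, noise_sd = 0.05, flicker_rate = 0,
                        contact_rate = 0, seed = 1L) {
  if (is.null(events)) {
    events <- data.frame(copy = integer(0), label = character(0),
                         i = integer(0), j = integer(0),
                         type = character(0), frame = integer(0))
  }
  stopifnot(noise_sd >= 0, flicker_rate >= 0, flicker_rate <= 1,
            contact_rate >= 0, contact_rate <= 1)
  structure(list(events = events, noise_sd = noise_sd,
                 flicker_rate = flicker_rate, contact_rate = contact_rate,
                 seed = as.integer(seed)),
            class = "reaction_script")
}

order_after <- function(type, before) {
  switch(type,
         dissociation = 0,
         formation = 1,
         single_to_double = 2,
         double_to_single = 1,
         stop("unknown event type ", type))
}

## resolve scripted events against a box: global pairs + bond-table row
resolve_events <- function(box, events, n_frames) {
  if (nrow(events) == 0L) {
    return(data.frame(copy = integer(0), label = character(0),
                      i = integer(0), j = integer(0), type = character(0),
                      frame = integer(0), row = integer(0)))
  }
  bt <- box$bond_table
  out <- events
  out$row <- NA_integer_
  for (r in seq_len(nrow(out))) {
    if (!is.na(out$label[r]) && !is.na(out$copy[r]) &&
        out$label[r] %in% bt$label[!is.na(bt$label)]) {
      hit <- which(bt$copy == out$copy[r] & bt$label == out$label[r])
      if (length(hit) != 1L) {
        stop("reaction script: no bond labeled ", out$label[r], " in copy ",
             out$copy[r])
      }
      out$i[r] <- bt$i[hit]; out$j[r] <- bt$j[hit]; out$row[r] <- hit
    } else {
      lo <- min(out$i[r], out$j[r]); hi <- max(out$i[r], out$j[r])
      out$i[r] <- lo; out$j[r] <- hi
      hit <- which(bt$i == lo & bt$j == hi)
      if (length(hit) == 1L) {
        out$row[r] <- hit
      } else if (out$type[r] != "formation") {
        stop("reaction script: event references absent bond ", lo, "-", hi)
      }
    }
    if (!(out$i[r] %in% box$frame$atoms$id) ||
        !(out$j[r] %in% box$frame$atoms$id)) {
      stop("reaction script: event references unknown atom")
    }
  }
  if (any(out$frame < 1L | out$frame > n_frames)) {
    stop("reaction script: event frame outside trajectory")
  }
  out[order(out$frame), , drop = FALSE]
}

#' Generate a synthetic bond-order trajectory with ground truth
#'
#' Evolves the box's bond orders as step functions at the scripted event
#' frames, adds Gaussian noise (clipped at 0), inserts flicker bonds and
#' weak contacts, and records a ground-truth log: the resolved committed
#' events, the species intervals of the noise-free scripted system (exact
#' atom sets with first/last frame and cumulative frame counts), and the
#' atom-set keys of every flicker-merged species. The atom set is constant
#' across frames; the same seed reproduces frames and log exactly.
#'
#' @param box A [generate_box()] result.
#' @param script A [make_script()].
#' @param n_frames Number of frames to emit (frame f at timestep
#'   `f * frames_per_output`).
#' @param meta A [trajectory_meta()] (timing only).
#' @return An object of class `synth_trajectory`: `frames`, `meta`, `truth`
#'   (`events`, `species`, `segments`, `flicker_keys`), `box`, `script`.
#' @export
generate_trajectory <- function(box, script, n_frames,
                                meta = trajectory_meta(n_frames = n_frames)) {
  meta$n_frames <- as.integer(n_frames)
  interval_ps <- frame_interval_ps(meta)
  ev <- resolve_events(box, script$events, n_frames)
  bt <- box$bond_table
  ## append scripted brand-new bonds (no bond-table row yet) with base order 0
  new_rows <- which(is.na(ev$row))
  for (r in new_rows) {
    bt <- rbind(bt, data.frame(i = ev$i[r], j = ev$j[r], order = 0,
                               copy = ev$copy[r], label = ev$label[r]))
    ev$row[r] <- nrow(bt)
  }
  atoms <- box$frame$atoms
  n_atoms <- nrow(atoms)
  id2pos <- integer(max(atoms$id)); id2pos[atoms$id] <- seq_len(n_atoms)
  ## ground truth descriptors and times
  ev$descriptor <- paste(ev$label, ev$type)
  ev$time_ps <- ev$frame * interval_ps
  truth_events <- ev[, c("copy", "label", "type", "descriptor", "frame",
                         "time_ps", "i", "j")]
  rownames(truth_events) <- NULL
  ## piecewise-constant base orders: segments between event frames
  bounds <- sort(unique(c(1L, ev$frame, n_frames + 1L)))
  segments <- list()
  cur <- bt$order
  truth_species <- new.env(parent = emptyenv())
  for (s in seq_len(length(bounds) - 1L)) {
    f0 <- bounds[s]; f1 <- bounds[s + 1L] - 1L
    hit <- which(ev$frame == f0)
    for (r in hit) {
      cur[ev$row[r]] <- order_after(ev$type[r], cur[ev$row[r]])
    }
    present <- cur > 0
    memb <- uf_partition(n_atoms, id2pos[bt$i[present]], id2pos[bt$j[present]])
    comp_ids <- split(atoms$id, memb)
    comp_el <- split(atoms$element, memb)
    keys <- vapply(comp_ids, function(x) paste(sort(x), collapse = "-"),
                   character(1))
    forms <- vapply(comp_el, hill_formula, character(1))
    segments[[s]] <- list(first = f0, last = f1, keys = unname(keys),
                          formulas = unname(forms), membership = memb)
    nfr <- f1 - f0 + 1L
    for (ksp in seq_along(keys)) {
      rec <- truth_species[[keys[ksp]]]
      if (is.null(rec)) {
        truth_species[[keys[ksp]]] <- list(formula = forms[ksp], n = nfr,
                                           first = f0, last = f1)
      } else {
        rec$n <- rec$n + nfr; rec$last <- f1
        truth_species[[keys[ksp]]] <- rec
      }
    }
    segments[[s]]$cur_orders <- cur
  }
  keys_all <- ls(truth_species)
  species_df <- data.frame(
    key = keys_all,
    formula = vapply(keys_all, function(k) truth_species[[k]]$formula, character(1)),
    n_frames = vapply(keys_all, function(k) truth_species[[k]]$n, numeric(1)),
    first_frame = vapply(keys_all, function(k) truth_species[[k]]$first, numeric(1)),
    last_frame = vapply(keys_all, function(k) truth_species[[k]]$last, numeric(1)),
    row.names = NULL)
  species_df$lifetime_ps <- species_df$n_frames * interval_ps
  ## emit frames under the script's seed
  frames <- vector("list", n_frames)
  flicker_log <- list(); fl_n <- 0L
  flicker_keys <- character(0)
  with_local_seed(script$seed, {
    active <- data.frame(i = integer(0), j = integer(0), order = numeric(0),
                         left = integer(0))
    seg_idx <- 1L
    for (f in seq_len(n_frames)) {
      while (f > segments[[seg_idx]]$last) seg_idx <- seg_idx + 1L
      seg <- segments[[seg_idx]]
      base <- seg$cur_orders
      ## flicker / contact spawning
      for (kind in c("flicker", "contact")) {
        rate <- if (kind == "flicker") script$flicker_rate else script$contact_rate
        if (rate > 0 && stats::runif(1) < rate && n_atoms >= 2L) {
          pair <- sample.int(n_atoms, 2L)
          gi <- min(atoms$id[pair]); gj <- max(atoms$id[pair])
          bonded <- any(bt$i == gi & bt$j == gj & base > 0)
          if (!bonded) {
            ordr <- if (kind == "flicker") stats::runif(1, 0.5, 0.7) else
              stats::runif(1, 0.15, 0.45)
            dur <- sample.int(5L, 1L)
            active <- rbind(active, data.frame(i = gi, j = gj, order = ordr,
                                               left = dur))
            fl_n <- fl_n + 1L
            flicker_log[[fl_n]] <- data.frame(kind = kind, i = gi, j = gj,
                                              order = ordr, first_frame = f,
                                              last_frame = f + dur - 1L)
            if (kind == "flicker") {
              ## record the merged species this flicker creates in the truth
              memb2 <- seg$membership
              ca <- memb2[id2pos[gi]]; cb <- memb2[id2pos[gj]]
              if (ca != cb) {
                merged <- sort(atoms$id[memb2 %in% c(ca, cb)])
                flicker_keys <- c(flicker_keys,
                                  paste(merged, collapse = "-"))
              }
            }
          }
        }
      }
      orders <- base
      if (script$noise_sd > 0) {
        orders <- pmax(0, orders + stats::rnorm(length(orders), 0,
                                                script$noise_sd))
      }
      keep <- orders > 0
      bonds <- data.frame(i = bt$i[keep], j = bt$j[keep], order = orders[keep])
      if (nrow(active) > 0L) {
        extra <- active[active$left > 0L, c("i", "j", "order"), drop = FALSE]
        if (nrow(extra) > 0L) bonds <- rbind(bonds, extra)
        active$left <- active$left - 1L
        active <- active[active$left > 0L, , drop = FALSE]
      }
      ts <- f * meta$frames_per_output
      frames[[f]] <- bond_frame(ts, ts * meta$timestep_fs, atoms, bonds)
    }
  })
  flicker_df <- if (fl_n > 0L) do.call(rbind, flicker_log) else
    data.frame(kind = character(0), i = integer(0), j = integer(0),
               order = numeric(0), first_frame = integer(0),
               last_frame = integer(0))
  structure(list(frames = frames, meta = meta,
                 truth = list(events = truth_events, species = species_df,
                              segments = segments,
                              flicker_keys = unique(flicker_keys),
                              flicker_log = flicker_df),
                 box = box, script = script),
            class = "synth_trajectory")
}

#' @export
print.synth_trajectory <- function(x, ...) {
  cat(sprintf("synth_trajectory: %d frames, %d atoms, %d scripted events, %d flickers\n",
              length(x$frames), nrow(x$box$frame$atoms),
              nrow(x$truth$events), nrow(x$truth$flicker_log)))
  invisible(x)
}

## truth containment: key of the species holding `atom` at `frame`
truth_species_at <- function(truth, atom, frame) {
  for (seg in truth$segments) {
    if (frame >= seg$first && frame <= seg$last) {
      pos <- seg$membership[atom]
      return(seg$keys[pos])
    }
  }
  NA_character_
}

#' Generate a temperature-ramp run with known onset
#'
#' Each intact copy independently loses one randomly chosen template bond
#' with a per-frame hazard that follows the plateau + shifted-exponential
#' survival model: the expected intact count is `N0 * exp(-(T - T0)/scale)`
#' once the ramp passes `T0`. Records the true intact-count series; frames
#' can be skipped (`emit_frames = FALSE`) for fit-recovery studies that only
#' need the counts.
#'
#' @param template Reactant template.
#' @param n_copies Initial molecule count `N0`.
#' @param T0_K True decay-onset location (K).
#' @param scale_K True decay scale (K).
#' @param n_frames Ramp frames (default 3200 = 800 ps at 0.25 ps/frame).
#' @param interval_ps Frame interval (ps).
#' @param T_start,T_max,rate_K_per_ps Ramp protocol (default 300 to 3500 K
#'   at 4 K/ps).
#' @param n_O2 Spectator O2 molecules to include in the box.
#' @param seed RNG seed.
#' @param emit_frames Build full [bond_frame()]s (`TRUE`) or only the truth
#'   series (`FALSE`).
#' @return List of class `synth_ramp`: `truth` (a [ramp_series()]),
#'   `events` (`copy`, `i`, `j`, `frame`), `frames` (or `NULL`),
#'   `temperatures_K`, `T0_K`, `scale_K`, `meta`.
#' @export
generate_ramp <- function(template, n_copies = 50L, T0_K = 1100,
                          scale_K = 150, n_frames = 3200L, interval_ps = 0.25,
                          T_start = 300, T_max = 3500, rate_K_per_ps = 4,
                          n_O2 = 0L, seed = 1L, emit_frames = TRUE) {
  sched <- ramp_schedule(n_frames, interval_ps, T_start, T_max, rate_K_per_ps)
  temps <- sched$temperatures_K
  stopifnot(T0_K > T_start)
  box <- generate_box(template, n_copies, n_O2)
  n_bonds_t <- nrow(template$bonds)
  diss_frame <- rep.int(NA_integer_, n_copies)
  diss_bond <- rep.int(NA_integer_, n_copies)
  with_local_seed(seed, {
    prevT <- T_start
    for (f in seq_len(n_frames)) {
      Tf <- temps[f]
      if (Tf > T0_K) {
        dT <- Tf - max(prevT, T0_K)
        p <- 1 - exp(-dT / scale_K)
        alive <- which(is.na(diss_frame))
        if (length(alive) > 0L && p > 0) {
          hit <- alive[stats::runif(length(alive)) < p]
          diss_frame[hit] <- f
          diss_bond[hit] <- sample.int(n_bonds_t, length(hit), replace = TRUE)
        }
      }
      prevT <- Tf
    }
  })
  counts <- vapply(seq_len(n_frames), function(f) {
    sum(is.na(diss_frame) | diss_frame > f)
  }, numeric(1))
  truth <- ramp_series(temps, counts, replicate_id = paste0("seed", seed))
  reacted <- which(!is.na(diss_frame))
  events <- data.frame(
    copy = reacted,
    i = box$bond_table$i[match(reacted, box$bond_table$copy) - 1L +
                           diss_bond[reacted]],
    j = box$bond_table$j[match(reacted, box$bond_table$copy) - 1L +
                           diss_bond[reacted]],
    frame = diss_frame[reacted])
  frames <- NULL
  if (emit_frames) {
    ev <- data.frame(copy = events$copy, label = NA_character_,
                     i = events$i, j = events$j,
                     type = "dissociation", frame = events$frame)
    script <- make_script(events = ev, noise_sd = 0, seed = seed)
    meta <- trajectory_meta(timestep_fs = interval_ps * 1000, frames_per_output = 1L,
                            n_frames = n_frames,
                            replicate_id = paste0("seed", seed))
    frames <- generate_trajectory(box, script, n_frames, meta)$frames
  }
  structure(list(truth = truth, events = events, frames = frames,
                 temperatures_K = temps, T0_K = T0_K, scale_K = scale_K,
                 meta = trajectory_meta(timestep_fs = interval_ps * 1000,
                                        frames_per_output = 1L,
                                        n_frames = n_frames,
                                        replicate_id = paste0("seed", seed))),
            class = "synth_ramp")
}

#' Noise-free decay series from the onset model
#'
#' Evaluates the plateau + shifted-exponential model itself on a ramp
#' schedule — the self-consistency input for fit-recovery checks.
#'
#' @inheritParams generate_ramp
#' @return A [ramp_series()] with continuous (non-integer) counts.
#' @export
model_ramp_series <- function(n_copies = 50L, T0_K = 1100, scale_K = 150,
                              n_frames = 3200L, interval_ps = 0.25,
                              T_start = 300, T_max = 3500, rate_K_per_ps = 4) {
  sched <- ramp_schedule(n_frames, interval_ps, T_start, T_max, rate_K_per_ps)
  temps <- sched$temperatures_K
  counts <- ifelse(temps <= T0_K, n_copies,
                   n_copies * exp(-(temps - T0_K) / scale_K))
  ramp_series(temps, counts, replicate_id = "model")
}
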