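## clamp scripted frames into the committable window and keep per-copy order
space_frames <- function(f, n_frames, min_gap = 2L) {
  hi <- max(2L, n_frames - 60L)
  lo <- min(10L, hi)
  f <- pmin(pmax(f, lo), hi)
  if (length(f) > 1L) {
    for (k in seq_along(f)[-1L]) f[k] <- max(f[k], f[k - 1L] + min_gap)
  }
  pmin(f, n_frames)
}

#' Packaged thermo-oxidation scenario for the monomer (molecule A)
#'
#' Scripts the monomer's headline chemistry onto a synthetic box: some
#' copies lose the phenolic H (1A dissociation, giving C19H29O3), some run
#' the carbon dioxide route (4A ethyl loss, 3A single-to-double, 2A
#' dissociation releasing the O=C-O fragment that is CO2), and some the
#' ethyl hydroperoxide route (1A H loss and 4A ethyl loss, then C-O
#' formation with an O2 and H-O formation with the donated H, giving
#' C2H6O2). Remaining copies stay unreacted.
#'
#' @param n_copies Template copies in the box.
#' @param n_O2 O2 molecules (the hydroperoxide route consumes one per copy).
#' @param n_frames Frames to emit.
#' @param n_hloss,n_co2,n_ethp Copies assigned to each route.
#' @param start_frame First scripted event frame.
#' @param stagger Frame shift between consecutive reacting copies.
#' @param jitter_frames Gaussian sd (frames) jittering every event time;
#'   0 gives fully deterministic scripted timing.
#' @param noise_sd,flicker_rate,contact_rate,seed Passed to [make_script()].
#' @return A `synth_trajectory` with an extra `scenario` field listing the
#'   per-copy route assignments and expected product atom sets.
#' @export
synth_scenario_A <- function(n_copies = 9L, n_O2 = 30L, n_frames = 300L,
                             n_hloss = 2L, n_co2 = 2L, n_ethp = 2L,
                             start_frame = 50L, stagger = 7L,
                             jitter_frames = 0, noise_sd = 0,
                             flicker_rate = 0, contact_rate = 0, seed = 1L) {
  stopifnot(n_hloss + n_co2 + n_ethp <= n_copies, n_ethp <= n_O2)
  tmplA <- mol_template_A()
  box <- generate_box(tmplA, n_copies, n_O2)
  n_t <- nrow(tmplA$atoms)                 # 52
  routes <- rep("unreacted", n_copies)
  routes[seq_len(n_hloss)] <- "hloss"
  if (n_co2 > 0L) routes[n_hloss + seq_len(n_co2)] <- "co2"
  if (n_ethp > 0L) routes[n_hloss + n_co2 + seq_len(n_ethp)] <- "ethp"
  ev <- list(); k <- 0L; reacting <- 0L
  products <- list()
  with_local_seed(seed + 7919L, {
    for (c in seq_len(n_copies)) {
      if (routes[c] == "unreacted") next
      reacting <- reacting + 1L
      b <- start_frame + (reacting - 1L) * stagger
      off <- (c - 1L) * n_t
      jit <- function(f) {
        if (jitter_frames > 0) f + round(stats::rnorm(length(f), 0, jitter_frames))
        else f
      }
      if (routes[c] == "hloss") {
        f <- space_frames(jit(b), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(copy = c, label = "1A", i = NA_integer_,
                              j = NA_integer_, type = "dissociation", frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "hloss", formula = "C19H29O3",
               atoms = setdiff(off + tmplA$atoms$idx, off + 8L))
      } else if (routes[c] == "co2") {
        f <- space_frames(jit(b + c(0L, 15L, 30L)), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(copy = c, label = c("4A", "3A", "2A"),
                              i = NA_integer_, j = NA_integer_,
                              type = c("dissociation", "single_to_double",
                                       "dissociation"),
                              frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "co2", formula = "CO2",
               atoms = off + c(19L, 20L, 21L))
      } else {                            # ethp
        o2row <- box$o2[reacting, ]
        f <- space_frames(jit(b + c(0L, 15L, 30L, 45L)), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(
          copy = c,
          label = c("1A", "4A", "C-O", "H-O"),
          i = c(NA_integer_, NA_integer_, off + 22L, off + 8L),
          j = c(NA_integer_, NA_integer_, o2row$o1, o2row$o2),
          type = c("dissociation", "dissociation", "formation", "formation"),
          frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "ethp", formula = "C2H6O2",
               atoms = sort(c(off + c(22L, 23L, 48L, 49L, 50L, 51L, 52L, 8L),
                              o2row$o1, o2row$o2)))
      }
    }
  })
  events <- if (k > 0L) do.call(rbind, ev) else NULL
  script <- make_script(events = events, noise_sd = noise_sd,
                        flicker_rate = flicker_rate,
                        contact_rate = contact_rate, seed = seed)
  out <- generate_trajectory(box, script, n_frames)
  out$scenario <- list(name = "A", routes = routes, products = products)
  out
}

#' Packaged thermal-dehydration scenario for the dimer (molecule B)
#'
#' Scripts the dimer's water chemistry: on each reacting copy one monomer
#' half (alternating unprimed/primed) loses its phenolic H (1B), the ring
#' C-O transiently stabilises as a double bond (3B single-to-double), the
#' side-chain C-O (4B) releases an OH radical, and the H and OH recombine
#' (H-O formation) into H2O. Additional copies lose one or both phenolic H
#' atoms only, giving the C26H33O4 / C26H32O4 products.
#'
#' @inheritParams synth_scenario_A
#' @param n_h2o Copies running the full water route.
#' @param n_hloss Copies losing a single phenolic H (C26H33O4).
#' @param n_h2loss Copies losing both phenolic H atoms (C26H32O4).
#' @return A `synth_trajectory` with a `scenario` field as in
#'   [synth_scenario_A()].
#' @export
synth_scenario_B <- function(n_copies = 9L, n_O2 = 0L, n_frames = 300L,
                             n_h2o = 3L, n_hloss = 2L, n_h2loss = 1L,
                             start_frame = 50L, stagger = 7L,
                             jitter_frames = 0, noise_sd = 0,
                             flicker_rate = 0, contact_rate = 0, seed = 1L) {
  stopifnot(n_h2o + n_hloss + n_h2loss <= n_copies)
  tmplB <- mol_template_B()
  box <- generate_box(tmplB, n_copies, n_O2)
  n_t <- nrow(tmplB$atoms)                 # 64
  routes <- rep("unreacted", n_copies)
  routes[seq_len(n_h2o)] <- "h2o"
  if (n_hloss > 0L) routes[n_h2o + seq_len(n_hloss)] <- "hloss"
  if (n_h2loss > 0L) routes[n_h2o + n_hloss + seq_len(n_h2loss)] <- "h2loss"
  prime <- function(lab, primed) if (primed) paste0(lab, "'") else lab
  ev <- list(); k <- 0L; reacting <- 0L
  products <- list()
  with_local_seed(seed + 7919L, {
    for (c in seq_len(n_copies)) {
      if (routes[c] == "unreacted") next
      reacting <- reacting + 1L
      primed <- reacting %% 2L == 0L
      h <- if (primed) 32L else 0L
      b <- start_frame + (reacting - 1L) * stagger
      off <- (c - 1L) * n_t
      jit <- function(f) {
        if (jitter_frames > 0) f + round(stats::rnorm(length(f), 0, jitter_frames))
        else f
      }
      if (routes[c] == "h2o") {
        f <- space_frames(jit(b + c(0L, 5L, 20L, 40L)), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(
          copy = c,
          label = c(prime("1B", primed), prime("3B", primed),
                    prime("4B", primed), "H-O"),
          i = c(NA_integer_, NA_integer_, NA_integer_, off + h + 8L),
          j = c(NA_integer_, NA_integer_, NA_integer_, off + h + 16L),
          type = c("dissociation", "single_to_double", "dissociation",
                   "formation"),
          frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "h2o", formula = "H2O",
               atoms = sort(off + h + c(8L, 16L, 17L)))
      } else if (routes[c] == "hloss") {
        f <- space_frames(jit(b), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(copy = c, label = prime("1B", primed),
                              i = NA_integer_, j = NA_integer_,
                              type = "dissociation", frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "hloss", formula = "C26H33O4",
               atoms = setdiff(off + tmplB$atoms$idx, off + h + 8L))
      } else {                            # h2loss: both phenolic H atoms
        f <- space_frames(jit(b + c(0L, 10L)), n_frames)
        k <- k + 1L
        ev[[k]] <- data.frame(copy = c, label = c("1B", "1B'"),
                              i = NA_integer_, j = NA_integer_,
                              type = "dissociation", frame = f)
        products[[length(products) + 1L]] <-
          list(copy = c, route = "h2loss", formula = "C26H32O4",
               atoms = setdiff(off + tmplB$atoms$idx, off + c(8L, 40L)))
      }
    }
  })
  events <- if (k > 0L) do.call(rbind, ev) else NULL
  script <- make_script(events = events, noise_sd = noise_sd,
                        flicker_rate = flicker_rate,
                        contact_rate = contact_rate, seed = seed)
  out <- generate_trajectory(box, script, n_frames)
  out$scenario <- list(name = "B", routes = routes, products = products)
  out
}
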