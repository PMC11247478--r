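test_that("labeled-bond mapping binds every label in every intact copy", {
  boxB <- generate_box(mol_template_B(), 3L, 0L)
  m <- map_labeled_bonds(boxB$frame, mol_template_B())
  expect_equal(as.integer(table(m$label)), rep(3L, 8L))
  expect_setequal(unique(m$molecule_index), 1:3)
  # every mapped pair is a real bond of the right elements
  el <- stats::setNames(boxB$frame$atoms$element,
                        as.character(boxB$frame$atoms$id))
  oh <- m[m$label %in% c("1B", "1B'", "2B", "2B'"), ]
  expect_true(all(paste0(el[as.character(oh$i)], el[as.character(oh$j)])
                  %in% c("OH", "HO")))
  # a single A copy: exactly one instance of each of 1A-4A
  boxA <- generate_box(mol_template_A(), 1L, 0L)
  mA <- map_labeled_bonds(boxA$frame, mol_template_A())
  expect_equal(sort(mA$label), c("1A", "2A", "3A", "4A"))
})

test_that("a pre-broken copy is unmatched and reported", {
  box <- generate_box(mol_template_A(), 3L, 0L)
  ev <- data.frame(copy = 2L, label = "2A", i = NA_integer_, j = NA_integer_,
                   type = "dissociation", frame = 1L)
  traj <- generate_trajectory(box, make_script(events = ev, noise_sd = 0), 5L)
  expect_warning(
    m <- map_labeled_bonds(traj$frames[[1L]], mol_template_A(),
                           expected_copies = 3L),
    "expected 3")
  expect_equal(as.integer(table(m$label)), rep(2L, 4L))
})

test_that("bond states classify at the 0.5 and 1.5 midpoints", {
  expect_equal(classify_state_series(c(0, 0.49, 0.5, 1.0, 1.49, 1.5, 2.0)),
               c("absent", "absent", "single", "single", "single",
                 "double", "double"))
})

test_that("events are committed only after the persistence window", {
  tp <- seq_len(300) * 0.25
  inst <- list(label = "1A", molecule_index = 1L, i = 1L, j = 2L,
               orders = c(rep(1, 100), rep(0, 200)), time_ps = tp)
  ev <- detect_events(inst, 50L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "dissociation")
  expect_equal(ev$frame, 101L)
  expect_equal(ev$time_ps, tp[101L])
  # a 10-frame excursion is flicker, not an event
  flick <- list(label = "1A", molecule_index = 1L, i = 1L, j = 2L,
                orders = c(rep(1, 100), rep(0, 10), rep(1, 190)), time_ps = tp)
  expect_equal(nrow(detect_events(flick, 50L)), 0L)
  # single -> double transitions classify correctly
  s2d <- list(label = "3A", molecule_index = 1L, i = 1L, j = 2L,
              orders = c(rep(1, 100), rep(2, 200)), time_ps = tp)
  expect_equal(detect_events(s2d, 50L)$event_type, "single_to_double")
})

test_that("a scripted molecule-A run recovers its event log exactly", {
  box <- generate_box(mol_template_A(), 1L, 0L)
  ev <- data.frame(copy = 1L, label = c("1A", "4A", "3A", "2A"),
                   i = NA_integer_, j = NA_integer_,
                   type = c("dissociation", "dissociation",
                            "single_to_double", "dissociation"),
                   frame = c(30L, 90L, 150L, 210L))
  traj <- generate_trajectory(box, make_script(events = ev, noise_sd = 0), 300L)
  mapping <- map_labeled_bonds(traj$frames[[1L]], mol_template_A())
  inst <- bond_series(traj$frames, mapping, traj$meta)
  got <- detect_events_all(inst, 50L)
  expect_equal(got$label, c("1A", "4A", "3A", "2A"))
  expect_equal(got$event_type,
               c("dissociation", "dissociation", "single_to_double",
                 "dissociation"))
  expect_equal(got$frame, c(30L, 90L, 150L, 210L))
  # and with default bond-order noise the same events are recovered
  trajn <- generate_trajectory(box, make_script(events = ev, noise_sd = 0.05,
                                                seed = 9L), 300L)
  instn <- bond_series(trajn$frames,
                       map_labeled_bonds(trajn$frames[[1L]], mol_template_A()),
                       trajn$meta)
  gotn <- detect_events_all(instn, 50L)
  expect_equal(gotn[, c("label", "event_type", "frame")],
               got[, c("label", "event_type", "frame")])
})

test_that("per-label bonded counts respect event bookkeeping", {
  boxB <- generate_box(mol_template_B(), 4L, 0L)
  ev <- data.frame(copy = c(1L, 2L, 3L), label = c("1B", "1B", "1B'"),
                   i = NA_integer_, j = NA_integer_,
                   type = "dissociation", frame = c(40L, 60L, 80L))
  traj <- generate_trajectory(boxB, make_script(events = ev, noise_sd = 0),
                              200L)
  mapping <- map_labeled_bonds(traj$frames[[1L]], mol_template_B())
  inst <- bond_series(traj$frames, mapping, traj$meta)
  counts <- bond_count_series(inst, aggregate_primed = TRUE)
  expect_equal(unname(counts["1B", 1L]), 8L)        # 4 copies x (1B + 1B')
  expect_equal(unname(counts["1B", 200L]), 8L - 3L) # minus dissociations
  expect_true(all(counts["3B", ] == 8L))
  # start - dissociations + formations = end, per label
  evs <- detect_events_all(inst, 50L)
  for (lab in rownames(counts)) {
    hit <- evs[sub("'+$", "", evs$label) == lab, ]
    delta <- sum(hit$event_type == "formation") -
      sum(hit$event_type == "dissociation")
    expect_equal(unname(counts[lab, 200L]), unname(counts[lab, 1L]) + delta)
  }
})

test_that("new-bond detection finds scripted formations and nothing else", {
  traj <- synth_scenario_A(n_frames = 300L, seed = 1)
  nb <- detect_new_bonds(traj$frames, meta = traj$meta)
  truth_nb <- traj$truth$events[grepl("formation", traj$truth$events$type), ]
  expect_equal(nrow(nb), nrow(truth_nb))
  expect_equal(nb$frame, truth_nb$frame)
  expect_equal(nb$label, truth_nb$label)
  expect_equal(sort(paste(nb$i, nb$j)), sort(paste(truth_nb$i, truth_nb$j)))
  # no non-template bonds -> empty
  quiet <- generate_trajectory(generate_box(mol_template_A(), 1L, 2L),
                               make_script(noise_sd = 0), 60L)
  expect_equal(nrow(detect_new_bonds(quiet$frames, meta = quiet$meta)), 0L)
  # H + OH recombination in the dimer scenario yields an H-O formation
  trajB <- synth_scenario_B(n_copies = 2L, n_frames = 200L, n_h2o = 1L,
                            n_hloss = 0L, n_h2loss = 0L, seed = 3)
  nbB <- detect_new_bonds(trajB$frames, meta = trajB$meta)
  expect_equal(nbB$label, "H-O")
  expect_equal(nrow(nbB), 1L)
})
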