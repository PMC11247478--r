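test_that("box assembly reproduces the standard system sizes", {
  expect_equal(nrow(generate_box(mol_template_A(), 50L, 300L)$frame$atoms),
               3200L)
  expect_equal(nrow(generate_box(mol_template_B(), 50L, 300L)$frame$atoms),
               3800L)
  empty <- generate_box(mol_template_A(), 0L, 0L)
  expect_equal(nrow(empty$frame$atoms), 0L)
  expect_equal(nrow(empty$frame$bonds), 0L)
})

test_that("an empty noise-free script leaves every frame identical to the box", {
  box <- generate_box(mol_template_A(), 2L, 4L)
  traj <- generate_trajectory(box, make_script(noise_sd = 0), 6L)
  for (fr in traj$frames) {
    expect_equal(fr$atoms, box$frame$atoms)
    got <- fr$bonds[order(fr$bonds$i, fr$bonds$j), ]
    want <- box$frame$bonds[order(box$frame$bonds$i, box$frame$bonds$j), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the same seed reproduces frames, logs and dump files exactly", {
  mk <- function() synth_scenario_A(n_copies = 3L, n_O2 = 6L, n_frames = 40L,
                                    n_hloss = 1L, n_co2 = 1L, n_ethp = 1L,
                                    start_frame = 10L, noise_sd = 0.05,
                                    flicker_rate = 0.2, jitter_frames = 3,
                                    seed = 123)
  a <- mk(); b <- mk()
  expect_equal(a$truth$events, b$truth$events)
  expect_equal(a$truth$species, b$truth$species)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_bonds_dump(a$frames, fa)
  write_bonds_dump(b$frames, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("scripts referencing absent bonds or frames are rejected", {
  box <- generate_box(mol_template_A(), 1L, 0L)
  bad_bond <- data.frame(copy = 1L, label = NA_character_, i = 1L, j = 3L,
                         type = "dissociation", frame = 5L)
  expect_error(generate_trajectory(box, make_script(events = bad_bond), 10L),
               "absent bond")
  bad_frame <- data.frame(copy = 1L, label = "1A", i = NA_integer_,
                          j = NA_integer_, type = "dissociation", frame = 50L)
  expect_error(generate_trajectory(box, make_script(events = bad_frame), 10L),
               "outside trajectory")
})

test_that("noiseless census reproduces the ground-truth species log exactly", {
  traj <- synth_scenario_A(n_frames = 200L, seed = 6)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  truth <- traj$truth$species
  # identical instance sets, frame counts and spans (precision = recall = 1)
  got <- tl$instances[order(tl$instances$key), ]
  want <- truth[order(truth$key),
                c("key", "formula", "n_frames", "first_frame", "last_frame")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, names(want)],
               transform(want, n_frames = as.integer(n_frames),
                         first_frame = as.integer(first_frame),
                         last_frame = as.integer(last_frame)))
  # per-frame census equals the truth segment composition
  for (f in c(1L, 77L, 130L, 200L)) {
    seg <- Filter(function(s) f >= s$first && f <= s$last,
                  traj$truth$segments)[[1L]]
    want_cen <- table(seg$formulas)
    got_cen <- frame_census(traj$frames[[f]], 0.5)
    expect_equal(got_cen[sort(names(want_cen))],
                 stats::setNames(as.integer(want_cen[sort(names(want_cen))]),
                                 sort(names(want_cen))))
  }
})

test_that("noiseless event detection matches the scripted log (P = R = 1)", {
  traj <- synth_scenario_B(n_frames = 250L, seed = 8)
  mapping <- map_labeled_bonds(traj$frames[[1L]], mol_template_B())
  inst <- bond_series(traj$frames, mapping, traj$meta)
  got <- rbind(detect_events_all(inst, 50L),
               detect_new_bonds(traj$frames, meta = traj$meta))
  truth <- traj$truth$events
  expect_equal(nrow(got), nrow(truth))
  key <- function(d, lab, typ, frm) sort(paste(d[[lab]], d[[typ]], d[[frm]]))
  expect_equal(key(got, "label", "event_type", "frame"),
               key(truth, "label", "type", "frame"))
})

test_that("ramp generation follows the protocol and the survival model", {
  expect_length(ramp_schedule(800 / 0.25, 0.25)$temperatures_K, 3200L)
  ramp <- generate_ramp(mol_template_A(), n_copies = 40L, T0_K = 1100,
                        scale_K = 150, seed = 2, emit_frames = FALSE)
  counts <- ramp$truth$intact_counts
  expect_equal(counts[1L], 40)
  expect_true(all(diff(counts) <= 0))
  # no losses before the ramp reaches T0
  expect_true(all(counts[ramp$temperatures_K <= 1100] == 40))
  # onset far above the ramp end: nothing dissociates
  quiet <- generate_ramp(mol_template_A(), n_copies = 10L, T0_K = 5000,
                         scale_K = 150, n_frames = 100L, seed = 2,
                         emit_frames = FALSE)
  expect_true(all(quiet$truth$intact_counts == 10))
})

test_that("emitted ramp frames conserve atoms and parse cleanly", {
  ramp <- generate_ramp(mol_template_A(), n_copies = 3L, T0_K = 700,
                        scale_K = 200, n_frames = 60L, interval_ps = 4,
                        seed = 4, emit_frames = TRUE)
  natoms <- vapply(ramp$frames, function(fr) nrow(fr$atoms), integer(1))
  expect_true(all(natoms == 3L * 52L))
  f <- withr::local_tempfile()
  write_bonds_dump(ramp$frames[seq_len(5L)], f)
  back <- parse_bonds_dump(f, elements_map_cho)
  expect_length(back$frames, 5L)
})
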