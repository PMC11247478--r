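one_copy_script <- function(events, n_frames, n_O2 = 1L, seed = 1L) {
  box <- generate_box(mol_template_A(), 1L, n_O2)
  script <- make_script(events = events, noise_sd = 0, seed = seed)
  generate_trajectory(box, script, n_frames)
}

test_that("an H-loss event moves one count between formulas at its frame", {
  k <- 40L
  traj <- one_copy_script(
    data.frame(copy = 1L, label = "1A", i = NA_integer_, j = NA_integer_,
               type = "dissociation", frame = k), n_frames = 100L)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  expect_equal(unname(tl$counts["C19H30O3", ]),
               c(rep(1L, k - 1L), rep(0L, 100L - k + 1L)))
  expect_equal(unname(tl$counts["C19H29O3", ]),
               c(rep(0L, k - 1L), rep(1L, 100L - k + 1L)))
  expect_equal(unname(tl$counts["H", k]), 1L)
})

test_that("static trajectories give every instance the full duration", {
  traj <- one_copy_script(NULL, n_frames = 30L, n_O2 = 3L)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  expect_true(all(tl$instances$lifetime_ps == 30L * 0.25))
  expect_equal(nrow(tl$instances), 4L)  # 1 molecule + 3 O2
})

test_that("lifetime filter boundary sits exactly at 50 frames (12.5 ps)", {
  # species living 49 frames (12.25 ps) is removed, 50 frames is retained
  mk <- function(gap) one_copy_script(
    data.frame(copy = 1L, label = c("1A", "1A"),
               i = NA_integer_, j = NA_integer_,
               type = c("dissociation", "formation"),
               frame = c(100L, 100L + gap)), n_frames = 250L)
  tl49 <- build_timelines(mk(49L)$frames, 0.5, trajectory_meta())
  tl50 <- build_timelines(mk(50L)$frames, 0.5, trajectory_meta())
  expect_false("C19H29O3" %in% lifetime_filter(tl49, 12.5)$formulas)
  expect_true("C19H29O3" %in% lifetime_filter(tl50, 12.5)$formulas)
  # threshold 0 is the identity
  expect_equal(lifetime_filter(tl49, 0)$formulas, tl49$formulas)
})

test_that("lifetime filter is idempotent and monotone in the threshold", {
  traj <- synth_scenario_A(n_copies = 4L, n_O2 = 8L, n_frames = 120L,
                           n_hloss = 1L, n_co2 = 1L, n_ethp = 1L,
                           start_frame = 20L, stagger = 5L, noise_sd = 0.05,
                           flicker_rate = 0.3, seed = 4)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  prev <- tl$formulas
  for (th in c(0, 2, 8, 15, 25)) {
    filt <- lifetime_filter(tl, th)
    expect_true(all(filt$formulas %in% prev))
    expect_equal(lifetime_filter(filt, th)$formulas, filt$formulas)
    prev <- filt$formulas
  }
})

test_that("flicker species are removed by the default lifetime filter", {
  traj <- synth_scenario_A(n_copies = 4L, n_O2 = 8L, n_frames = 120L,
                           n_hloss = 1L, n_co2 = 1L, n_ethp = 1L,
                           start_frame = 20L, stagger = 5L, noise_sd = 0.05,
                           flicker_rate = 0.3, seed = 4)
  expect_gt(length(traj$truth$flicker_keys), 0L)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  expect_gt(sum(tl$instances$key %in% traj$truth$flicker_keys), 0L)
  filt <- lifetime_filter(tl, 12.5)
  expect_equal(sum(filt$instances$key %in% traj$truth$flicker_keys), 0L)
})

fake_timeline <- function(counts, interval = 0.25, rep_id = "r1") {
  structure(list(formulas = rownames(counts), counts = counts,
                 n_frames = ncol(counts), frame_interval_ps = interval,
                 replicate_id = rep_id),
            class = "species_timelines")
}

test_that("product ranking orders by trailing-window mean and averages replicates", {
  counts <- matrix(c(5L, 3L), nrow = 2, ncol = 40,
                   dimnames = list(c("CO2", "C2H6O2"), NULL))
  rk <- rank_products(fake_timeline(counts), window_ps = 5)
  expect_equal(rk$formula, c("CO2", "C2H6O2"))
  expect_equal(rk$mean_count, c(5, 3))
  # replicate window means 2, 3, 4 -> reported mean 3
  reps <- lapply(c(2, 3, 4), function(v) {
    fake_timeline(matrix(v, 1, 40, dimnames = list("H2O", NULL)))
  })
  expect_equal(rank_products(reps, window_ps = 5)$mean_count, 3)
  # invariant to replicate order; ties broken lexicographically
  expect_equal(rank_products(rev(reps), window_ps = 5),
               rank_products(reps, window_ps = 5))
  tied <- matrix(2L, nrow = 2, ncol = 40,
                 dimnames = list(c("H2O", "CO2"), NULL))
  expect_equal(rank_products(fake_timeline(tied), window_ps = 5)$formula,
               c("CO2", "H2O"))
  # exclusion of feed formulas
  expect_equal(rank_products(fake_timeline(counts), window_ps = 5,
                             exclude = "CO2")$formula, "C2H6O2")
  # window longer than trajectory
  expect_error(rank_products(fake_timeline(counts), window_ps = 1e6),
               "longer than trajectory")
})

test_that("intermediates are collected by shared atoms and lifetime-filtered", {
  box <- generate_box(mol_template_A(), 1L, 1L)
  o2 <- box$o2[1L, ]
  ev <- data.frame(copy = 1L,
                   label = c("1A", "4A", "C-O", "H-O"),
                   i = c(NA_integer_, NA_integer_, 22L, 8L),
                   j = c(NA_integer_, NA_integer_, o2$o1, o2$o2),
                   type = c("dissociation", "dissociation",
                            "formation", "formation"),
                   frame = c(20L, 90L, 160L, 230L))
  traj <- generate_trajectory(box, make_script(events = ev, noise_sd = 0), 300L)
  tl <- build_timelines(traj$frames, 0.5, traj$meta)
  inter <- find_intermediates(tl, "C2H6O2", 12.5)
  expect_true(all(c("C2H5", "C2H5O2", "C19H29O3", "O2") %in% inter$formula))
  # the intact feed only lives 19 frames (4.75 ps) here: filtered out
  expect_false("C19H30O3" %in% inter$formula)
  # the ethyl radical appears when 4A breaks and is absorbed at C-O formation
  expect_equal(inter$first_ps[inter$formula == "C2H5"], 90L * 0.25)
  expect_equal(inter$last_ps[inter$formula == "C2H5"], 159L * 0.25)
  # an unreacted feed molecule is its own sole intermediate
  quiet <- one_copy_script(NULL, n_frames = 60L, n_O2 = 0L)
  tlq <- build_timelines(quiet$frames, 0.5, quiet$meta)
  interq <- find_intermediates(tlq, "C19H30O3", 12.5)
  expect_equal(interq$formula, "C19H30O3")
  expect_error(find_intermediates(tlq, "CO2"), "absent at final frame")
})

test_that("timelines reject atom-set changes between frames", {
  traj <- one_copy_script(NULL, n_frames = 3L)
  broken <- traj$frames
  broken[[2L]]$atoms <- broken[[2L]]$atoms[-1L, ]
  broken[[2L]]$bonds <- broken[[2L]]$bonds[
    broken[[2L]]$bonds$i != 1L & broken[[2L]]$bonds$j != 1L, ]
  expect_error(build_timelines(broken, 0.5, traj$meta), "conservation")
})
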