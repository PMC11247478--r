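test_that("toy O2 dump parses with symmetric duplicates collapsed", {
  f <- withr::local_tempfile(lines = toy_o2_dump_lines())
  run <- parse_bonds_dump(f, elements_map_cho)
  expect_length(run$frames, 2L)
  for (fr in run$frames) {
    expect_equal(nrow(fr$bonds), 1L)
    expect_equal(fr$bonds$order, 2)
    expect_equal(fr$bonds$i, 1L)
    expect_equal(fr$atoms$element, c("O", "O"))
  }
  expect_equal(run$frames[[1]]$time_fs, 1000 * 0.25)
  expect_equal(frame_interval_fs(run$meta), 250)
  expect_equal(run$meta$n_frames, 2L)
})

test_that("asymmetric duplicate listings warn and keep the lower id's value", {
  f <- withr::local_tempfile(lines = toy_o2_dump_lines("1.0000", "1.2000"))
  w <- capture_warnings(run <- parse_bonds_dump(f, elements_map_cho))
  expect_length(w, 2L)  # one warning per affected frame
  expect_match(w, "asymmetric", all = TRUE)
  expect_equal(run$frames[[1]]$bonds$order, 1)
  # below the 0.05 tolerance: silent, still lower-id value
  f2 <- withr::local_tempfile(lines = toy_o2_dump_lines("1.0000", "1.0400"))
  expect_no_warning(run2 <- parse_bonds_dump(f2, elements_map_cho))
  expect_equal(run2$frames[[1]]$bonds$order, 1)
})

test_that("malformed input is rejected with a useful error", {
  # unknown atom type
  f <- withr::local_tempfile(lines = toy_o2_dump_lines())
  expect_error(parse_bonds_dump(f, c(`1` = "C")), "unknown atom type")
  # neighbor id absent from frame
  bad <- toy_o2_dump_lines()
  bad[9] <- "2 3 1 7 0 2.0000 2.0000 0.0000 0.0000"
  f2 <- withr::local_tempfile(lines = bad)
  expect_error(parse_bonds_dump(f2, elements_map_cho), "absent from frame")
  # malformed header
  bad2 <- toy_o2_dump_lines()
  bad2[1] <- "# Timestep banana"
  f3 <- withr::local_tempfile(lines = bad2)
  expect_error(parse_bonds_dump(f3, elements_map_cho), "line 1")
  expect_error(parse_bonds_dump(tempfile(), elements_map_cho), "no such file")
})

test_that("write -> parse round trip preserves orders to printed precision", {
  traj <- synth_scenario_A(n_copies = 3L, n_O2 = 6L, n_frames = 4L,
                           n_hloss = 0L, n_co2 = 0L, n_ethp = 0L,
                           noise_sd = 0.07, seed = 11)
  f <- withr::local_tempfile()
  write_bonds_dump(traj$frames, f)
  back <- parse_bonds_dump(f, elements_map_cho)
  expect_length(back$frames, 4L)
  for (k in seq_along(traj$frames)) {
    a <- traj$frames[[k]]$bonds
    b <- back$frames[[k]]$bonds
    m <- merge(a, b, by = c("i", "j"))
    expect_equal(nrow(m), nrow(a))
    expect_equal(m$order.y, round(m$order.x, 4))
  }
  # parse -> write -> parse is exact
  f2 <- withr::local_tempfile()
  write_bonds_dump(back$frames, f2)
  again <- parse_bonds_dump(f2, elements_map_cho)
  expect_equal(lapply(again$frames, `[[`, "bonds"),
               lapply(back$frames, `[[`, "bonds"))
})

test_that("packaged templates parse with the expected formulas and labels", {
  a <- mol_template_A()
  expect_equal(a$formula, "C19H30O3")
  expect_equal(nrow(a$atoms), 52L)
  expect_setequal(a$bonds$label[!is.na(a$bonds$label)],
                  c("1A", "2A", "3A", "4A"))
  b <- mol_template_B()
  expect_equal(b$formula, "C26H34O4")
  expect_equal(nrow(b$atoms), 64L)
  expect_setequal(b$bonds$label[!is.na(b$bonds$label)],
                  c("1B", "2B", "3B", "4B", "1B'", "2B'", "3B'", "4B'"))
  o2 <- o2_template()
  expect_equal(o2$formula, "O2")
  expect_equal(o2$bonds$order, 2)
})

test_that("template validation rejects broken files", {
  disc <- list(name = "x", formula = "C2", atoms = list(list(1L, "C"), list(2L, "C")),
               bonds = list())
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(disc, f, auto_unbox = TRUE, null = "null")
  expect_error(parse_template(f), "disconnected")
  coll <- list(name = "x", formula = "C2",
               atoms = list(list(1L, "C"), list(2L, "C")),
               bonds = list(list(1L, 2L, 1, "1A"), list(2L, 1L, 1, "1A")))
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(coll, f2, auto_unbox = TRUE, null = "null")
  expect_error(parse_template(f2), "label collision")
  wrong <- list(name = "x", formula = "C3", atoms = list(list(1L, "C"), list(2L, "C")),
                bonds = list(list(1L, 2L, 1, NULL)))
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(wrong, f3, auto_unbox = TRUE, null = "null")
  expect_error(parse_template(f3), "formula")
})

test_that("write_table sorts deterministically and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  # empty census -> header-only file
  empty <- data.frame(replicate = character(0), frame = integer(0),
                      time_ps = numeric(0), formula = character(0),
                      count = integer(0))
  write_table(empty, f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(names(read_table(f)), names(empty))
  # one frame with H2O and O2: rows sorted by formula
  rec <- data.frame(replicate = "r1", frame = 1L, time_ps = 0.25,
                    formula = c("O2", "H2O"), count = c(300L, 2L))
  write_table(rec, f)
  got <- read_table(f)
  expect_equal(got$formula, c("H2O", "O2"))
  expect_equal(got$count, c(2L, 300L))
  # round trip of an events table reproduces records exactly
  ev <- data.frame(replicate = "r1", molecule_index = c(2L, 1L),
                   bond_label_or_pair = c("4A", "1A"),
                   event_type = "dissociation", time_ps = c(25.123456, 12.5))
  written <- write_table(ev, f)
  expect_equal(read_table(f), written)
})
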