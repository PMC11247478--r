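# Brute-force reachability oracle: partition a frame's atoms by transitive
# closure of the thresholded adjacency matrix (independent of the igraph
# component path used by the package).
reach_oracle <- function(frame, cutoff) {
  ids <- frame$atoms$id
  n <- length(ids)
  A <- diag(TRUE, n)
  keep <- frame$bonds$order >= cutoff
  if (any(keep)) {
    pi <- match(frame$bonds$i[keep], ids)
    pj <- match(frame$bonds$j[keep], ids)
    A[cbind(pi, pj)] <- TRUE
    A[cbind(pj, pi)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  groups <- unique(apply(A, 1L, function(r) paste(sort(ids[r]), collapse = "-")))
  sort(groups)
}

partition_keys <- function(frame, cutoff) {
  sort(vapply(connected_species(frame, cutoff),
              function(s) paste(s$atom_ids, collapse = "-"), character(1)))
}

# random frame with shuffled, non-contiguous atom ids
random_frame <- function(n_atoms, n_bonds, elements = c("C", "H", "O")) {
  ids <- sort(sample.int(5L * n_atoms, n_atoms))
  atoms <- data.frame(id = ids, element = sample(elements, n_atoms, replace = TRUE))
  if (n_bonds == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  } else {
    pairs <- unique(matrix(t(replicate(n_bonds, sort(sample(ids, 2L)))),
                           ncol = 2L))
    bonds <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                        order = stats::runif(nrow(pairs), 0, 2))
  }
  bond_frame(0L, 0, atoms, bonds)
}

elements_map_cho <- c(`1` = "C", `2` = "H", `3` = "O")

# minimal hand-written dump: two frames of one O2 molecule
toy_o2_dump_lines <- function(order1 = "2.0000", order2 = "2.0000") {
  c("# Timestep 1000",
    "# ",
    "# Number of particles 2",
    "# ",
    "# Max number of bonds per atom 16 with coarse bond order cutoff 0.300",
    "# Particle connection table and bond orders",
    "# id type nb id_1...id_nb mol bo_1...bo_nb abo nlp q",
    paste("1 3 1 2 0", order1, order1, "2.0000 0.0000"),
    paste("2 3 1 1 0", order2, order2, "2.0000 0.0000"),
    "# ",
    "# Timestep 2000",
    "# ",
    "# Number of particles 2",
    "# ",
    "# Max number of bonds per atom 16 with coarse bond order cutoff 0.300",
    "# Particle connection table and bond orders",
    "# id type nb id_1...id_nb mol bo_1...bo_nb abo nlp q",
    paste("1 3 1 2 0", order1, order1, "2.0000 0.0000"),
    paste("2 3 1 1 0", order2, order2, "2.0000 0.0000"),
    "# ")
}
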