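#' Trajectory metadata
#'
#' Describes the timing of a bond-order dump: the MD integration step in fs,
#' how many MD steps elapse between dumped frames, and the number of frames.
#' The dump interval is `timestep_fs * frames_per_output` (250 fs for the
#' standard production protocol: 0.25 fs steps dumped every 1000 steps).
#'
#' @param timestep_fs MD integration timestep in femtoseconds (> 0).
#' @param frames_per_output MD steps between dumped frames (>= 1).
#' @param n_frames Number of dumped frames.
#' @param replicate_id Label for the replicate this trajectory belongs to.
#' @return An object of class `trajectory_meta`.
#' @export
trajectory_meta <- function(timestep_fs = 0.25, frames_per_output = 1000L,
                            n_frames = NA_integer_, replicate_id = "r1") {
  stopifnot(timestep_fs > 0, frames_per_output >= 1)
  structure(list(timestep_fs = timestep_fs,
                 frames_per_output = as.integer(frames_per_output),
                 n_frames = as.integer(n_frames),
                 replicate_id = replicate_id),
            class = "trajectory_meta")
}

#' @rdname trajectory_meta
#' @param meta A `trajectory_meta` object.
#' @export
frame_interval_fs <- function(meta) meta$timestep_fs * meta$frames_per_output

#' @rdname trajectory_meta
#' @export
frame_interval_ps <- function(meta) frame_interval_fs(meta) / 1000

#' Frame count of a dump protocol
#'
#' Number of dumped frames for a run of `duration_ps` picoseconds at one
#' frame every `interval_ps` picoseconds (1 ns at 0.25 ps/frame gives 4000).
#'
#' @param duration_ps Run duration in ps.
#' @param interval_ps Dump interval in ps.
#' @return Integer frame count.
#' @export
production_frame_count <- function(duration_ps = 1000, interval_ps = 0.25) {
  as.integer(round(duration_ps / interval_ps))
}

#' @export
print.trajectory_meta <- function(x, ...) {
  cat(sprintf("trajectory_meta: dt=%g fs, dump every %d steps (%g fs), %s frames [%s]\n",
              x$timestep_fs, x$frames_per_output, frame_interval_fs(x),
              ifelse(is.na(x$n_frames), "?", x$n_frames), x$replicate_id))
  invisible(x)
}

#' Construct a single-frame bond table
#'
#' A `bond_frame` holds one timestep's symmetric bond table: the atoms
#' (1-based ids with element symbols) and the pairwise fractional bond
#' orders, stored once per pair with `i < j`.
#'
#' @param timestep Integer MD step index of the frame.
#' @param time_fs Elapsed simulation time in fs.
#' @param atoms `data.frame` with columns `id` (unique 1-based integers) and
#'   `element` (symbols).
#' @param bonds `data.frame` with columns `i`, `j` (atom ids, `i < j`) and
#'   `order` (non-negative bond order).
#' @return An object of class `bond_frame`.
#' @export
bond_frame <- function(timestep, time_fs, atoms, bonds) {
  atoms <- data.frame(id = as.integer(atoms$id), element = as.character(atoms$element))
  if (anyDuplicated(atoms$id)) stop("bond_frame: duplicate atom ids")
  if (nrow(bonds) > 0) {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.numeric(bonds$order))
    swap <- bonds$i > bonds$j
    if (any(swap)) {
      tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    }
    if (any(bonds$i == bonds$j)) stop("bond_frame: self-bond")
    if (any(bonds$order < 0)) stop("bond_frame: negative bond order")
    miss <- !(bonds$i %in% atoms$id) | !(bonds$j %in% atoms$id)
    if (any(miss)) {
      stop("bond_frame: bond references unknown atom id ",
           paste(unique(c(bonds$i[miss], bonds$j[miss]))[1], collapse = ","))
    }
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  structure(list(timestep = as.integer(timestep), time_fs = as.numeric(time_fs),
                 atoms = atoms, bonds = bonds),
            class = "bond_frame")
}

#' @export
print.bond_frame <- function(x, ...) {
  cat(sprintf("bond_frame: timestep %d (%.1f fs), %d atoms, %d bonds\n",
              x$timestep, x$time_fs, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Read an atom-type to element map
#'
#' ReaxFF bond dumps store numeric atom types; the map file supplies the
#' element symbol for each type, one `type element` pair per line.
#'
#' @param path Path to a whitespace-separated two-column text file.
#' @return Named character vector: names are type ids, values element symbols.
#' @export
read_element_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("type", "element"),
                           colClasses = c("integer", "character"))
  stats::setNames(tab$element, as.character(tab$type))
}

#' Parse a ReaxFF bonds dump
#'
#' Reads the LAMMPS `reaxff/bonds` text dialect: per frame a comment block
#' (`# Timestep <n>`, `# Number of particles <n>`, column-header lines), then
#' one row per atom listing its id, numeric type, neighbor count, neighbor
#' ids, molecule id, the bond order to each neighbor, the total bond order,
#' lone-pair count and charge. Every bond appears in both partner rows; the
#' duplicate listings are reconciled to a single `i < j` entry keeping the
#' value from the lower atom id's row, with a warning when the two listings
#' disagree by more than 0.05.
#'
#' @param path Path to the dump file.
#' @param element_map Named character vector mapping numeric atom type to
#'   element symbol (see [read_element_map()]).
#' @param timestep_fs MD timestep in fs used to convert step index to time.
#' @param replicate_id Replicate label stored in the returned metadata.
#' @return A list with components `meta` (a [trajectory_meta()]) and `frames`
#'   (list of [bond_frame()], one per `# Timestep` block, in file order).
#' @export
parse_bonds_dump <- function(path, element_map, timestep_fs = 0.25,
                             replicate_id = "r1") {
  if (!file.exists(path)) stop("parse_bonds_dump: no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^#\\s*Timestep", lines)
  if (length(starts) == 0L) stop("parse_bonds_dump: no '# Timestep' header found")
  ends <- c(starts[-1L] - 1L, length(lines))
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- lines[starts[k]]
    ts <- suppressWarnings(as.integer(sub("^#\\s*Timestep\\s+", "", hdr)))
    if (is.na(ts)) {
      stop("parse_bonds_dump: malformed '# Timestep' header at line ", starts[k])
    }
    block <- lines[starts[k]:ends[k]]
    rows <- block[!grepl("^\\s*#", block) & nzchar(trimws(block))]
    frames[[k]] <- parse_dump_block(rows, ts, element_map, timestep_fs,
                                    line_offset = starts[k])
  }
  n <- length(frames)
  fpo <- if (n >= 2L) {
    d <- frames[[2L]]$timestep - frames[[1L]]$timestep
    if (d >= 1L) d else 1L
  } else {
    max(frames[[1L]]$timestep, 1L)
  }
  meta <- trajectory_meta(timestep_fs = timestep_fs, frames_per_output = fpo,
                          n_frames = n, replicate_id = replicate_id)
  list(meta = meta, frames = frames)
}

parse_dump_block <- function(rows, timestep, element_map, timestep_fs, line_offset) {
  n <- length(rows)
  ids <- integer(n); types <- integer(n)
  from <- vector("list", n); to <- vector("list", n); bo <- vector("list", n)
  for (r in seq_len(n)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[r]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < 3L) {
      stop("parse_bonds_dump: malformed atom row near line ", line_offset + r)
    }
    nb <- as.integer(v[3L])
    if (length(v) < 3L + nb + 1L + nb + 3L) {
      stop("parse_bonds_dump: truncated atom row near line ", line_offset + r)
    }
    ids[r] <- as.integer(v[1L]); types[r] <- as.integer(v[2L])
    if (nb > 0L) {
      from[[r]] <- rep.int(ids[r], nb)
      to[[r]] <- as.integer(v[3L + seq_len(nb)])
      bo[[r]] <- v[3L + nb + 1L + seq_len(nb)]
    }
  }
  el <- unname(element_map[as.character(types)])
  if (anyNA(el)) {
    stop("parse_bonds_dump: unknown atom type ",
         paste(unique(types[is.na(el)]), collapse = ","),
         " (not in element map)")
  }
  atoms <- data.frame(id = ids, element = el)
  from <- unlist(from); to <- unlist(to); ord <- unlist(bo)
  if (length(from) == 0L) {
    return(bond_frame(timestep, timestep * timestep_fs, atoms,
                      data.frame(i = integer(), j = integer(), order = numeric())))
  }
  if (!all(to %in% ids)) {
    bad <- setdiff(to, ids)[1]
    stop("parse_bonds_dump: atom row references neighbor id ", bad,
         " absent from frame at timestep ", timestep)
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi)
  owner_lo <- from == lo          # entry came from the lower atom id's row
  primary <- ord[owner_lo]
  names(primary) <- key[owner_lo]
  mirror <- ord[!owner_lo]
  names(mirror) <- key[!owner_lo]
  both <- intersect(names(primary), names(mirror))
  if (length(both) > 0L) {
    dif <- abs(primary[both] - mirror[both])
    nbad <- sum(dif > 0.05)
    if (nbad > 0L) {
      warning("parse_bonds_dump: ", nbad, " bond(s) at timestep ", timestep,
              " listed with asymmetric orders differing by > 0.05; ",
              "keeping the lower atom id's value")
    }
  }
  only_mirror <- setdiff(names(mirror), names(primary))
  vals <- c(primary, mirror[only_mirror])
  ij <- do.call(rbind, strsplit(names(vals), " ", fixed = TRUE))
  bonds <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                      order = as.numeric(vals))
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  bond_frame(timestep, timestep * timestep_fs, atoms, bonds)
}

#' Write frames in the ReaxFF bonds-dump dialect
#'
#' Emits the same text dialect that [parse_bonds_dump()] reads, listing every
#' bond in both partner rows (symmetric duplication) with orders printed to
#' four decimals.
#'
#' @param frames List of [bond_frame()] objects.
#' @param path Output file path.
#' @param type_map Named integer vector mapping element symbol to numeric
#'   atom type, e.g. `c(C = 1, H = 2, O = 3)`.
#' @return Invisibly, `path`.
#' @export
write_bonds_dump <- function(frames, path, type_map = c(C = 1L, H = 2L, O = 3L)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fr in frames) {
    atoms <- fr$atoms; bonds <- fr$bonds
    type <- type_map[atoms$element]
    if (anyNA(type)) stop("write_bonds_dump: element missing from type_map")
    nbr <- vector("list", nrow(atoms))
    obr <- vector("list", nrow(atoms))
    idx <- match(c(bonds$i, bonds$j), atoms$id)
    other <- c(bonds$j, bonds$i)
    oo <- c(bonds$order, bonds$order)
    if (length(idx) > 0L) {
      sp <- split(seq_along(idx), idx)
      for (nm in names(sp)) {
        a <- as.integer(nm)
        nbr[[a]] <- other[sp[[nm]]]
        obr[[a]] <- oo[sp[[nm]]]
      }
    }
    writeLines(c(sprintf("# Timestep %d", fr$timestep),
                 "# ",
                 sprintf("# Number of particles %d", nrow(atoms)),
                 "# ",
                 "# Max number of bonds per atom 16 with coarse bond order cutoff 0.300",
                 "# Particle connection table and bond orders",
                 "# id type nb id_1...id_nb mol bo_1...bo_nb abo nlp q"), con)
    for (a in seq_len(nrow(atoms))) {
      nb <- length(nbr[[a]])
      row <- c(atoms$id[a], type[a], nb, nbr[[a]], 0L,
               sprintf("%.4f", obr[[a]]), sprintf("%.4f", sum(obr[[a]])),
               "0.0000", "0.0000")
      writeLines(paste(row, collapse = " "), con)
    }
    writeLines("# ", con)
  }
  invisible(path)
}

#' Parse a molecule template
#'
#' Templates are JSON files with keys `name`, `formula`, `atoms`
#' (`[[index, element], ...]`) and `bonds` (`[[i, j, order, label|null], ...]`)
#' where `order` is the nominal bond order (1 or 2) and `label` names the
#' bonds tracked by the event analysis (e.g. `"1A"`). The template graph must
#' be connected, the declared formula must match the element multiset, and
#' labels must be unique.
#'
#' @param path Path to the JSON template.
#' @return An object of class `mol_template` with fields `name`, `formula`,
#'   `atoms` (`idx`, `element`) and `bonds` (`i`, `j`, `order`, `label`).
#' @export
parse_template <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  atoms <- data.frame(
    idx = vapply(js$atoms, function(a) as.integer(a[[1L]]), integer(1)),
    element = vapply(js$atoms, function(a) as.character(a[[2L]]), character(1)))
  bonds <- data.frame(
    i = vapply(js$bonds, function(b) as.integer(b[[1L]]), integer(1)),
    j = vapply(js$bonds, function(b) as.integer(b[[2L]]), integer(1)),
    order = vapply(js$bonds, function(b) as.numeric(b[[3L]]), numeric(1)),
    label = vapply(js$bonds, function(b) {
      if (length(b) < 4L || is.null(b[[4L]])) NA_character_ else as.character(b[[4L]])
    }, character(1)))
  if (anyDuplicated(atoms$idx)) stop("parse_template: duplicate atom indices")
  if (!all(bonds$i %in% atoms$idx) || !all(bonds$j %in% atoms$idx)) {
    stop("parse_template: bond references unknown atom index")
  }
  labs <- bonds$label[!is.na(bonds$label)]
  if (anyDuplicated(labs)) {
    stop("parse_template: label collision: ",
         paste(unique(labs[duplicated(labs)]), collapse = ","))
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(bonds$i, atoms$idx), match(bonds$j, atoms$idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(atoms) - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) {
    stop("parse_template: template graph is disconnected")
  }
  formula <- hill_formula(atoms$element)
  if (!is.null(js$formula) && !identical(js$formula, formula)) {
    stop("parse_template: declared formula ", js$formula,
         " does not match atoms (", formula, ")")
  }
  structure(list(name = js$name, formula = formula, atoms = atoms, bonds = bonds),
            class = "mol_template")
}

#' @export
print.mol_template <- function(x, ...) {
  labs <- x$bonds$label[!is.na(x$bonds$label)]
  cat(sprintf("mol_template '%s': %s, %d atoms, %d bonds, labels: %s\n",
              x$name, x$formula, nrow(x$atoms), nrow(x$bonds),
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
  invisible(x)
}

#' Packaged molecule templates
#'
#' Accessors for the templates shipped with the package: the modified lignin
#' monomer (molecule A, ethyl 3-(3,5-di-tert-butyl-4-hydroxyphenyl)propanoate,
#' C19H30O3, labeled bonds 1A-4A), the modified lignin dimer (molecule B,
#' 3,3'-di-tert-butyl-5,5'-di[(1E)-3-hydroxyprop-1-enyl]biphenyl-2,2'-diol,
#' C26H34O4, labeled bonds 1B-4B and 1B'-4B'), and molecular oxygen.
#'
#' @return A `mol_template`.
#' @export
mol_template_A <- function() {
  parse_template(system.file("extdata", "molecule_A.json", package = "reaxtrack"))
}

#' @rdname mol_template_A
#' @export
mol_template_B <- function() {
  parse_template(system.file("extdata", "molecule_B.json", package = "reaxtrack"))
}

#' @rdname mol_template_A
#' @export
o2_template <- function() {
  parse_template(system.file("extdata", "o2.json", package = "reaxtrack"))
}

#' Write an analysis table as CSV
#'
#' Common CSV writer for census, event, pathway and onset tables: numeric
#' columns are rounded to 6 significant digits and rows are sorted
#' deterministically (by time column when present, then by
#' formula/label/bond column, then remaining columns left to right).
#'
#' @param records A `data.frame` of records sharing one schema.
#' @param path Output path.
#' @return Invisibly, the sorted/rounded `data.frame` that was written.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6L)
  }
  keys <- intersect(c("time_ps", "formula", "label", "bond_label_or_pair",
                      "cutoff", "replicate"), names(out))
  keys <- c(keys, setdiff(names(out), keys))
  if (nrow(out) > 1L) {
    out <- out[do.call(order, unname(out[keys])), , drop = FALSE]
    rownames(out) <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
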