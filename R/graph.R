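#' Threshold a bond frame into an adjacency edge list
#'
#' A pair of atoms is considered bonded when its fractional bond order is
#' greater than or equal to the cutoff (closed lower bound, so a bond order
#' exactly at the cutoff counts as bonded). Raising the cutoff can only
#' remove edges.
#'
#' @param frame A [bond_frame()].
#' @param cutoff Bond-order threshold (> 0); the operating default throughout
#'   the package is 0.5.
#' @return A `data.frame` with columns `i`, `j` (the retained edges) carrying
#'   the frame's atom ids as attribute `atom_ids` and elements as `elements`.
#' @export
apply_cutoff <- function(frame, cutoff = 0.5) {
  stopifnot(inherits(frame, "bond_frame"), cutoff > 0)
  keep <- frame$bonds$order >= cutoff
  adj <- frame$bonds[keep, c("i", "j"), drop = FALSE]
  rownames(adj) <- NULL
  attr(adj, "atom_ids") <- frame$atoms$id
  attr(adj, "elements") <- frame$atoms$element
  adj
}

## membership vector (aligned with atom order) for an edge list over n atoms
component_membership <- function(edges_idx, n_atoms) {
  if (nrow(edges_idx) == 0L) return(seq_len(n_atoms))
  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(edges_idx)))
  as.integer(igraph::components(g)$membership)
}

## full partition of a frame at a cutoff; the workhorse behind
## connected_species / frame_census / build_timelines.
## Returns ids-per-component (sorted, components ordered by smallest atom id),
## formulas, stable instance keys, and the per-atom component index.
partition_frame <- function(frame, cutoff = 0.5) {
  adj <- apply_cutoff(frame, cutoff)
  ids <- frame$atoms$id
  el <- frame$atoms$element
  memb <- component_membership(
    cbind(match(adj$i, ids), match(adj$j, ids)), length(ids))
  comp_ids <- split(ids, memb)
  comp_el <- split(el, memb)
  mins <- vapply(comp_ids, min, numeric(1))
  ord <- order(mins)
  comp_ids <- lapply(comp_ids[ord], sort)
  comp_el <- comp_el[ord]
  formulas <- vapply(comp_el, hill_formula, character(1))
  keys <- vapply(comp_ids, function(x) paste(x, collapse = "-"), character(1))
  memb <- match(memb, as.integer(names(mins))[ord])
  list(ids = unname(comp_ids), formulas = unname(formulas),
       keys = unname(keys), membership = memb)
}

#' Chemical species in one frame
#'
#' Identifies the chemical species of a frame as the connected components of
#' the bonded graph at the given cutoff (the graph-traversal species
#' detection step). Every atom belongs to exactly one species; species are
#' returned ordered by their smallest atom id.
#'
#' @inheritParams apply_cutoff
#' @return A list of species instances, each a list with `atom_ids` (sorted
#'   1-based ids) and `formula` (canonical Hill string).
#' @export
connected_species <- function(frame, cutoff = 0.5) {
  p <- partition_frame(frame, cutoff)
  mapply(function(ids, f) list(atom_ids = ids, formula = f),
         p$ids, p$formulas, SIMPLIFY = FALSE)
}

#' Species census of one frame
#'
#' Counts species instances per canonical formula at the given cutoff.
#' Atom conservation holds by construction: the formula atom counts times the
#' census counts sum to the frame's atom total.
#'
#' @inheritParams apply_cutoff
#' @return Named integer vector (names are Hill formulas, sorted), counts of
#'   instances per formula. Empty frame gives an empty vector.
#' @export
frame_census <- function(frame, cutoff = 0.5) {
  if (nrow(frame$atoms) == 0L) return(stats::setNames(integer(0), character(0)))
  p <- partition_frame(frame, cutoff)
  tab <- table(p$formulas)
  stats::setNames(as.integer(tab), names(tab))
}
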