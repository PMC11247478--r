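# Build the packaged molecule templates (run from /root/pkg).
# Molecule A: ethyl 3-(3,5-di-tert-butyl-4-hydroxyphenyl)propanoate, C19H30O3.
# Molecule B: 3,3'-di-tert-butyl-5,5'-di[(1E)-3-hydroxyprop-1-enyl]biphenyl-2,2'-diol, C26H34O4.

hill <- function(els) {
  counts <- table(els); e <- sort(names(counts))
  if ("C" %in% e) e <- c(intersect(c("C", "H"), e), setdiff(e, c("C", "H")))
  n <- as.integer(counts[e]); paste0(e, ifelse(n == 1, "", n), collapse = "")
}

## ---- molecule A ------------------------------------------------------------
# 1-6 aromatic ring (Kekule); C1 propanoate chain, C3/C5 tert-butyl, C4 phenol.
elA <- c(rep("C", 6), "O", "H", rep("C", 8), "C", "C", "C", "O", "O", "C", "C",
         rep("H", 29))
stopifnot(length(elA) == 52)
bA <- rbind(
  c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2), c(6, 1, 1),
  c(4, 7, 1),                    # ring C-O (phenol)
  c(7, 8, 1),                    # 1A: phenolic O-H
  c(3, 9, 1), c(9, 10, 1), c(9, 11, 1), c(9, 12, 1),
  c(5, 13, 1), c(13, 14, 1), c(13, 15, 1), c(13, 16, 1),
  c(1, 17, 1), c(17, 18, 1),
  c(18, 19, 1),                  # 2A: Calpha-C(=O)
  c(19, 20, 2),                  # carbonyl C=O
  c(19, 21, 1),                  # 3A: ester C-O
  c(21, 22, 1),                  # 4A: ester O-CH2 (ethyl)
  c(22, 23, 1),
  c(2, 24, 1), c(6, 25, 1),
  c(10, 26, 1), c(10, 27, 1), c(10, 28, 1),
  c(11, 29, 1), c(11, 30, 1), c(11, 31, 1),
  c(12, 32, 1), c(12, 33, 1), c(12, 34, 1),
  c(14, 35, 1), c(14, 36, 1), c(14, 37, 1),
  c(15, 38, 1), c(15, 39, 1), c(15, 40, 1),
  c(16, 41, 1), c(16, 42, 1), c(16, 43, 1),
  c(17, 44, 1), c(17, 45, 1), c(18, 46, 1), c(18, 47, 1),
  c(22, 48, 1), c(22, 49, 1),
  c(23, 50, 1), c(23, 51, 1), c(23, 52, 1))
labA <- rep(NA_character_, nrow(bA))
labA[bA[, 1] == 7 & bA[, 2] == 8] <- "1A"
labA[bA[, 1] == 18 & bA[, 2] == 19] <- "2A"
labA[bA[, 1] == 19 & bA[, 2] == 21] <- "3A"
labA[bA[, 1] == 21 & bA[, 2] == 22] <- "4A"

## ---- molecule B ------------------------------------------------------------
# Per half (local 1-32, half 2 offset +32): ring 1-6 (C1 biphenyl link,
# C2 phenol, C3 tBu, C5 (E)-3-hydroxyprop-1-enyl), 7 phenol O, 8 phenol H,
# 9-12 tBu, 13=CH, 14=CH, 15 CH2, 16 side O, 17 side H, 18- H atoms.
half_el <- c(rep("C", 6), "O", "H", rep("C", 4), "C", "C", "C", "O", "H",
             rep("H", 15))
stopifnot(length(half_el) == 32)
half_bonds <- function(off, p) {
  lab <- function(x) paste0(x, if (p) "'" else "")
  b <- rbind(
    c(1, 2, 2, NA), c(2, 3, 1, NA), c(3, 4, 2, NA), c(4, 5, 1, NA),
    c(5, 6, 2, NA), c(6, 1, 1, NA),
    c(2, 7, 1, lab("3B")),        # ring C-O
    c(7, 8, 1, lab("1B")),        # phenolic O-H
    c(3, 9, 1, NA), c(9, 10, 1, NA), c(9, 11, 1, NA), c(9, 12, 1, NA),
    c(5, 13, 1, NA), c(13, 14, 2, NA), c(14, 15, 1, NA),
    c(15, 16, 1, lab("4B")),      # side-chain C-O
    c(16, 17, 1, lab("2B")),      # side-chain O-H
    c(4, 18, 1, NA), c(6, 19, 1, NA),
    c(10, 20, 1, NA), c(10, 21, 1, NA), c(10, 22, 1, NA),
    c(11, 23, 1, NA), c(11, 24, 1, NA), c(11, 25, 1, NA),
    c(12, 26, 1, NA), c(12, 27, 1, NA), c(12, 28, 1, NA),
    c(13, 29, 1, NA), c(14, 30, 1, NA), c(15, 31, 1, NA), c(15, 32, 1, NA))
  data.frame(i = as.integer(b[, 1]) + off, j = as.integer(b[, 2]) + off,
             order = as.numeric(b[, 3]), label = b[, 4])
}
elB <- c(half_el, half_el)
bB <- rbind(half_bonds(0L, FALSE), half_bonds(32L, TRUE),
            data.frame(i = 1L, j = 33L, order = 1, label = NA))

## ---- checks ----------------------------------------------------------------
check <- function(el, bonds, formula, n_labels) {
  stopifnot(hill(el) == formula)
  deg <- numeric(length(el))
  val <- numeric(length(el))
  for (r in seq_len(nrow(bonds))) {
    deg[bonds$i[r]] <- deg[bonds$i[r]] + 1
    deg[bonds$j[r]] <- deg[bonds$j[r]] + 1
    val[bonds$i[r]] <- val[bonds$i[r]] + bonds$order[r]
    val[bonds$j[r]] <- val[bonds$j[r]] + bonds$order[r]
  }
  want <- c(C = 4, H = 1, O = 2)[el]
  stopifnot(all(val == want))
  # connectivity via simple BFS
  adj <- lapply(seq_along(el), function(a)
    c(bonds$j[bonds$i == a], bonds$i[bonds$j == a]))
  seen <- logical(length(el)); q <- 1L; seen[1] <- TRUE
  while (length(q)) {
    a <- q[1]; q <- q[-1]
    for (nb in adj[[a]]) if (!seen[nb]) { seen[nb] <- TRUE; q <- c(q, nb) }
  }
  stopifnot(all(seen))
  stopifnot(sum(!is.na(bonds$label)) == n_labels)
  cat(formula, ": OK (", length(el), "atoms,", nrow(bonds), "bonds )\n")
}
bAdf <- data.frame(i = as.integer(bA[, 1]), j = as.integer(bA[, 2]),
                   order = as.numeric(bA[, 3]), label = labA)
check(elA, bAdf, "C19H30O3", 4)
check(elB, bB, "C26H34O4", 8)

## ---- write JSON ------------------------------------------------------------
tmpl_json <- function(name, el, bonds, path) {
  atoms <- lapply(seq_along(el), function(a) list(a, el[a]))
  bl <- lapply(seq_len(nrow(bonds)), function(r) {
    list(bonds$i[r], bonds$j[r], bonds$order[r],
         if (is.na(bonds$label[r])) NULL else bonds$label[r])
  })
  jsonlite::write_json(list(name = name, formula = hill(el), atoms = atoms,
                            bonds = bl),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  cat("wrote", path, "\n")
}
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
tmpl_json("molecule_A", elA, bAdf, "inst/extdata/molecule_A.json")
tmpl_json("molecule_B", elB, bB, "inst/extdata/molecule_B.json")
tmpl_json("O2", c("O", "O"), data.frame(i = 1L, j = 2L, order = 2,
                                        label = NA_character_),
          "inst/extdata/o2.json")
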