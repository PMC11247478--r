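#' Canonical Hill formula from an element multiset
#'
#' Orders elements by the Hill convention: carbon first, hydrogen second,
#' all remaining elements alphabetically. When no carbon is present the
#' ordering is purely alphabetical (so water is `"H2O"`, not `"OH2"`).
#' A count suffix is omitted when an element occurs once.
#'
#' @param elements Character vector of element symbols, one entry per atom
#'   (repeats allowed), e.g. `c("C","H","H","H","H")`.
#' @return A single formula string, e.g. `"CH4"`.
#' @examples
#' hill_formula(c("C", "C", "H", "H", "H", "H", "H", "H", "O", "O"))  # "C2H6O2"
#' hill_formula(c("O", "H", "H"))  # "H2O"
#' @export
hill_formula <- function(elements) {
  if (length(elements) == 0L) {
    stop("hill_formula: empty element multiset")
  }
  counts <- table(elements)
  els <- sort(names(counts))
  if ("C" %in% els) {
    first <- intersect(c("C", "H"), els)
    els <- c(first, setdiff(els, first))
  }
  n <- as.integer(counts[els])
  paste0(els, ifelse(n == 1L, "", n), collapse = "")
}

## element counts (named integer) from a formula string; inverse of hill_formula
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0L || paste0(parts, collapse = "") != formula) {
    stop("parse_formula: malformed formula '", formula, "'")
  }
  els <- sub("[0-9]+$", "", parts)
  ns <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(ns == "", 1L, as.integer(ns))
  stats::setNames(as.integer(n), els)
}

## total atom count encoded by a Hill formula string
formula_atom_count <- function(formula) {
  sum(parse_formula(formula))
}
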