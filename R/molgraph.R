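# Molecular graph container used throughout the package.  Kept deliberately
# minimal: elements, formal charges, and typed bonds are all the atom-coloring
# featurization needs.  No perception (aromaticity, stereo, valence models).

# IUPAC element symbols, H through Og.
.periodic_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Construct a molecular graph
#'
#' A `molecule_graph` holds the connection table of one compound: an ordered
#' atom list (element symbol plus formal charge) and a bond list with integer
#' bond orders.  Order code 4 denotes an aromatic bond and is treated as its
#' own bond type; no kekulization or aromaticity perception is performed.
#'
#' @param compound_id Non-empty identifier string.
#' @param elements Character vector of element symbols, one per atom.
#' @param charges Integer vector of formal charges, one per atom (default 0).
#' @param bonds Integer matrix with columns `a`, `b`, `order`; `a` and `b` are
#'   1-based atom indices, `order` is in 1:4 (4 = aromatic).
#' @return An object of class `molecule_graph`.
#' @examples
#' water <- molecule_graph("water", c("O", "H", "H"),
#'                         bonds = rbind(c(1, 2, 1), c(1, 3, 1)))
#' compound_size(water)
#' @export
molecule_graph <- function(compound_id, elements,
                           charges = integer(length(elements)),
                           bonds = matrix(integer(0), 0L, 3L)) {
  if (!is.character(compound_id) || length(compound_id) != 1L ||
      is.na(compound_id) || !nzchar(compound_id)) {
    stop("'compound_id' must be a single non-empty string", call. = FALSE)
  }
  elements <- as.character(elements)
  bad <- setdiff(unique(elements), .periodic_symbols)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  charges <- as.integer(charges)
  if (length(charges) != length(elements)) {
    stop("'charges' must have one entry per atom", call. = FALSE)
  }
  if (is.null(dim(bonds))) bonds <- matrix(as.integer(bonds), ncol = 3L)
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("a", "b", "order")))
  n <- length(elements)
  if (nrow(bonds)) {
    a <- bonds[, 1L]; b <- bonds[, 2L]; o <- bonds[, 3L]
    if (anyNA(bonds)) stop("bond table contains NA", call. = FALSE)
    if (any(a < 1L | a > n | b < 1L | b > n)) {
      stop("bond references nonexistent atom (index out of range)",
           call. = FALSE)
    }
    if (any(a == b)) stop("self-bonds are not allowed", call. = FALSE)
    if (!all(o %in% 1:4)) {
      stop("bond order must be 1, 2, 3, or 4 (aromatic)", call. = FALSE)
    }
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) {
      stop("duplicate bond between the same atom pair", call. = FALSE)
    }
  }
  structure(list(compound_id = compound_id, elements = elements,
                 charges = charges, bonds = bonds),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d atoms, %d bonds\n",
              x$compound_id, length(x$elements), nrow(x$bonds)))
  comp <- table(x$elements)
  cat("  composition:",
      paste(sprintf("%s%d", names(comp), as.integer(comp)), collapse = " "),
      "\n")
  invisible(x)
}

# Adjacency list: for each atom, a 2-column matrix (neighbor, order).
.mol_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- rep(list(matrix(integer(0), 0L, 2L)), n)
  if (nrow(graph$bonds)) {
    b <- graph$bonds
    both <- rbind(cbind(b[, 1L], b[, 2L], b[, 3L]),
                  cbind(b[, 2L], b[, 1L], b[, 3L]))
    sp <- split.data.frame(both[, 2:3, drop = FALSE], both[, 1L])
    for (nm in names(sp)) adj[[as.integer(nm)]] <- as.matrix(sp[[nm]])
  }
  adj
}
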