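# Molecular data model: an atom table (tibble), a bond graph, and named
# rotatable dihedrals.  Conformations are plain N x 3 matrices in Angstrom,
# row-aligned with the atom table.

#' Build an atom table
#'
#' Creates the per-atom tibble used throughout the package.  One row per
#' atom with identity (name, element, residue, chain), coordinates (Angstrom),
#' nonbonded parameters (partial charge in elementary units, Lennard-Jones
#' sigma in Angstrom and epsilon in kcal/mol) and interaction role flags.
#' `is_heavy` is derived from the element; hydrogen-bond donor/acceptor and
#' hydrophobic flags default to `FALSE` and are typically set by the caller
#' or by [assign_hydrophobic_flags()].
#'
#' @param name Character vector of atom names (e.g. "OD1", "N").
#' @param element Character vector of element symbols; must be nonempty.
#' @param x,y,z Coordinates in Angstrom.
#' @param charge Partial charges, elementary charge units.
#' @param sigma,epsilon Lennard-Jones parameters (Angstrom, kcal/mol),
#'   both nonnegative.
#' @param resname,resno,chain Residue name, residue number, chain identifier.
#' @param donor,acceptor,hydrophobic Logical role flags.
#' @return A tibble with one row per atom and an integer `index` column
#'   (1-based).
#' @examples
#' atom_table(name = c("C1", "C2"), element = c("C", "C"),
#'            x = c(0, 1.54), y = 0, z = 0)
#' @export
atom_table <- function(name, element, x = 0, y = 0, z = 0,
                       charge = 0, sigma = 0, epsilon = 0,
                       resname = "LIG", resno = 1L, chain = "A",
                       donor = FALSE, acceptor = FALSE, hydrophobic = FALSE) {
  n <- length(name)
  element <- rep_len(as.character(element), n)
  if (any(!nzchar(element))) {
    abort("every atom needs a nonempty element symbol")
  }
  if (any(sigma < 0) || any(epsilon < 0)) {
    abort("Lennard-Jones sigma and epsilon must be nonnegative")
  }
  tibble(
    index = seq_len(n),
    name = as.character(name), element = as.character(element),
    resname = rep_len(resname, n), resno = as.integer(rep_len(resno, n)),
    chain = rep_len(chain, n),
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    charge = rep_len(as.numeric(charge), n),
    sigma = rep_len(as.numeric(sigma), n),
    epsilon = rep_len(as.numeric(epsilon), n),
    is_heavy = element != "H",
    donor = rep_len(donor, n), acceptor = rep_len(acceptor, n),
    hydrophobic = rep_len(hydrophobic, n)
  )
}

#' Assemble a molecule from an atom table and bond list
#'
#' A `molecule` couples an atom table with an undirected bond graph and a
#' list of labelled rotatable dihedrals.  The bond graph of a single
#' molecule must be connected, contain no self-edges, and reference valid
#' atom indices.
#'
#' @param atoms Atom tibble from [atom_table()].
#' @param bonds Two-column integer matrix (or data frame) of 1-based atom
#'   index pairs.
#' @param name Molecule name.
#' @param dihedrals Optional named list of [dihedral_spec()] objects.
#' @return An object of class `molecule`: a list with elements `atoms`,
#'   `bonds`, `name`, `dihedrals`.
#' @export
molecule <- function(atoms, bonds, name = "MOL", dihedrals = list()) {
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2) abort("bonds must have two columns")
  n <- nrow(atoms)
  if (any(bonds < 1L) || any(bonds > n)) abort("bond indices out of range")
  if (any(bonds[, 1] == bonds[, 2])) abort("bond graph must have no self-edges")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) {
    abort("bond graph of a single molecule must be connected")
  }
  structure(
    list(atoms = atoms, bonds = bonds, name = name, dihedrals = dihedrals),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, %d labelled dihedral(s)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), length(x$dihedrals)))
  invisible(x)
}

#' Extract the reference conformation of a molecule
#'
#' @param mol A [molecule()].
#' @return N x 3 numeric matrix of coordinates (Angstrom).
#' @export
conformation <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Define a rotatable dihedral
#'
#' A dihedral is an ordered 4-tuple of distinct atom indices (i-j-k-l) whose
#' middle pair (j, k) must be a bond, plus the set of atoms that move when
#' the j-k bond is rotated.  The rotating set must contain atom l and must
#' not contain atom i.  Labels follow the Greek-letter convention used for
#' catecholamine torsions (alpha, beta, gamma, ...).
#'
#' @param label Character label for the dihedral.
#' @param atoms Integer vector of four distinct 1-based atom indices.
#' @param rotating Integer vector: indices moved by a rotation of the bond.
#' @param mol Optional [molecule()] used to validate that (j, k) is a bond
#'   and that the rotating set is the connected far side of that bond.
#' @return Object of class `dihedral_spec`.
#' @export
dihedral_spec <- function(label, atoms, rotating, mol = NULL) {
  atoms <- as.integer(atoms)
  rotating <- sort(as.integer(rotating))
  if (length(atoms) != 4 || anyDuplicated(atoms)) {
    abort("a dihedral needs four distinct atom indices")
  }
  if (!(atoms[4] %in% rotating)) abort("rotating set must contain the last dihedral atom")
  if (atoms[1] %in% rotating) abort("rotating set must not contain the first dihedral atom")
  if (!is.null(mol)) {
    jk <- sort(atoms[2:3])
    hit <- any(mol$bonds[, 1] == jk[1] & mol$bonds[, 2] == jk[2])
    if (!hit) abort("middle atom pair of a dihedral must be a bond")
    far <- far_side_atoms(mol, atoms[2], atoms[3])
    if (!setequal(rotating, far)) {
      abort("rotating set is not the connected far side of the central bond")
    }
  }
  structure(list(label = label, atoms = atoms, rotating = rotating),
            class = "dihedral_spec")
}

# Atoms on the k side of bond j-k (excluding j's side), by graph traversal
# with the j-k edge removed.
far_side_atoms <- function(mol, j, k) {
  g <- igraph::graph_from_edgelist(mol$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mol$atoms) - igraph::vcount(g)))
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k)))
  comp <- igraph::components(g)$membership
  which(comp == comp[k])
}
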