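# Rigid-body and dihedral geometry on N x 3 coordinate matrices.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Measure a signed dihedral angle
#'
#' Standard signed torsion about the middle bond of a four-atom sequence,
#' IUPAC sign convention, returned in degrees in the range (-180, 180].
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @param spec A [dihedral_spec()] (only its four atom indices are used),
#'   or an integer vector of four atom indices.
#' @return Angle in degrees, in (-180, 180].
#' @examples
#' butane <- make_toy_ligand("butane_like")
#' measure_dihedral(conformation(butane), butane$dihedrals[[1]])
#' @export
measure_dihedral <- function(conf, spec) {
  idx <- if (inherits(spec, "dihedral_spec")) spec$atoms else as.integer(spec)
  p <- conf[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    abort("degenerate geometry: three consecutive dihedral atoms are collinear")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# Rotation matrix for angle (radians) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, angle) {
  u <- u / vnorm(u)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotate the far side of a bond to a target dihedral angle
#'
#' Rotates exactly the atoms in the dihedral's rotating set about the middle
#' bond so that the measured dihedral equals `target_deg`.  Atoms outside
#' the rotating set are untouched, so bond lengths and angles inside each
#' rigid half are preserved exactly.
#'
#' @param conf N x 3 coordinate matrix.
#' @param spec A [dihedral_spec()].
#' @param target_deg Target dihedral angle in degrees.
#' @return New N x 3 coordinate matrix with
#'   `measure_dihedral(result, spec) == target_deg` (to numerical precision).
#' @export
rotate_about_bond <- function(conf, spec, target_deg) {
  if (!inherits(spec, "dihedral_spec")) abort("spec must be a dihedral_spec")
  near <- spec$atoms[1:2]
  if (any(near %in% spec$rotating)) {
    abort("inconsistent spec: rotating set contains a near-side atom")
  }
  current <- measure_dihedral(conf, spec)
  delta <- deg2rad(target_deg - current)
  j <- spec$atoms[2]; k <- spec$atoms[3]
  axis <- conf[k, ] - conf[j, ]
  R <- rotation_about_axis(axis, delta)
  out <- conf
  moved <- conf[spec$rotating, , drop = FALSE]
  moved <- sweep(moved, 2, conf[j, ])
  out[spec$rotating, ] <- sweep(moved %*% t(R), 2, conf[j, ], `+`)
  out
}

#' In-place (common-frame) RMSD between two conformations
#'
#' Root-mean-square deviation over an atom subset with no superposition:
#' atoms are compared in the frame they sit in, index-aligned, as a docking
#' program does with a fixed receptor frame.
#'
#' @param a,b N x 3 coordinate matrices with index-aligned atoms.
#' @param subset Integer vector of atom indices; defaults to all atoms.
#' @return RMSD in Angstrom.
#' @export
rmsd_in_place <- function(a, b, subset = seq_len(nrow(a))) {
  if (length(subset) == 0) abort("subset must be nonempty")
  d <- a[subset, , drop = FALSE] - b[subset, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Least-squares rigid superposition (Kabsch) and superimposed RMSD
#'
#' Finds the proper rotation and translation minimizing the RMSD of `b`
#' onto `a` over the given subset (singular value decomposition of the
#' covariance, determinant-corrected so no reflection is ever returned),
#' and reports the minimized RMSD.  The superimposed RMSD can never exceed
#' the in-place RMSD.
#'
#' @inheritParams rmsd_in_place
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation` applied to `b`), and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(a, b, subset = seq_len(nrow(a))) {
  if (length(subset) < 3) abort("superposition needs at least 3 subset atoms")
  pa <- a[subset, , drop = FALSE]
  pb <- b[subset, , drop = FALSE]
  ca <- colMeans(pa); cb <- colMeans(pb)
  A <- sweep(pa, 2, ca); B <- sweep(pb, 2, cb)
  # collinearity check: rank of centred coordinates
  if (qr(A)$rank < 2 || qr(B)$rank < 2) {
    abort("degenerate subset: atoms are collinear, superposition is ill-defined")
  }
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  translation <- ca - as.numeric(R %*% cb)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param conf N x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(conf, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(conf %*% t(rotation), 2, translation, `+`)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the selected atoms from their centroid.
#' Unweighted by default (the convention used for ligand sizing in docking
#' grid setups); set `weights` to atomic masses for the mass-weighted form.
#'
#' @param conf N x 3 coordinate matrix.
#' @param subset Integer atom indices; defaults to all.
#' @param weights Optional nonnegative weights (e.g. masses), recycled over
#'   the subset.
#' @return Radius of gyration in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))) # 1
#' @export
radius_of_gyration <- function(conf, subset = seq_len(nrow(conf)), weights = NULL) {
  if (length(subset) == 0) abort("subset must be nonempty")
  p <- conf[subset, , drop = FALSE]
  if (is.null(weights)) {
    ctr <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
  } else {
    w <- rep_len(weights, nrow(p))
    ctr <- colSums(p * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(p, 2, ctr)^2)) / sum(w))
  }
}
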