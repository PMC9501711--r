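# Intramolecular nonbonded (Coulomb + Lennard-Jones) energy, used to strip
# the nonbonded background out of quantum-mechanical torsional scans.

#' Define a nonbonded energy model
#'
#' Parameters of the pairwise Coulomb + Lennard-Jones model.  Defaults are
#' the OPLS all-atom conventions: Coulomb prefactor 332.0636
#' kcal A / (mol e^2), vacuum dielectric, 1-4 interactions scaled by 0.5
#' for both electrostatics and dispersion, geometric-mean combining for
#' both sigma and epsilon.
#'
#' @param coulomb_constant Coulomb prefactor, kcal A / (mol e^2).
#' @param relative_dielectric Relative dielectric constant (>= 1 typical).
#' @param scale14_coulomb,scale14_lj 1-4 scale factors in \[0, 1\].
#' @param combining_rule Only "geometric" is implemented.
#' @return Object of class `nonbonded_model` (a named list).
#' @export
nonbonded_model <- function(coulomb_constant = 332.0636,
                            relative_dielectric = 1,
                            scale14_coulomb = 0.5,
                            scale14_lj = 0.5,
                            combining_rule = "geometric") {
  if (coulomb_constant <= 0 || relative_dielectric <= 0) {
    abort("nonbonded constants must be positive")
  }
  if (any(c(scale14_coulomb, scale14_lj) < 0) ||
      any(c(scale14_coulomb, scale14_lj) > 1)) {
    abort("1-4 scale factors must lie in [0, 1]")
  }
  combining_rule <- match.arg(combining_rule, "geometric")
  structure(list(coulomb_constant = coulomb_constant,
                 relative_dielectric = relative_dielectric,
                 scale14_coulomb = scale14_coulomb,
                 scale14_lj = scale14_lj,
                 combining_rule = combining_rule),
            class = "nonbonded_model")
}

#' Intramolecular nonbonded energy of a conformation
#'
#' Sums Coulomb `k q_i q_j / (eps_r r)` and Lennard-Jones
#' `4 eps \[(sigma/r)^12 - (sigma/r)^6\]` over all atom pairs whose
#' exclusion class is `scaled_14` (multiplied by the model's 1-4 scale
#' factors) or `full`.  Pairs closer than 0.1 Angstrom raise a clash error.
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @param mol A [molecule()] supplying charges and LJ parameters.
#' @param model A [nonbonded_model()].
#' @param exclusions Pair table from [build_exclusions()]; computed from
#'   `mol` when omitted.
#' @return Energy in kcal/mol.
#' @export
nonbonded_energy <- function(conf, mol, model = nonbonded_model(),
                             exclusions = NULL) {
  exclusions <- exclusions %||% build_exclusions(mol)
  act <- exclusions[exclusions$class %in% c("scaled_14", "full"), ]
  if (nrow(act) == 0) return(0)
  i <- act$i; j <- act$j
  d <- conf[i, , drop = FALSE] - conf[j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r < 0.1)) {
    bad <- which(r < 0.1)[1]
    abort(sprintf("steric clash: atoms %d and %d at %.3f A", i[bad], j[bad], r[bad]))
  }
  at <- mol$atoms
  qq <- at$charge[i] * at$charge[j]
  e_c <- model$coulomb_constant * qq / (model$relative_dielectric * r)
  sig <- sqrt(at$sigma[i] * at$sigma[j])
  eps <- sqrt(at$epsilon[i] * at$epsilon[j])
  sr6 <- (sig / r)^6
  e_lj <- 4 * eps * (sr6^2 - sr6)
  s14 <- act$class == "scaled_14"
  sum(e_c * ifelse(s14, model$scale14_coulomb, 1)) +
    sum(e_lj * ifelse(s14, model$scale14_lj, 1))
}
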