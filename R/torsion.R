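# Torsional stage of force-field derivation: strip the nonbonded background
# from a QM dihedral scan and fit the residual with an OPLS-style cosine
# series by linear least squares.

#' Container for a quantum-mechanical torsional scan
#'
#' Couples a dihedral definition with scan points: one conformation and one
#' QM energy per scanned angle.  Energies are stored in kJ/mol (converted
#' on input if given in kcal/mol).
#'
#' @param dihedral A [dihedral_spec()].
#' @param angle Numeric vector of scan angles, degrees; unique modulo 360.
#' @param conformations List of N x 3 coordinate matrices, one per angle.
#' @param qm_energy Numeric vector of QM energies.
#' @param unit Unit of `qm_energy`: "kJ/mol" (default) or "kcal/mol".
#' @return Object of class `torsion_scan`: tibble with columns `angle`,
#'   `qm_energy` (kJ/mol) and list-column `conf`, with the dihedral spec
#'   attached as attribute `dihedral`.
#' @export
torsion_scan <- function(dihedral, angle, conformations, qm_energy,
                         unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  if (length(angle) < 8) abort("a torsional scan needs at least 8 points")
  if (anyDuplicated(round(wrap_angle(angle), 9))) {
    abort("scan angles must be unique modulo 360")
  }
  if (!all(is.finite(qm_energy))) abort("scan energies must be finite")
  if (unit == "kcal/mol") qm_energy <- kcal_to_kj(qm_energy)
  out <- tibble(angle = wrap_angle(angle), qm_energy = qm_energy,
                conf = conformations)
  structure(out, dihedral = dihedral,
            class = c("torsion_scan", class(out)))
}

#' Define an OPLS-style cosine torsional term
#'
#' The torsional potential is the alternating-sign OPLS Fourier series
#' `V(theta) = sum_n 1/2 V_n (1 + (-1)^(n+1) cos(n theta))`, i.e.
#' `1/2 V1 (1 + cos theta) + 1/2 V2 (1 - cos 2 theta) + ...`, plus an
#' additive constant.  Coefficients are in kJ/mol.
#'
#' @param coefficients Numeric vector `V_1 .. V_N`, kJ/mol.
#' @param offset Additive constant, kJ/mol.
#' @param label Optional dihedral label.
#' @return Object of class `fourier_torsion`.
#' @examples
#' evaluate_torsion(fourier_torsion(c(0, 0, 2)), c(0, 60, 180))
#' @export
fourier_torsion <- function(coefficients, offset = 0, label = NULL) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || !all(is.finite(coefficients)) ||
      !is.finite(offset)) {
    abort("fourier_torsion needs at least one finite coefficient")
  }
  structure(list(coefficients = coefficients, offset = offset, label = label),
            class = "fourier_torsion")
}

#' @export
print.fourier_torsion <- function(x, ...) {
  cat("<fourier_torsion>",
      if (!is.null(x$label)) paste0("[", x$label, "]") else "",
      paste(sprintf("V%d=%.4g", seq_along(x$coefficients), x$coefficients),
            collapse = " "),
      sprintf("offset=%.4g kJ/mol\n", x$offset))
  invisible(x)
}

# Design matrix of the alternating OPLS basis at angles in degrees.
opls_basis <- function(angle_deg, max_order) {
  th <- deg2rad(angle_deg)
  vapply(seq_len(max_order), function(n) {
    s <- if (n %% 2 == 1) 1 else -1
    0.5 * (1 + s * cos(n * th))
  }, numeric(length(th)))
}

#' Evaluate a torsional term
#'
#' @param term A [fourier_torsion()].
#' @param angle_deg Angles in degrees (vectorised); the potential has
#'   period 360 degrees.
#' @return Energies in kJ/mol.
#' @export
evaluate_torsion <- function(term, angle_deg) {
  B <- opls_basis(angle_deg, length(term$coefficients))
  as.numeric(B %*% term$coefficients) + term$offset
}

#' Residual torsional profile after nonbonded subtraction
#'
#' For each scan point, subtracts the intramolecular Coulomb and
#' Lennard-Jones energy of the scan conformation from the QM energy and
#' shifts the result so its minimum is zero.  The residual is the part of
#' the QM profile assignable to the explicit torsional term.
#'
#' @param scan A [torsion_scan()].
#' @param mol The [molecule()] the scan conformations belong to.
#' @param model A [nonbonded_model()].
#' @param exclusions Optional precomputed [build_exclusions()] table.
#' @return Object of class `residual_profile`: tibble with columns `angle`
#'   (degrees), `energy` (kJ/mol, min 0) and `nonbonded` (kJ/mol).
#' @export
residual_profile <- function(scan, mol, model = nonbonded_model(),
                             exclusions = NULL) {
  exclusions <- exclusions %||% build_exclusions(mol)
  nb <- map_dbl(seq_len(nrow(scan)), function(i) {
    tryCatch(
      nonbonded_energy(scan$conf[[i]], mol, model, exclusions),
      error = function(e) {
        abort(sprintf("at scan angle %.1f deg: %s",
                      scan$angle[i], conditionMessage(e)))
      })
  })
  nb_kj <- kcal_to_kj(nb)
  res <- scan$qm_energy - nb_kj
  out <- tibble(angle = scan$angle, energy = res - min(res), nonbonded = nb_kj)
  structure(out, dihedral = attr(scan, "dihedral"),
            class = c("residual_profile", class(out)))
}

#' Fit a cosine series to a residual torsional profile
#'
#' Ordinary (optionally weighted) linear least squares of the residual
#' profile on the alternating OPLS cosine basis of orders `1..max_order`
#' plus a free constant.  The fit is deterministic; a rank-deficient design
#' (angles aliasing a basis function) raises an error naming the offending
#' order.  Boltzmann weighting at a given temperature down-weights
#' high-energy scan points (`w = exp(-E/kT)`); it is off by default.
#' Manually refined coefficients can be imposed via `overrides` (a named
#' vector like `c(V3 = 4.2)`); they are substituted after fitting and
#' recorded in the fit object.
#'
#' @param profile A [residual_profile()], or any data frame with columns
#'   `angle` (degrees) and `energy` (kJ/mol).
#' @param max_order Highest cosine order N (default 4).
#' @param weights Optional per-point weights.
#' @param boltzmann_temperature Optional temperature (K); when supplied,
#'   Boltzmann weights replace uniform weights.
#' @param overrides Optional named numeric vector of coefficient overrides.
#' @return Object of class `torsion_fit` with the fitted
#'   [fourier_torsion()], per-point residuals, RMSE (kJ/mol) and standard
#'   errors.  Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_fourier <- function(profile, max_order = 4, weights = NULL,
                        boltzmann_temperature = NULL, overrides = NULL) {
  angle <- profile$angle
  energy <- profile$energy
  if (length(angle) < max_order + 1) {
    abort("need at least max_order + 1 scan points")
  }
  B <- opls_basis(angle, max_order)
  X <- cbind(offset = 1, B)
  colnames(X) <- c("offset", paste0("V", seq_len(max_order)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    abort(paste0("rank-deficient design: scan angles alias basis term(s) ",
                 paste(dropped, collapse = ", ")))
  }
  if (!is.null(boltzmann_temperature)) {
    kT <- dockfit_constants()$R_kJ * boltzmann_temperature
    weights <- exp(-(energy - min(energy)) / kT)
  }
  w <- weights %||% rep(1, length(angle))
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, energy * sw)
  beta <- fit$coefficients
  coefs <- beta[-1]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(coefs))
    if (length(bad)) abort(paste0("unknown override term(s): ",
                                  paste(bad, collapse = ", ")))
    coefs[names(overrides)] <- overrides
  }
  term <- fourier_torsion(unname(coefs), offset = unname(beta[1]),
                          label = attr(profile, "dihedral")$label)
  fitted_vals <- evaluate_torsion(term, angle)
  resid <- energy - fitted_vals
  rmse <- sqrt(mean(resid^2))
  # standard errors from the unweighted-or-weighted LS solution
  dof <- max(1L, length(angle) - ncol(X))
  sigma2 <- sum((fit$residuals)^2) / dof
  XtXinv <- chol2inv(qr.R(qr(X * sw)))
  se <- sqrt(pmax(0, diag(XtXinv)) * sigma2)
  names(se) <- colnames(X)
  structure(
    list(term = term, max_order = max_order,
         rmse = rmse,
         residuals = tibble(angle = angle, energy = energy,
                            fitted = fitted_vals, residual = resid,
                            weight = w),
         std_errors = se,
         overrides = overrides),
    class = "torsion_fit")
}

#' @export
print.torsion_fit <- function(x, ...) {
  cat(sprintf("<torsion_fit> order %d, RMSE %.4g kJ/mol%s\n", x$max_order,
              x$rmse,
              if (length(x$overrides)) " (with manual overrides)" else ""))
  print(x$term)
  invisible(x)
}

#' @describeIn fit_fourier Coefficient table: one row per basis term with
#'   estimate (kJ/mol), standard error, and whether it was overridden.
#' @param x A `torsion_fit`.
#' @param ... Unused.
#' @export
tidy.torsion_fit <- function(x, ...) {
  terms <- c("offset", paste0("V", seq_along(x$term$coefficients)))
  est <- c(x$term$offset, x$term$coefficients)
  tibble(term = terms,
         order = c(0L, seq_along(x$term$coefficients)),
         estimate = est,
         std.error = unname(x$std_errors[terms]),
         overridden = terms %in% names(x$overrides %||% character()))
}

#' @describeIn fit_fourier One-row fit summary (RMSE, max |residual|,
#'   number of points, order).
#' @export
glance.torsion_fit <- function(x, ...) {
  tibble(rmse = x$rmse,
         max_abs_residual = max(abs(x$residuals$residual)),
         nobs = nrow(x$residuals),
         max_order = x$max_order)
}

#' @describeIn fit_fourier Profile points and fitted curve.
#' @param object A `torsion_fit`.
#' @export
autoplot.torsion_fit <- function(object, ...) {
  grid <- tibble(angle = seq(-180, 180, by = 1))
  grid$energy <- evaluate_torsion(object$term, grid$angle)
  ggplot2::ggplot(object$residuals, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$energy), colour = "grey30") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$energy),
                       colour = "firebrick") +
    ggplot2::labs(x = "dihedral angle (deg)", y = "energy (kJ/mol)",
                  title = object$term$label %||% "torsional profile fit")
}

#' Compare a fitted torsional term against a reference profile
#'
#' Evaluates the term on the profile's angles, shifts both curves so their
#' minimum over the compared points is zero, and reports the maximum
#' absolute difference, the RMSE and a per-angle table.
#'
#' @param term A [fourier_torsion()].
#' @param profile Data frame with columns `angle` (degrees) and `energy`
#'   (kJ/mol); typically a [residual_profile()].
#' @return Object of class `profile_comparison`: list with `max_abs`,
#'   `rmse` (kJ/mol) and `table` (tibble: angle, reference, fitted, delta).
#' @export
profile_comparison <- function(term, profile) {
  ref <- profile$energy - min(profile$energy)
  fitted_vals <- evaluate_torsion(term, profile$angle)
  fitted_vals <- fitted_vals - min(fitted_vals)
  delta <- fitted_vals - ref
  structure(
    list(max_abs = max(abs(delta)), rmse = sqrt(mean(delta^2)),
         table = tibble(angle = profile$angle, reference = ref,
                        fitted = fitted_vals, delta = delta)),
    class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> max |delta| %.4g kJ/mol, RMSE %.4g kJ/mol over %d points\n",
              x$max_abs, x$rmse, nrow(x$table)))
  invisible(x)
}

#' Format a torsional term as a Gromacs-style dihedral line
#'
#' Emits the fitted coefficients as a Fourier dihedral parameter text line
#' (kJ/mol, fixed "%.6f" formatting) for inclusion in a topology file, and
#' as a JSON parameter block via [jsonlite::toJSON].
#'
#' @param term A [fourier_torsion()].
#' @param atoms Optional four atom names for the comment field.
#' @return Character scalar (the text line).
#' @export
format_gromacs_dihedral <- function(term, atoms = NULL) {
  pad4 <- c(term$coefficients, rep(0, max(0, 4 - length(term$coefficients))))[1:4]
  lbl <- if (!is.null(atoms)) paste(atoms, collapse = " ") else "X X X X"
  sprintf("%s  5  %s ; %s", lbl,
          paste(sprintf("%.6f", pad4), collapse = "  "),
          term$label %||% "fitted torsion")
}
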