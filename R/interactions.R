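# Geometric protein-ligand interaction profiling: hydrogen-bond
# compatibility by donor-acceptor heavy-atom distance, hydrophobic
# contacts, and per-residue any-atom contact fractions.

#' Classify a donor-acceptor distance as hydrogen-bond compatible
#'
#' A distance is compatible with hydrogen bonding iff it does not exceed
#' the threshold (inclusive; default 3.5 Angstrom).  The rule is
#' heavy-atom distance only -- no angle criterion.
#'
#' @param d Donor-acceptor distances, Angstrom (> 0).
#' @param threshold Compatibility threshold, Angstrom.
#' @return Logical vector.
#' @examples
#' classify_hbond_distance(c(2.7, 3.5, 3.7)) # TRUE TRUE FALSE
#' @export
classify_hbond_distance <- function(d, threshold = 3.5) {
  if (any(d <= 0)) abort("distances must be positive")
  # 1e-9 A guard so constructed geometries sitting exactly on the
  # threshold are not misclassified by floating-point noise
  d - threshold <= 1e-9
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

pair_distances <- function(a, b) {
  # |A| x |B| distance matrix between two atom tibbles
  xa <- atom_xyz(a); xb <- atom_xyz(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Detect hydrogen bonds between a ligand and a receptor
#'
#' Two modes.  Without `pairs`, every donor-acceptor atom pair across the
#' two molecules (either direction) within `search_radius` is measured and
#' classified.  With a pair dictionary -- a data frame with columns
#' `label`, `receptor_atom`, `receptor_resno`, `ligand_atom` naming
#' specific atom pairs -- exactly those pairs are measured, in order;
#' a named ligand atom that is absent from the ligand (e.g. the beta-OH of
#' a ligand lacking that group) yields a row with `present = FALSE` and
#' `NA` distance rather than an error, while a missing *receptor* atom is
#' an error naming the pair.
#'
#' @param ligand,receptor Atom tibbles (see [atom_table()]) with
#'   coordinates and donor/acceptor flags.
#' @param pairs Optional pair dictionary (see Details above).
#' @param threshold Hydrogen-bond compatibility threshold, Angstrom.
#' @param search_radius Maximum donor-acceptor distance considered in
#'   automatic mode, Angstrom.
#' @return Tibble with one row per hydrogen-bond record: `label`,
#'   `ligand_atom`, `receptor_atom`, `receptor_residue`, `distance`,
#'   `compatible`, `present`.
#' @export
detect_hbonds <- function(ligand, receptor, pairs = NULL, threshold = 3.5,
                          search_radius = 8) {
  if (is.null(pairs)) {
    D <- pair_distances(ligand, receptor)
    polar_pair <- outer(ligand$donor, receptor$acceptor, `&`) |
      outer(ligand$acceptor, receptor$donor, `&`)
    hit <- which(polar_pair & D <= search_radius, arr.ind = TRUE)
    if (nrow(hit) == 0) {
      return(tibble(label = character(), ligand_atom = character(),
                    receptor_atom = character(), receptor_residue = character(),
                    distance = numeric(), compatible = logical(),
                    present = logical()))
    }
    li <- hit[, 1]; ri <- hit[, 2]
    res <- sprintf("%s%d", receptor$resname[ri], receptor$resno[ri])
    out <- tibble(
      label = sprintf("%s (%s)-%s", receptor$name[ri], res, ligand$name[li]),
      ligand_atom = ligand$name[li],
      receptor_atom = receptor$name[ri],
      receptor_residue = res,
      distance = D[hit],
      present = TRUE
    )
    out$compatible <- classify_hbond_distance(out$distance, threshold)
    return(arrange(out, .data$distance))
  }
  rows <- pmap(pairs, function(label, receptor_atom, receptor_resno,
                               ligand_atom, ...) {
    ri <- which(receptor$name == receptor_atom & receptor$resno == receptor_resno)
    if (length(ri) == 0) {
      abort(sprintf("receptor atom %s/%d not found for pair '%s'",
                    receptor_atom, receptor_resno, label))
    }
    ri <- ri[1]
    li <- which(ligand$name == ligand_atom)
    res <- sprintf("%s%d", receptor$resname[ri], receptor$resno[ri])
    if (length(li) == 0) {
      return(tibble(label = label, ligand_atom = ligand_atom,
                    receptor_atom = receptor_atom, receptor_residue = res,
                    distance = NA_real_, compatible = NA, present = FALSE))
    }
    li <- li[1]
    d <- sqrt(sum((atom_xyz(ligand)[li, ] - atom_xyz(receptor)[ri, ])^2))
    tibble(label = label, ligand_atom = ligand_atom,
           receptor_atom = receptor_atom, receptor_residue = res,
           distance = d, compatible = classify_hbond_distance(d, threshold),
           present = TRUE)
  })
  bind_rows(rows)
}

#' Flag hydrophobic atoms
#'
#' Marks carbon and sulfur atoms not bonded to nitrogen or oxygen as
#' hydrophobic (the usual geometric-profiler convention).
#'
#' @param mol A [molecule()].
#' @return The molecule with its atoms' `hydrophobic` column updated.
#' @export
assign_hydrophobic_flags <- function(mol) {
  at <- mol$atoms
  polar_nb <- rep(FALSE, nrow(at))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
    if (at$element[j] %in% c("N", "O")) polar_nb[i] <- TRUE
    if (at$element[i] %in% c("N", "O")) polar_nb[j] <- TRUE
  }
  mol$atoms$hydrophobic <- at$element %in% c("C", "S") & !polar_nb
  mol
}

#' Detect hydrophobic contacts
#'
#' All pairs of hydrophobic-flagged ligand and receptor atoms within the
#' cutoff (inclusive; default 4.0 Angstrom), plus per-residue counts.
#'
#' @param ligand,receptor Atom tibbles with `hydrophobic` flags.
#' @param cutoff Contact cutoff, Angstrom.
#' @return List with `contacts` (tibble: ligand_atom, receptor_atom,
#'   receptor_residue, distance) and `by_residue` (tibble: residue keyed by
#'   chain/resno/resname, n_contacts).
#' @export
detect_hydrophobic <- function(ligand, receptor, cutoff = 4.0) {
  lf <- ligand[ligand$hydrophobic, , drop = FALSE]
  rf <- receptor[receptor$hydrophobic, , drop = FALSE]
  empty <- tibble(ligand_atom = character(), receptor_atom = character(),
                  receptor_residue = character(), distance = numeric())
  if (nrow(lf) == 0 || nrow(rf) == 0) {
    return(list(contacts = empty,
                by_residue = tibble(chain = character(), resno = integer(),
                                    resname = character(), n_contacts = integer())))
  }
  D <- pair_distances(lf, rf)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  contacts <- if (nrow(hit)) {
    li <- hit[, 1]; ri <- hit[, 2]
    tibble(ligand_atom = lf$name[li], receptor_atom = rf$name[ri],
           receptor_residue = sprintf("%s%d", rf$resname[ri], rf$resno[ri]),
           chain = rf$chain[ri], resno = rf$resno[ri], resname = rf$resname[ri],
           distance = D[hit])
  } else {
    mutate(empty, chain = character(0), resno = integer(0), resname = character(0))
  }
  by_res <- contacts |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(n_contacts = n(), .groups = "drop")
  list(contacts = select(contacts, "ligand_atom", "receptor_atom",
                         "receptor_residue", "distance"),
       by_residue = by_res)
}

#' Per-residue contact fractions over a trajectory
#'
#' For each receptor residue, the fraction of frames in which any ligand
#' atom lies within `cutoff` (inclusive; default 5.0 Angstrom) of any atom
#' of that residue.
#'
#' @param frames List of frames; each frame is a list with elements
#'   `ligand` and `receptor` (atom tibbles with coordinates).  A static
#'   complex may be passed as a single-frame list.
#' @param cutoff Contact cutoff, Angstrom.
#' @return Tibble: `chain`, `resno`, `resname`, `fraction` in \[0, 1\].
#' @export
contact_profile <- function(frames, cutoff = 5.0) {
  if (length(frames) == 0) abort("need at least one frame")
  per_frame <- map(frames, function(fr) {
    D <- pair_distances(fr$ligand, fr$receptor)
    near <- apply(D <= cutoff, 2, any)   # per receptor atom
    tibble(chain = fr$receptor$chain, resno = fr$receptor$resno,
           resname = fr$receptor$resname, near = near) |>
      group_by(.data$chain, .data$resno, .data$resname) |>
      summarise(in_contact = any(.data$near), .groups = "drop")
  })
  bind_rows(per_frame) |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(fraction = mean(.data$in_contact), .groups = "drop") |>
    arrange(.data$chain, .data$resno)
}

#' Summarise hydrogen-bond and hydrophobic interaction counts
#'
#' Runs both detectors on a complex and tabulates the number of compatible
#' hydrogen bonds and hydrophobic contacts -- the per-model counts shown in
#' interaction-count bar plots.
#'
#' @param ligand,receptor Atom tibbles.
#' @param hbond_threshold,hydrophobic_cutoff Distance rules, Angstrom.
#' @param pairs Optional hydrogen-bond pair dictionary (see
#'   [detect_hbonds()]).
#' @return One-row tibble: `n_hbonds`, `n_hydrophobic`.
#' @export
interaction_summary <- function(ligand, receptor, pairs = NULL,
                                hbond_threshold = 3.5,
                                hydrophobic_cutoff = 4.0) {
  hb <- detect_hbonds(ligand, receptor, pairs = pairs,
                      threshold = hbond_threshold)
  hp <- detect_hydrophobic(ligand, receptor, cutoff = hydrophobic_cutoff)
  tibble(n_hbonds = sum(hb$compatible, na.rm = TRUE),
         n_hydrophobic = nrow(hp$contacts))
}

#' Plot a per-residue contact profile
#'
#' @param profile Result of [contact_profile()].
#' @return A ggplot: contact fraction per residue.
#' @export
plot_contact_profile <- function(profile) {
  profile$residue <- factor(sprintf("%s%d", profile$resname, profile$resno),
                            levels = sprintf("%s%d", profile$resname, profile$resno))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of frames in contact") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
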