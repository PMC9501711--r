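# File formats and run configuration: fixed-column PDB (through bio3d),
# a PDBQT-lite dialect carrying partial charges and rotatable bonds,
# XVG-style angle/profile tables, and YAML run configuration.

#' Read a (multi-model) PDB file
#'
#' Wraps [bio3d::read.pdb()] into the package's atom-tibble convention.
#' ATOM and HETATM records are kept; 1-based residue numbering and
#' insertion codes round-trip unchanged.
#'
#' @param path PDB file path.
#' @return List with `atoms` (atom tibble, coordinates of the first
#'   model) and `conformations` (list of N x 3 matrices, one per MODEL).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- atom_table(
    name = at$elety, element = ifelse(nzchar(trimws(at$elesy %||% "")),
                                      trimws(at$elesy),
                                      substr(trimws(at$elety), 1, 1)),
    x = at$x, y = at$y, z = at$z,
    resname = at$resid, resno = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain))
  atoms$insert <- ifelse(is.na(at$insert), "", at$insert)
  atoms$record <- at$type
  nmod <- nrow(pdb$xyz)
  confs <- map(seq_len(nmod), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  list(atoms = atoms, conformations = confs)
}

#' Write a (multi-model) PDB file
#'
#' Single conformations are written through [bio3d::write.pdb()]; several
#' conformations are wrapped in MODEL/ENDMDL records.
#'
#' @param atoms Atom tibble (see [atom_table()]); optional columns
#'   `record` ("ATOM"/"HETATM") and `insert` are honoured.
#' @param path Output path.
#' @param conformations Optional list of N x 3 matrices; defaults to the
#'   coordinates in `atoms`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, conformations = NULL) {
  rec <- atoms[["record"]] %||% rep("ATOM", nrow(atoms))
  ins <- atoms[["insert"]] %||% rep("", nrow(atoms))
  one_model <- function(xyz) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(file = tmp,
                     type = rec,
                     xyz = as.numeric(t(xyz)),
                     resno = atoms$resno, resid = atoms$resname,
                     eleno = seq_len(nrow(atoms)), elety = atoms$name,
                     chain = atoms$chain, insert = ins,
                     elesy = atoms$element)
    grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE)
  }
  confs <- conformations %||% list(atom_xyz(atoms))
  lines <- character(0)
  if (length(confs) == 1) {
    lines <- one_model(confs[[1]])
  } else {
    for (m in seq_along(confs)) {
      lines <- c(lines, sprintf("MODEL     %4d", m), one_model(confs[[m]]),
                 "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDBQT-lite file
#'
#' Parses the docking-format dialect: ATOM/HETATM records with the partial
#' charge in columns 67-76, plus BRANCH and TORSDOF records.  Only the
#' rotatable-bond atom pairs and the torsional-degrees-of-freedom count
#' are retained from the torsion tree.
#'
#' @param path PDBQT file path.
#' @return List with `atoms` (atom tibble including charges),
#'   `rotatable_bonds` (two-column integer matrix of atom serial pairs)
#'   and `torsdof` (integer or NA).
#' @export
read_pdbqt <- function(path) {
  lines <- readLines(path)
  at <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (length(at) == 0) abort(sprintf("no ATOM/HETATM records in %s", path))
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (any(is.na(v))) {
      abort(sprintf("malformed numeric field in %s (line %d)", path,
                    grep("^(ATOM|HETATM)", lines)[which(is.na(v))[1]]))
    }
    v
  }
  atoms <- atom_table(
    name = trimws(substr(at, 13, 16)),
    element = {
      e <- trimws(substr(at, 78, 79))
      ifelse(nzchar(e), substr(e, 1, 1), substr(trimws(substr(at, 13, 16)), 1, 1))
    },
    x = num(substr(at, 31, 38)), y = num(substr(at, 39, 46)),
    z = num(substr(at, 47, 54)),
    charge = num(substr(at, 67, 76)),
    resname = trimws(substr(at, 18, 20)),
    resno = as.integer(num(substr(at, 23, 26))),
    chain = { ch <- substr(at, 22, 22); ifelse(nzchar(trimws(ch)), ch, "A") })
  br <- grep("^BRANCH", lines, value = TRUE)
  rot <- if (length(br)) {
    do.call(rbind, lapply(strsplit(trimws(sub("^BRANCH", "", br)), "\\s+"),
                          function(p) as.integer(p[1:2])))
  } else {
    matrix(integer(0), ncol = 2)
  }
  td <- grep("^TORSDOF", lines, value = TRUE)
  torsdof <- if (length(td)) {
    as.integer(trimws(sub("^TORSDOF", "", td[1])))
  } else {
    NA_integer_
  }
  list(atoms = atoms, rotatable_bonds = rot, torsdof = torsdof)
}

#' Read dihedral-angle samples from a text file
#'
#' Accepts either one angle per line or XVG-style two-column (time, angle)
#' tables; `#` and `@` comment lines are skipped.
#'
#' @param path File path.
#' @return Numeric vector of angles (degrees), wrapped into (-180, 180].
#' @export
read_angles <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !ncol %in% c(1, 2)) {
    abort(sprintf("%s: expected 1 or 2 whitespace-separated columns", path))
  }
  vals <- vapply(fields, function(f) as.numeric(f[ncol]), numeric(1))
  wrap_angle(vals)
}

#' Write a profile as an XVG-style table
#'
#' Two columns (angle or bin center, value) preceded by `@`/`#` header
#' lines carrying axis labels and provenance (package version and any
#' supplied seed).  Undefined values are written as `nan`.
#'
#' @param x Data frame whose first two columns are written.
#' @param path Output path.
#' @param title,xlab,ylab Header strings.
#' @param seed Optional seed to echo in the header.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, path, title = "profile", xlab = "angle (deg)",
                      ylab = "value", seed = NULL) {
  hdr <- c(sprintf("# dockfit %s", as.character(utils::packageVersion("dockfit"))),
           if (!is.null(seed)) sprintf("# seed %d", seed),
           sprintf("@    title \"%s\"", title),
           sprintf("@    xaxis  label \"%s\"", xlab),
           sprintf("@    yaxis  label \"%s\"", ylab))
  body <- sprintf("%12.4f %14.8g", x[[1]], x[[2]])
  body <- sub("NA$", "nan", body)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a torsional scan table
#'
#' Delimited table with columns `angle` (degrees) and `energy`, with the
#' unit ("kJ/mol" or "kcal/mol") either in a `unit` column or supplied as
#' an argument.
#'
#' @param path File path (whitespace- or comma-delimited with header).
#' @param unit Energy unit when the table has no `unit` column.
#' @return Tibble with `angle` and `energy` (kJ/mol).
#' @export
read_scan_table <- function(path, unit = "kJ/mol") {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("angle", "energy") %in% names(df))) {
    abort(sprintf("%s: need columns 'angle' and 'energy'", path))
  }
  u <- if ("unit" %in% names(df)) df$unit[1] else unit
  e <- if (identical(u, "kcal/mol")) kcal_to_kj(df$energy) else df$energy
  tibble(angle = wrap_angle(df$angle), energy = e)
}

#' Default run configuration
#'
#' The package defaults reproduce the standard docking/analysis settings:
#' 2.0 A cluster tolerance; 0.5 A / 70% run-consistency rule; 5.0 A
#' any-atom contact cutoff; 3.5 A hydrogen-bond threshold; 4.0 A
#' hydrophobic cutoff; 298.15 K conversion temperature with a +0.2 pKd
#' offset to 310.15 K; 50 grid points per axis at 0.375 A spacing;
#' 5-degree free-energy bins; cosine-fit order 4.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cluster_tolerance = 2.0,
    consistency_rmsd = 0.5,
    consistency_fraction = 0.70,
    contact_cutoff = 5.0,
    hbond_threshold = 3.5,
    hydrophobic_cutoff = 4.0,
    temperature = 298.15,
    physiological_temperature = 310.15,
    pkd_offset = 0.2,
    grid_points = 50L,
    grid_spacing = 0.375,
    bin_width = 5,
    fit_max_order = 4L,
    seed = 1L
  )
}

#' Read and write a YAML run configuration
#'
#' Serialization is idempotent: `write_config(read_config(p))` reproduces
#' the same document.  Unknown keys are preserved; missing keys fall back
#' to [default_config()].
#'
#' @param path YAML file path.
#' @param config Named list (e.g. from [default_config()]).
#' @return `read_config`: named list.  `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
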